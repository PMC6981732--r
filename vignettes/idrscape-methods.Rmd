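---
title: "Methods: the intrinsic-disorder landscape pipeline"
author: "idrscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the intrinsic-disorder landscape pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

AP2/ERF transcription factors — and many other plant transcription-factor
families — share a characteristic architecture: one compact, highly
conserved DNA-binding domain (the ~58-residue AP2 domain, three
β-strands followed by an α-helix) embedded in long regions that never
adopt a stable fold. Those intrinsically disordered regions (IDRs) carry
the transcription-regulatory activity, and within them short
interaction-prone segments — molecular recognition features (MoRFs) —
are often conserved across the members of a phylogenetic subgroup.

`idrscape` implements the sequence-level analyses used to map this
landscape: compositional profiling against a folded-protein baseline,
two whole-protein binary disorder classifiers and their combination,
per-residue disorder statistics, low-complexity masking, MoRF detection
and subgroup-level conservation calling, phosphosite fractions, and a
neighbour-joining subgroup tree. Because the original inputs (curated
family sequences and the outputs of several trained external predictors)
cannot be bundled, a synthetic family generator reproduces the
architecture with machine-readable ground truth, so every stage is
testable end to end.

# Compositional profiling

For a set of sequences, `composition()` pools residue counts over the 20
canonical amino acids (placeholder `X` is excluded from numerator and
denominator). The relative profile against a fully-structured-protein
(FSP) baseline is, per residue type $i$,

$$\mathrm{value}_i = \frac{C_i - C_i^{FSP}}{C_i^{FSP}},$$

where $C_i$ is the query fraction and $C_i^{FSP}$ the baseline fraction.
Positive values mean enrichment relative to folded proteins. Confidence
intervals come from a percentile bootstrap that resamples *whole
proteins* with replacement (`bootstrap_profile()`); resampling residues
would understate the variance because composition is strongly clustered
within proteins. The default is 1000 replicates at the 95% level in the
pipeline configuration; the percentile method was chosen over BCa as the
simplest method consistent with resampling whole proteins.

The bundled baseline (`fsp_baseline()`) is a synthetic stand-in table of
average globular-protein residue frequencies; any baseline can be
substituted via a two-column TSV (`read_baseline()`). Profiles are
reported on a fixed order-to-disorder residue axis with tryptophan
(most order-promoting) leftmost and glutamate (most disorder-promoting)
rightmost; the interior ordering is conventional and configurable
(`order_disorder_axis()`).

# Binary disorder classifiers

**Charge-hydropathy (CH).** Per-residue Kyte–Doolittle hydropathy is
rescaled to $[0,1]$ by $(h + 4.5)/9$, smoothed with a centred window
(default 5, truncated at the ends) and averaged to give $\langle H
\rangle$; the mean absolute net charge is $\langle R \rangle = |(\#K +
\#R) - (\#D + \#E)|/L$ with histidine neutral by default. The classifier
is the line $\langle R \rangle = a\langle H \rangle - b$ with the
published boundary constants $a = 2.785$, $b = 1.151$ as defaults;
`ch_distance()` reports the signed vertical offset (positive =
disordered side), with the perpendicular distance available as an
option. The raw offset is what enters the phase-space quadrants.

**Cumulative distribution function (CDF).** Given a per-residue disorder
track, the CDF value at bin $b$ is the fraction of residues with score
$\le b$ (nine bins, 0.1–0.9). Ordered proteins accumulate low scores
quickly, so their curves run *above* a boundary; the CDF distance is the
mean signed offset over the boundary points (positive = ordered).
Published CDF boundaries are specific to the predictor that produced the
scores and are not available here, so the default boundary is the
analytic midpoint between the package's two score-emission models —
$\tfrac12[F_{\mathrm{Beta}(2,8)}(b) + F_{\mathrm{Beta}(8,2)}(b)]$ — and
`calibrate_cdf_boundary()` fits an empirical midpoint from any pair of
ordered/disordered reference track sets. When external predictor tracks
are used, the boundary should be recalibrated on tracks from the same
predictor.

**CH-CDF phase space.** Each protein (or region view) becomes a point
$(x, y) = (\text{CDF distance}, \text{CH distance})$. Quadrants encode
classifier agreement: Q1 (upper-right) disordered by CH but ordered by
CDF; Q2 (lower-right) ordered by both; Q3 (lower-left) disordered by CDF
but compact by CH; Q4 (upper-left) disordered by both. A zero on either
axis resolves toward the ordered call — an explicit tie rule so the four
labels are exhaustive and mutually exclusive.

**Disorder tracks.** External per-residue predictions are first-class
inputs (`read_track()`, validated against the sequences, scores clamped
to $[0,1]$ with a warning). `internal_track()` is a self-contained
windowed charge/hydropathy propensity — score $= 0.5 - k(aH_w - b -
R_w)$ clamped to $[0,1]$, window 21, gain $k = 0.5$ — that lets the
pipeline run with no external predictor; it makes no claim to reproduce
any trained predictor's scores. IDAA% is $100\times$ the fraction of
residues with score at or above 0.5 (`idaa_fraction()`); a
composition-only variant (`idaa_compositional()`) counts
disorder-promoting residue types instead, since the phrase "disorder
(promoting) amino acids" admits both readings.

# Low complexity

`cast_mask()` follows the iterative homopolymer-alignment idea: score
the sequence position-by-position against an infinite homopolymer of
each residue type using a substitution matrix, find the maximal-scoring
contiguous segment (a single linear Kadane scan; the quadratic
enumeration survives as a test oracle), and while the best (type,
segment) score reaches the threshold, mask occurrences of that type
within the segment as `X` and repeat. Defaults are BLOSUM62 and
threshold 40, the published defaults of the classic iterative
low-complexity detector this module follows. Ties
are resolved deterministically (higher score, then leftmost, then
alphabetical residue). Only the dominant residue type is masked, so
LCAA% — the percentage of masked residues per region class
(`lcaa_by_region()`: full, β-strands, α-helix, non-domain) — counts
exactly the residues driving the bias. Masking is idempotent and the
masked fraction is monotone non-increasing in the threshold; both are
property-tested.

# MoRFs and conservation

Inside long disordered regions, MoRFs appear as short downward spikes of
order propensity. `dip_candidates()` formalises this: maximal runs of
scores below 0.5, between 5 and 25 residues, whose flanking 10-residue
context averages at least 0.5 (one-sided at sequence ends), and which do
not overlap the DNA-binding domain — in-domain MoRFs are accepted only
from external prediction tables (`read_external_morfs()`, span or
per-residue-score schema). External tables take precedence when
supplied; the dip detector is an explicit stand-in justified by the
tendency of such dips to coincide with predicted MoRFs.

Conservation is assessed within subgroups on a supplied alignment.
Segments are mapped to alignment columns through the gap structure
(`map_to_alignment()`), clustered by single linkage with at least 5
shared columns, and a cluster is called conserved when its occupancy —
the fraction of subgroup members carrying an overlapping segment — is at
least 0.75. Both thresholds are configuration values: no published
criterion for "conserved within a subgroup" exists, so the package fixes
one and exposes it. Calls are named `<subgroup> <side><index>` with side
N (before the domain), C (after) or AP2 (inside), indices running
N-terminal to C-terminal, following the field's naming convention for
subgroup-conserved motifs. The consensus is the per-column majority residue over
covering members (ties and gap majorities become `X`). A call is flagged
*exclusive* when no other subgroup has a conserved call whose consensus
matches at $\ge 0.6$ identity under the best ungapped offset (identity
over the shorter consensus); exclusivity has no published operational
rule, so the similarity threshold is this package's own definition.

# Phosphosite fractions

`phospho_fractions()` ingests a site-prediction table and reports, per
residue type in {S, T, Y} and per region class (full, domain,
non-domain), $100\times$ predicted sites over residues of that type in
the region, with a pooled "all" column. Denominators are residue counts,
not candidate sites surviving a predictor's internal filtering — the
simpler and more comparable convention. A
type with no residues in a region is reported missing, never 0. The
counts satisfy full = domain + non-domain exactly, which is asserted in
tests.

# Subgroup tree

`p_distance()` computes mismatches over shared non-gap columns; a pair
with no shared columns is an error rather than a guess. `nj_tree()` is a
lightweight Saitou–Nei agglomerator: deterministic tie-breaking (equal
Q-criterion values resolve to the lexicographically lowest label pair,
merged nodes carrying their smallest constituent label), and negative
branch lengths clamped to zero with the deficit moved to the sibling
branch so the joined pair's distance is preserved. On additive matrices
the reconstructed path-length matrix equals the input to $10^{-9}$,
which the tests verify against explicit topology enumeration.
`bootstrap_support()` resamples alignment columns with replacement,
rebuilds the tree per replicate, and reports the percentage of
replicates containing each internal bipartition of the full-data tree;
splits above a configurable cutoff (default 70%) are flagged, matching
the convention of marking well-supported branches. p-distance was chosen
over a substitution model because no model was specified for the
original analysis and it keeps the stage exactly testable in closed
form.

# The synthetic generator

`family_spec()`/`generate_family()` define the study conditions used by
the test-suite and the acceptance script. Defaults, chosen once:

* 4 subgroups × 6 members; domain length 58 with β1/β2/β3/α sub-spans at
  the proportions of the real domain fold.
* Domain composition order-promoting and deliberately W/A/R-rich; flank
  composition disorder-promoting with E = 0.12 and K = 0.02, caricaturing
  the E-enrichment and unusual K-depletion of the real
  transcription-regulatory regions. The contrasts are roughly twice the
  real effect sizes so that classification properties are deterministic
  at 24-protein sample sizes.
* One subgroup consensus per subgroup derived from a family root (15%
  divergence), members at 8% substitution from their consensus. Flank
  lengths are drawn once per subgroup, so subgroup members align without
  gaps and alignment inputs are exact by construction.
* Planted 10-residue motifs at homologous flank offsets — one exclusive
  N-side motif per subgroup; subgroups 1 and 2 share their C-side motif
  (the rest are exclusive) — drawn from patterns echoing the recurring
  family motif classes (EAR-like, EDLL-like, LWSY-like, MCGGAI-like,
  basic and aromatic/acidic repeats). One 12-residue homopolymer run per
  protein seeds low complexity.
* Disorder scores are *emitted*, not computed: Beta(2, 8) in the domain
  and in motif dips, Beta(8, 2) in flanks. This decouples the
  MoRF/IDAA/CDF stages from the internal stand-in predictor; a
  `track_mode = "internal"` switch derives scores from sequence instead
  for integration testing.
* A toy phosphosite emitter: S/T followed by P is always predicted;
  otherwise Bernoulli rates of S 0.25 / T 0.20 / Y 0.05 in disordered
  regions and S 0.05 / T 0.05 / Y 0.30 in the domain, echoing the
  S/T-outside, Y-inside contrast. It makes no biological claim.

Everything is deterministic given the mandatory seed, and the ground
truth (motif spans, low-complexity runs, subgroup labels, generating
tree) round-trips through the emitted plain-text files.

What the generator does *not* emulate: real length variation requiring
gapped alignment within subgroups, predictor noise correlated along the
sequence, compositional drift between subgroups, incomplete or tandem
domains, and realistic effect sizes. Passing tests therefore demonstrate
that the *computations* are correct and well-calibrated on the
architecture they assume — not that the stand-in detectors would match
trained predictors on real proteins.

# Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open; on-disk tables are 1-based
  inclusive, converted only at the I/O boundary (round-trip tested).
* Zero on a phase-space axis resolves to the ordered call; CAST ties to
  higher score/leftmost/alphabetical; NJ ties to the lexicographically
  lowest label pair — every tie rule is explicit so reruns are
  byte-identical.
* Empty sequences, empty tracks, regions absent from a protein, and
  single-protein bootstrap sets are either errors or explicit missing
  values (never silent zeros); proteins with multiple domains are
  dropped with a warning by default, mirroring the exclusion of
  double-domain outliers in family curation.
* Problem sizes in the tests and acceptance script: 24-protein families,
  1000 bootstrap replicates for composition CIs, 100 for tree support,
  10–50 generated families for recovery statistics — sizes at which
  every stage's behaviour is already asymptotic for the properties
  tested.

# Limitations

The internal disorder track is a two-feature heuristic; CDF distances
computed from it are only meaningful against the package's calibrated
boundary, not against published predictor-specific boundaries. The
conserved-MoRF criterion (0.75 occupancy, 5 columns, 0.6 exclusivity
identity) is a reasonable operationalisation, not a community standard.
p-distance NJ will underestimate deep divergences where a substitution
model would correct multiple hits. None of the headline counts published
for the real 375-protein family (conserved-MoRF totals, table
percentages) are reproduced here, since they depend on the original
downloads and trained external predictors.
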