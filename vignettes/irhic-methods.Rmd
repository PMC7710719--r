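---
title: "Methods: models, parameters and numerical choices in irhic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices in irhic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`irhic` quantifies changes in 3D genome organization between two conditions
from binned Hi-C contact matrices. This vignette is the package's own
account of what each stage computes, which knobs matter, and where genuinely
open design choices were settled.

# The generative model behind the synthetic data

Every stage of the pipeline is validated against matrices with *planted*
structure. A `genome_spec` fixes the expected (noise-free) contact intensity
between bins *i* and *j*:

* **cis**: `E_ij = b_i b_j (s^-α + f) (1 + c v_i v_j) τ^[same TAD] Π p_k L_ij`
  with `s = max(1, |i − j|)` in bins (clamping avoids the diagonal
  singularity; distance is measured in bins, not bp),
* **trans**: `E_ij = b_i b_j f (1 + c v_i v_j)`, plus a spliced cis-like term
  `s_fused^-α` between the two arms of any planted translocation
  (reciprocal and fully clonal by default; a mixing fraction is available).

Here `α > 0` is the decay exponent (default 1, the classic contact-decay
regime), `f ≥ 0` a trans/long-range floor, `v ∈ {−1, +1}` the compartment
state with amplitude `c ∈ [0, 1)`, `τ ≥ 1` a within-TAD enrichment,
`p_k ∈ (0, 1]` the permeability of each TAD boundary crossed (the product
runs over all boundaries between *i* and *j*), `L` a per-loop enrichment on
a small square footprint (default 3 bins — pileups average over windows, so
peak shape details are immaterial), and `b > 0` per-bin biases that exercise
balancing. Counts are sampled as independent Poisson draws on the upper
triangle with means `depth · E_ij / ΣE` and mirrored; a Poisson field is the
simplest noise model consistent with count data, and all stochastic
operations take explicit integer seeds.

Default "study conditions" used throughout the tests: 40 kb bins for TAD
analyses, 250 kb for compartments and decay curves, control boundary
permeability 0.4, and an "irradiated" condition created by
`perturb_boundaries()`, which multiplies every permeability by a factor in
(0, 1]. The mapping from a physical dose to that factor is unknown — it is
purely a simulation knob; 0.625 (0.4 → 0.25) is used as the canonical
treated condition for power analyses.

**What the generator does not emulate.** Read-level artifacts (mapping,
fragment geometry), cell-cycle or sub-clonal mixtures (other than the
translocation fraction), loop-extrusion dynamics, and — importantly —
*locality* of insulation: planted permeabilities compound multiplicatively
across every boundary crossed, so a long chromosome with many strong
boundaries loses long-range cis signal faster than real chromatin does.
Passing recovery tests therefore demonstrate the estimators' correctness
under a stylized model, not performance bounds on real data.

# Matrix correction and scaling

`ice_balance()` finds the multiplicative per-bin correction that equalizes
valid-bin marginals (coefficient of variation < `tol`, default 1e-5). Bins
with marginals below 2% of the mean marginal are masked first (the filter
threshold is a package decision; upstream filtering conventions vary), and
all-zero rows are auto-masked with a warning. The default solver is the
Knight–Ruiz inexact-Newton scheme with conjugate-gradient inner iterations;
the classic marginal-division iteration (`algorithm = "ice"`) is retained
because it is the transparent reference — the equal-marginal scaling of an
irreducible nonnegative matrix is unique, so the two agree (this is tested),
but the classic iteration converges linearly and can need thousands of sweeps
on strongly structured matrices. A side effect worth knowing: bins near
chromosome ends have intrinsically lower raw marginals (one-sided decay), so
balancing upweights them; see the saddle-null limitation below.

`scale_to_total()` rescales every matrix to a fixed total (default 10⁶),
which makes condition pairs directly comparable; ratio maps use
`log2((A + ε)/(B + ε))` with ε defaulting to the smallest positive entry
across both matrices so empty cells do not dominate at coarse resolution.

# Reproducibility score

Each genome-wide matrix (cis + trans, coarse bins) is log-transformed (zeros
are replaced by the matrix's smallest positive entry; masked bins excluded),
reduced to its bin–bin Pearson correlation map, flattened column-wise, and
two datasets are compared by the Spearman rank correlation (average ranks for
ties) of those vectors. The unit diagonal is kept by default — constant
entries shift every rank equally and barely move the score — and a flag
removes it. The score is exactly invariant to fixed-total scaling.

# Distance-decay curves

For each chromosome, per-distance mean contact frequencies (diagonal
excluded, zero/nonpositive means dropped) are fitted with loess in
log10–log10 space — chosen over linear space for variance stabilization —
with span 0.3 and pair-count weights. Fits are evaluated on a shared grid of
50 log-spaced distances from one bin to the longest chromosome span,
averaged across chromosomes on the *linear* scale (a log-scale average is
available via `average = "log"`), and normalized so the value at the minimum
distance is exactly 1. `scaling_slope()` reports the OLS log–log slope over
the central decade of the grid; on a noise-free `α = 1.2` matrix it returns
−1.2 to machine-level accuracy, which is the package's decay-exponent
recovery check.

# Compartments and saddles

Per chromosome the matrix is O/E-normalized (each entry divided by its
distance-stratum mean), the Pearson correlation matrix of O/E is formed, and
its leading eigenvectors are extracted. Two decisions the underlying
literature leaves open are settled as follows:

* **Component choice.** Which component carries compartments is
  chromosome-dependent; when an anchor track is supplied the component (of
  the first 2 by default) with the largest |correlation| to the anchor is
  selected, and this choice is recorded per chromosome.
* **Sign orientation.** Eigenvector sign is arbitrary; it is fixed by
  positive correlation with the anchor (the planted vector in simulations;
  gene density or GC content are natural anchors on real data). Without an
  anchor the sign is left as computed and the track is marked unoriented.

`switch_fraction()` is the fraction of mutually valid bins whose A/B label
differs — symmetric in its arguments. `saddle()` ranks valid bins by the
eigenvector, splits them into Q = 10 equal-count quantiles, averages cis O/E
within quantile pairs, and summarizes strength as
`log2(AA·BB / AB²)` over the extreme 20% of quantiles on each side (the
corner size is a package decision).

**Known limitation (saddle null).** On a matrix with *no* compartment
signal, the leading component has nothing to find and locks onto
chromosome-end bins, which ICE has upweighted; the resulting self-ranked
null strength is ≈ −0.13 rather than 0, essentially independent of bin count
and depth (a random ranking gives ≈ 0). Null checks therefore compare the
no-signal strength against the weakest planted amplitude rather than against
exact zero; with `c = 0.1` the planted strength is already ~5× the null
artifact, and strength is strictly monotone in `c` over {0.1, 0.2, 0.3}.

# TAD boundaries: two callers

**Insulation score.** `I_i` is the mean of the `w × w` block of contacts
between the `w` bins upstream and downstream of bin *i*, with
`w = floor(square/res)` — 500 kb at 40 kb bins gives `w = 12` (480 kb
effective, since 500 kb is not an integral number of bins). The reported
score is `log2(I_i / geometric mean of I)` per chromosome; the geometric
mean (log-space mean) is used because the originating convention is
ambiguous between means, and it makes valid scores average 0. Bins within
`w` of chromosome ends, bins with empty squares, and chromosomes shorter
than `2w + 1` bins are masked. Boundaries sit where the delta vector — the
mean score over the 3 bins downstream minus the 3 bins upstream — crosses
zero from negative to positive (the crossing direction at a score minimum
under this orientation), centered on the local score minimum, leftmost bin
on ties. Strength is the local maximum of delta right of the crossing minus
the local minimum left of it; crossings below a noise floor of 0.1 are
discarded at call time, while the conventional "strength > 1" cut is applied
later, at the pileup/statistics stage, both thresholds exposed.

**Hicratio.** With `D = floor(d/res)` flanking bins (400 kb → D = 10 at
40 kb), within-window contact means and cross-window contact means are
compared *at matched genomic separations* and the per-distance ratios
averaged. Distance matching removes the decay from the comparison, so the
track is exactly 1 on a translation-invariant matrix and ≈ `τ/p` at a
boundary — which is what makes the conventional outlier filter (keep
strengths in (1, 12]) meaningful; a naive within/cross ratio over unmatched
distances has a baseline far above 1 under realistic decay and would empty
that band. Boundaries are local maxima of the track within ±D bins above
threshold 1, leftmost bin of a plateau.

Both callers are exactly invariant to fixed-total scaling (they are ratios
of means). On clean simulations with planted boundaries the two callers
agree within ±2 bins for ≥80% of insulation calls; on real data they are
known to diverge occasionally, which is why both are provided.

# Pileups

Boundary pileups average raw corrected contacts (no O/E normalization — an
option exists but defaults off) over boundary-centered windows of ±500 kb,
masking cells within 30 kb of the diagonal and skipping (and counting)
boundaries whose window leaves the chromosome; each boundary contributes
equal weight. Loop pileups average windows centered on anchor-pair bins.
Two readouts invert the generative model: the permeability estimate compares
cross-boundary and within-TAD quadrant means *at matched distances*
(geometric mean over distances), and the loop-enrichment estimate divides
the center pixel by the mean of same-offset diagonal pixels outside the
footprint — matching distances in both cases removes the decay confound
that plain quadrant means would suffer. These readouts are computed on
scaled, unbalanced simulations (no bias is planted there, and correction
would slightly redistribute signal around boundaries), recovering planted
`p = 0.3` within ~1% and `λ = 3` within a few percent at depth 10⁷.

# Paired comparisons

Boundary sets from two conditions are matched greedily by position
(nearest first, each boundary used once, default tolerance 1 bin), and
matched strength differences are tested with a one-sided Wilcoxon
signed-rank test: exact distribution below 20 nonzero differences, normal
approximation with continuity correction otherwise; zero differences are
dropped (standard signed-rank convention). Pooled (unmatched) comparisons
are possible but the matched mode is recommended — a signed-rank test
formally requires pairing. Change summaries report type-7 quartiles with the
upper whisker at `q3 + 1.5·IQR` and the lower whisker clamped to the data
minimum.

Power and calibration are established in the test suite by simulation:
with 100 boundaries, depth 10⁷ and permeability 0.4 → 0.25, the full
pipeline detects strengthening at p < 0.01 in effectively every seeded
replicate, while control-vs-control replicate pairs give one-sided p-values
indistinguishable from uniform (Kolmogorov–Smirnov) across 200 small-genome
seeds.

# Pipeline, problem sizes and determinism

`run_pipeline()` executes all stages from a YAML config and writes every
intermediate artifact plus a JSON summary; any stage failure aborts with the
stage name, preserving partial outputs. All randomness lives in the
simulator's explicit seeds, so reruns of one config are bit-identical.
`make_demo()` emits a 320-bin, two-chromosome control/treated bundle
(permeability 0.6 → 0.45, compartment amplitude 0.35, four λ = 3 loops,
depth 4 × 10⁶) that exercises every stage in seconds. Test problem sizes
were chosen as the smallest at which each recovery is comfortably stable:
~300–500 bins for balancing/compartment checks, ~2,000 bins × 20 seeds for
directional power, ~400 bins × 200 seeds for null calibration.

# Interfaces and formats

Matrices travel as a self-describing dense text format (header, bin table,
dense square matrix; see the README) — cooler's HDF5 container is out of
scope for this package. Tracks are written as bedGraph, boundaries as BED
with the strength in the score column, loops as BEDPE (all 0-based,
half-open); genome-wide matrices keep chromosomes in bin-table order. A thin
command-line wrapper (`inst/cli/irhic`) maps subcommands onto the exported
functions.
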