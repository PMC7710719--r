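# irhic

Analysis of binned Hi-C contact matrices for quantifying how 3D genome
organization responds to a perturbation — built around the ionizing-radiation
(IR) use case, where the effects of interest are a loss of mid-to-long-range
contacts, stable A/B compartment identity, and a genome-wide *increase in TAD
boundary strength* after exposure.

The package is aimed at chromosome-conformation analysts who start from
binned, symmetric contact matrices (not reads) and need a reproducible,
tested control-vs-treated pipeline:

* **Matrix operations** — iterative correction (ICE: multiplicative per-bin
  correction equalizing marginals, solved with a Knight–Ruiz Newton scheme),
  fixed-total scaling (every map scaled to a sum of 10⁶ so conditions are
  comparable), rebinning, masking, and log2 ratio maps.
* **Reproducibility** — each matrix is reduced to its log-scale bin–bin
  correlation map; maps are flattened and compared by Spearman rank
  correlation.
* **Distance decay** — contact frequency *P(s)* versus genomic distance *s*,
  loess-fitted in log–log space per chromosome, averaged, and normalized to 1
  at the minimum distance.
* **Compartments** — per-chromosome observed/expected (O/E) normalization,
  PCA of the O/E correlation matrix, anchor-based sign orientation, A/B
  switch fractions, and saddle-plot compartment strength
  `log2(AA·BB / AB²)` over eigenvector quantiles.
* **TAD boundaries** — two independent callers:
  *insulation score* (mean contacts in a `w × w` square sliding along the
  diagonal, default 500 kb; boundaries at delta-vector zero crossings, with a
  strength from the flanking delta extrema), and
  *Hicratio* (within-window vs cross-window contacts at matched distances in
  `d = 400 kb` flanks; boundaries at local maxima, strengths filtered to
  (1, 12] for statistics).
* **Pileups** — aggregate maps around boundaries (±500 kb, 30 kb diagonal
  exclusion, strength > 1) and loop anchors (BEDPE input), with log2-ratio
  and subtraction composites.
* **Comparisons** — greedy boundary matching between conditions and
  one-sided Wilcoxon signed-rank tests (continuity correction; exact below
  n = 20) on matched strength changes.
* **Synthetic data** — a generator that plants known structure
  (power-law decay `s^-α`, compartment plaid, TAD boundaries of controllable
  permeability *p*, loops, bin biases, translocations) and samples Poisson
  counts, so every stage above is validated by parameter recovery.

## Worked example

Simulate a control genome with 11 TAD boundaries of permeability 0.4, and an
"irradiated" condition in which every permeability is multiplied by 0.625
(lower permeability = stronger boundaries), then run the boundary-strength
comparison:

```r
library(irhic)

spec <- genome_spec(
  chrom_lengths = c(chr1 = 12e6), resolution = 40000,
  decay_exponent = 1, decay_floor = 1e-4,
  tad_boundaries = list(chr1 = seq(1e6, 11e6, by = 1e6)),
  boundary_permeability = 0.4, within_tad_enrichment = 1.5)
irradiated <- perturb_boundaries(spec, 0.625)

control <- scale_to_total(ice_balance(sample_counts(expected_matrix(spec), 5e6, seed = 1)))
treated <- scale_to_total(ice_balance(sample_counts(expected_matrix(irradiated), 5e6, seed = 2)))

b_ctl <- call_boundaries_insulation(insulation_track(control))
b_trt <- call_boundaries_insulation(insulation_track(treated))
pairs <- match_boundaries(b_ctl, b_trt)
boundary_strength_test(pairs, direction = "treated_greater")
#> boundary strength comparison (wilcoxon signed-rank)
#>   n matched: 11  zero differences dropped: 0
#>   V = 66  one-sided p ( treated_greater ) = 0.00048828
strength_change_summary(pairs)
#> strength changes (treated - control), n = 11
#>   median 0.8653  IQR [ 0.8369 , 0.8809 ]  whiskers [ 0.8102 , 0.947 ]
```

All 11 boundaries are recovered at their planted positions (±1 bin), every
matched boundary gets stronger in the treated condition, and the one-sided
signed-rank test detects the planted strengthening with the smallest p-value
an 11-pair exact test can produce (1/2¹¹ ≈ 4.9 × 10⁻⁴: all differences
positive).

The full pipeline (balance → scale → reproducibility → ratio maps → scaling
curves → compartments/saddle → both boundary callers → pileups → matched
comparison) runs from a YAML config:

```r
cfg <- make_demo("demo", seed = 7)   # synthetic control/treated bundle + config
run_pipeline(cfg)                    # writes artifacts + summary.json under demo/results/
```

A thin command-line wrapper is installed at `inst/cli/irhic`
(`irhic demo`, `irhic run config.yaml`, `irhic balance`, `irhic insulation`,
...).

## Dense-tsv matrix format

Matrices are exchanged as plain text: a `#` header (`resolution`, `assembly`,
`balanced`, `bins`), a bin table (`chrom start end valid`, 0-based
half-open), a `# matrix` marker, then the dense square matrix row by row
(`NA` for masked bins). See `write_matrix()` / `read_matrix()`.
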