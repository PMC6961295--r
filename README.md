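# rfhic

Restriction-fragment-resolution interaction-frequency estimation for Hi-C.

Hi-C counts ligation events between pairs of restriction fragments (RFs),
but at its native fragment resolution the count matrix is so sparse — under
0.001 read pairs per intrachromosomal entry for a 4-cutter digest at 10⁹
total pairs — that individual counts are useless as estimates of the
underlying interaction frequency (IF). The usual fix, fixed-width binning,
throws away exactly the resolution the digest provides. `rfhic` estimates
the complete RF×RF IF matrix from the sparse counts and provides the
fragment-level structural callers built on top of it.

## What is inside

Given a fragment map (BED) and a sparse upper-triangle count matrix
(`chrom<TAB>i<TAB>j<TAB>count`, 0-based, i ≤ j), the package provides:

* **Fragment-bias normalisation** — one multiplicative bias per fragment,
  `bias_i = rowSum_i / total · n_frag` (mean one by construction), with
  `nRC(i,j) = RC(i,j)/(bias_i · bias_j)` and its exact inverse.
* **Four IF estimators** of increasing sophistication:
  * fixed binning over runs of consecutive fragments;
  * Gaussian kernel smoothing with a fixed bandwidth `h` (truncated at ±3h,
    edge-renormalised);
  * adaptive-bandwidth smoothing, where each cell uses the smallest `h`
    whose window holds ≥ `MinimumCount` (default 100) raw reads, found in
    constant time from a prefix-sum matrix;
  * a Markov-random-field estimator: log-normal prior centred on the
    boundary-respecting **median** of the eight neighbours with variance
    `max(α·log(MedNeigh), 0.01)` (α = 0.2), Poisson (or negative-binomial)
    count likelihood `RC ~ Pois(IF · bias_i · bias_j)`, optimised by
    iterated conditional modes over multiplicative factor grids, with sharp
    transitions pre-detected by a scaled two-sample Kolmogorov–Smirnov scan
    (threshold 1.5) and excluded from the neighbourhoods.
* **Domain-boundary calling** via the scale-normalised directionality index
  `DI′ = sign(B−A)·[(A−E)²/E² + (B−E)²/E²]` over ±500 kb windows, boundaries
  being strict local extrema of DI′ in a 21-fragment window.
* **Loop calling** with a donut filter on the distance-normalised matrix
  (`score = P/max(D, H, V, BL)` over bp-defined regions at the (30, 60) kb
  and (50, 100) kb scales), greedy 20-kb elimination, and per-distance-bin
  gamma FDRs calibrated on a diagonal-wise permuted matrix.
* **A seeded synthetic-data generator and cross-validation harness** —
  power-law decay, nested domains, tapered loops, log-normal biases,
  Poisson read sampling, exact binomial-thinning splits — so every stage is
  testable without external data.
* A command-line front end (`inst/cli/rfhic`) wrapping the same functions:
  `simulate`, `normalize`, `estimate`, `boundaries`, `loops`, `crossval`,
  `convert`, `render`.

## Worked example

Simulate a 300-fragment chromosome at ~0.5 reads per cell, hold out 20% of
the reads, and compare estimators on the held-out counts:

```r
library(rfhic)

params <- sim_params(n_fragments = 300)
truth  <- simulate_true_if(params, seed = 42)
rc     <- sample_read_counts(truth$if_true, truth$bias, params$depth, seed = 43)
rc
#> rc_matrix: 300 x 300, 44890 read pairs (full-matrix total)

sets <- split_read_counts(rc, fraction = 0.8, seed = 44)
bias <- compute_fragment_bias(sets$input)
nrc  <- normalize_counts(sets$input, bias)

fit <- estimate_mrf(sets$input, bias, nrc = nrc)
attr(fit, "sweeps")
#> [1] 14

for (est in list(fixed4 = estimate_fixed_binning(nrc, 4),
                 akde   = estimate_akde(sets$input, nrc),
                 mrf    = fit)) {
  pred <- scale_to_test(denormalize(est, bias), sets$test)
  cat(sprintf("SSE vs held-out reads: %.1f\n", sse_eval(pred, sets$test)))
}
#> SSE vs held-out reads: 5481.4   (fixed binning, 4 fragments/bin)
#> SSE vs held-out reads: 4292.0   (adaptive KDE)
#> SSE vs held-out reads: 3462.2   (MRF)
```

The sum of squared errors against the independently sampled test reads
drops by a fifth going from the adaptive KDE to the MRF estimate, and by a
third relative to binning — the same ordering the cross-validation benchmark
below reproduces over ten seeds.

Domain boundaries on a three-domain chromosome land exactly on the planted
junctions (paired +/− extrema flank each junction):

```r
p <- sim_params(n_fragments = 400, size_shape = 200, n_tads = 3,
                tad_factor = 4, n_subtads = 0, n_loops = 0)
truth <- simulate_true_if(p, seed = 8)
prof  <- directionality_profile(truth$if_true, truth$fmap, delta = 1e5)
call_domain_boundaries(prof, truth$fmap, window = 21,
                       exclusion_bp = 1e5, top_k = 4)
#>  fragment   di_prime sign
#>       121 -0.7670198   -1
#>       122  0.7353994    1
#>       193  0.7021504    1
#>       192 -0.6906446   -1
truth$tad_boundaries
#> [1] 122 193
```

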