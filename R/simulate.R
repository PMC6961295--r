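#' Parameters for the synthetic Hi-C generator
#'
#' Defines a synthetic chromosome with known ground truth: fragment sizes
#' drawn from a gamma distribution (shape 1, i.e. exponential, matches the
#' spacing of a random digestion), power-law distance decay
#' `(d + 1)^(-gamma)` on bp distance, nested block structure (domains and
#' subdomains with elevated within-block contact), point loops enriched over
#' the local background, log-normal multiplicative fragment biases rescaled
#' to mean 1, and a total read depth for Poisson sampling.
#'
#' @param n_fragments Number of restriction fragments (default 500).
#' @param size_mean Mean fragment size in bp (default 3700, a six-cutter
#'   average).
#' @param size_shape Gamma shape of the size distribution (default 1).
#' @param size_min Minimum fragment size in bp (default 50).
#' @param decay_gamma Distance-decay exponent (default 1).
#' @param baseline Baseline IF at distance 0 (default 1).
#' @param n_tads,tad_factor Number of domains and within-domain
#'   multiplicative contrast (defaults 4 and 3).
#' @param n_subtads,subtad_factor Number of nested subdomains and their
#'   additional contrast (defaults 12 and 1.8).
#' @param n_loops,loop_factor,loop_radius_bp Number of point loops, their
#'   fold enrichment and half-width in bp (defaults 5, 10, 15000).
#' @param bias_sdlog Log-normal sd of the fragment biases (default 0.3).
#' @param depth Total read pairs to sample; the default gives a mean of
#'   about 0.5 reads per matrix cell (`0.5 * n_fragments^2`).
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_fragments = 500, size_mean = 3700, size_shape = 1,
                       size_min = 50, decay_gamma = 1, baseline = 1,
                       n_tads = 4, tad_factor = 3, n_subtads = 12,
                       subtad_factor = 1.8, n_loops = 5, loop_factor = 10,
                       loop_radius_bp = 15000, bias_sdlog = 0.3,
                       depth = NULL) {
  if (n_fragments < 10) stop("n_fragments must be >= 10")
  if (size_mean <= size_min) stop("size_mean must exceed size_min")
  if (decay_gamma < 0 || baseline <= 0) stop("decay/baseline must be positive")
  if (tad_factor < 1 || subtad_factor < 1 || loop_factor < 1) {
    stop("contrast factors must be >= 1")
  }
  if (is.null(depth)) depth <- round(0.5 * n_fragments^2)
  structure(list(n_fragments = n_fragments, size_mean = size_mean,
                 size_shape = size_shape, size_min = size_min,
                 decay_gamma = decay_gamma, baseline = baseline,
                 n_tads = n_tads, tad_factor = tad_factor,
                 n_subtads = n_subtads, subtad_factor = subtad_factor,
                 n_loops = n_loops, loop_factor = loop_factor,
                 loop_radius_bp = loop_radius_bp, bias_sdlog = bias_sdlog,
                 depth = depth), class = "sim_params")
}

#' Simulate a ground-truth interaction-frequency matrix
#'
#' Builds the latent IF matrix `IF_true(i,j) = baseline * (d_ij + 1)^(-gamma)
#' * tadFactor(i,j) * subtadFactor(i,j) * loopFactor(i,j)` on a synthetic
#' fragment map, together with mean-one log-normal fragment biases. All
#' randomness is driven by `seed`; identical parameters and seed give
#' bit-identical output.
#'
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @return List of class `sim_truth` with elements `fmap` ([fragment_map()]),
#'   `if_true` ([if_matrix()], normalized), `bias` (numeric, mean 1),
#'   `tad_boundaries` (fragment indices of the domain junctions),
#'   `loops` (data.frame of planted anchor pairs), `params`.
#' @export
simulate_true_if <- function(params = sim_params(), seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  n <- params$n_fragments
  sizes <- pmax(round(stats::rgamma(n, shape = params$size_shape,
                                    scale = params$size_mean / params$size_shape)),
                params$size_min)
  end <- cumsum(sizes)
  start <- c(0, end[-n])
  fmap <- fragment_map("chrS", start, end)
  pos <- frag_pos(fmap)

  # power-law decay on genomic distance measured in kb: contact probability
  # saturates below the kb scale, so tiny fragments do not produce
  # pathological near-diagonal spikes
  d <- abs(outer(pos, pos, `-`)) / 1000
  vals <- params$baseline * (d + 1)^(-params$decay_gamma)

  # nested block structure: domain junctions, then subdomain junctions
  tad_b <- if (params$n_tads > 1) {
    sort(sample(seq(20L, n - 20L), params$n_tads - 1L))
  } else integer()
  tad_of <- findInterval(seq_len(n), c(0L, tad_b))
  same_tad <- outer(tad_of, tad_of, `==`)
  vals[same_tad] <- vals[same_tad] * params$tad_factor
  if (params$n_subtads > 0) {
    sub_b <- sort(sample(setdiff(seq(10L, n - 10L), tad_b),
                         params$n_subtads))
    sub_of <- findInterval(seq_len(n), c(0L, sub_b))
    same_sub <- outer(sub_of, sub_of, `==`) & same_tad
    vals[same_sub] <- vals[same_sub] * params$subtad_factor
  }

  loops <- data.frame(anchor1 = integer(), anchor2 = integer())
  if (params$n_loops > 0) {
    min_sep <- max(20L, round(1e5 / params$size_mean))  # >= ~100 kb apart
    a1 <- sample(seq_len(n - min_sep), params$n_loops)
    a2 <- vapply(a1, function(a) {
      hi <- min(n, a + round(5e5 / params$size_mean))
      sample(seq(a + min_sep, hi), 1L)
    }, 0L)
    loops <- data.frame(anchor1 = a1, anchor2 = a2)
    r <- params$loop_radius_bp
    for (k in seq_len(nrow(loops))) {
      ri <- which(abs(pos - pos[loops$anchor1[k]]) <= r)
      ci <- which(abs(pos - pos[loops$anchor2[k]]) <= r)
      # bilinear taper: full fold enrichment at the anchor pair, fading to
      # the background at the loop radius, so the anchor is a genuine peak
      wi <- 1 - abs(pos[ri] - pos[loops$anchor1[k]]) / r
      wj <- 1 - abs(pos[ci] - pos[loops$anchor2[k]]) / r
      mult <- 1 + (params$loop_factor - 1) * outer(wi, wj)
      vals[ri, ci] <- vals[ri, ci] * mult
      vals[ci, ri] <- vals[ci, ri] * t(mult)
    }
  }

  bias <- stats::rlnorm(n, meanlog = 0, sdlog = params$bias_sdlog)
  bias <- bias / mean(bias)

  structure(list(fmap = fmap,
                 if_true = if_matrix(vals, normalized = TRUE),
                 bias = bias, tad_boundaries = tad_b, loops = loops,
                 params = params),
            class = "sim_truth")
}

#' Sample a read-count matrix from a ground-truth IF matrix
#'
#' Each unordered fragment pair receives an independent Poisson count with
#' rate proportional to `IF_true(i,j) * bias_i * bias_j`, scaled so the
#' expected full-matrix total (off-diagonal cells counted once per
#' orientation) equals `depth`.
#'
#' @param if_true Ground-truth [if_matrix()].
#' @param bias Fragment bias vector (mean 1).
#' @param depth Expected total read pairs.
#' @param seed Integer seed.
#' @return An [rc_matrix()].
#' @export
sample_read_counts <- function(if_true, bias, depth, seed = 1L) {
  if (depth < 0) stop("depth must be >= 0")
  n <- nrow(if_true)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  s <- unclass(if_true) * outer(bias, bias)
  total <- sum(s)
  lam <- depth * s / total
  # each unordered pair is sampled once and mirrored; the full-matrix total
  # (off-diagonal cells counted once per orientation) then has expectation
  # exactly depth
  ut <- upper.tri(lam)
  rc <- matrix(0, n, n)
  rc[ut] <- stats::rpois(sum(ut), lam[ut])
  rc <- rc + t(rc)
  diag(rc) <- stats::rpois(n, diag(lam))
  rc_matrix(rc)
}

#' Split a read-count matrix by binomial thinning
#'
#' Assigns each of the `RC(i,j)` read pairs of every cell independently to
#' the input set with probability `fraction`; the remainder forms the test
#' set. The two parts sum back to the original matrix cell-wise, exactly.
#'
#' @param rc An [rc_matrix()].
#' @param fraction Probability a read pair lands in the input set
#'   (default 0.8).
#' @param seed Integer seed.
#' @return List with elements `input` and `test`, both [rc_matrix()].
#' @export
split_read_counts <- function(rc, fraction = 0.8, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- nrow(rc)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  m <- unclass(rc)
  keep <- matrix(0, n, n)
  ut <- upper.tri(m, diag = TRUE)
  keep[ut] <- stats::rbinom(sum(ut), m[ut], fraction)
  keep[lower.tri(keep)] <- t(keep)[lower.tri(keep)]
  storage.mode(keep) <- "integer"
  rest <- m - keep
  storage.mode(rest) <- "integer"
  list(input = rc_matrix(keep), test = rc_matrix(rest))
}

#' Downsample a read-count matrix
#'
#' Binomial thinning to a fraction of the reads (the input half of
#' [split_read_counts()]).
#' @param rc An [rc_matrix()].
#' @param fraction Retained fraction in (0, 1]; 1 returns `rc` unchanged.
#' @param seed Integer seed.
#' @export
downsample_read_counts <- function(rc, fraction, seed = 1L) {
  if (fraction == 1) return(rc)
  split_read_counts(rc, fraction, seed)$input
}

#' Sum of squared errors between a prediction and held-out counts
#'
#' `sum over i < j of (IF_pred(i,j) - RC_test(i,j))^2` over unmasked cells.
#' The prediction should first be scaled to the test set's total
#' (see [scale_to_test()]).
#'
#' @param if_pred Predicted [if_matrix()] (non-normalized scale).
#' @param rc_test Held-out [rc_matrix()].
#' @return Scalar SSE.
#' @export
sse_eval <- function(if_pred, rc_test) {
  if (!all(dim(if_pred) == dim(rc_test))) stop("shape mismatch")
  mask <- if_mask(if_pred)
  use <- upper.tri(if_pred) & !cell_mask(mask)
  sum((unclass(if_pred)[use] - unclass(rc_test)[use])^2)
}

#' Scale a prediction to a test set's total read pairs
#'
#' Multiplies the prediction so its unmasked upper-triangle sum equals the
#' test matrix's sum over the same cells.
#' @param if_pred Predicted [if_matrix()].
#' @param rc_test Held-out [rc_matrix()].
#' @return Rescaled [if_matrix()].
#' @export
scale_to_test <- function(if_pred, rc_test) {
  mask <- if_mask(if_pred)
  use <- upper.tri(if_pred) & !cell_mask(mask)
  ps <- sum(unclass(if_pred)[use])
  ts <- sum(unclass(rc_test)[use])
  if (ps <= 0) return(if_pred)
  if_matrix(unclass(if_pred) * ts / ps, normalized = is_normalized(if_pred),
            mask = mask)
}
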