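#' Detect sharp transition boundaries between adjacent rows/columns
#'
#' Scans the normalised count matrix for the sharp horizontal or vertical
#' steps characteristic of domain boundaries. For every adjacent row pair
#' (i, i+1) and column segment of `segment_len` cells, a two-sample
#' Kolmogorov-Smirnov statistic is computed between the two rows' values over
#' the segment and scaled by `sqrt(n*m/(n+m))` so a fixed threshold above 1
#' is meaningful. Boundaries are accepted greedily from the largest statistic
#' down, skipping candidates that overlap an already-accepted boundary of the
#' same orientation at the same row/column interface, until the statistic
#' falls below `ks_threshold`. Vertical boundaries are the symmetric scan of
#' the columns.
#'
#' @param nrc Normalised count matrix ([if_matrix()]).
#' @param ks_threshold Acceptance threshold on the scaled statistic
#'   (default 1.5).
#' @param segment_len Segment length in cells (default 8).
#' @return Data frame with columns `orientation` ("horizontal"/"vertical"),
#'   `index` (row of the upper row / column of the left column, 1-based),
#'   `start`, `end` (segment extent, 1-based inclusive), `statistic`; class
#'   `transition_boundaries`.
#' @export
detect_transition_boundaries <- function(nrc, ks_threshold = 1.5,
                                         segment_len = 8) {
  if (segment_len < 2) stop("segment_len must be >= 2")
  segment_len <- as.integer(segment_len)
  vals <- unclass(nrc)
  pick <- function(stats) {
    # greedy non-overlapping selection per interface
    cand <- which(stats >= ks_threshold, arr.ind = TRUE)
    if (nrow(cand) == 0L) {
      return(data.frame(index = integer(), start = integer(), end = integer(),
                        statistic = numeric()))
    }
    st <- stats[cand]
    o <- order(-st)
    cand <- cand[o, , drop = FALSE]
    st <- st[o]
    taken <- vector("list", nrow(stats))
    keep <- logical(length(st))
    for (k in seq_along(st)) {
      i <- cand[k, 1L]
      j1 <- cand[k, 2L]
      j2 <- j1 + segment_len - 1L
      iv <- taken[[i]]
      ok <- TRUE
      if (!is.null(iv)) {
        ok <- all(j2 < iv[, 1L] | j1 > iv[, 2L])
      }
      if (ok) {
        taken[[i]] <- rbind(iv, c(j1, j2))
        keep[k] <- TRUE
      }
    }
    acc <- data.frame(index = cand[keep, 1L], start = cand[keep, 2L],
                      end = cand[keep, 2L] + segment_len - 1L,
                      statistic = st[keep])
    # merge touching segments on the same interface into one boundary
    if (nrow(acc) > 1L) {
      acc <- acc[order(acc$index, acc$start), , drop = FALSE]
      merged <- acc[1L, , drop = FALSE]
      for (k in 2:nrow(acc)) {
        last <- nrow(merged)
        if (acc$index[k] == merged$index[last] &&
            acc$start[k] <= merged$end[last] + 1L) {
          merged$end[last] <- max(merged$end[last], acc$end[k])
          merged$statistic[last] <- max(merged$statistic[last],
                                        acc$statistic[k])
        } else {
          merged <- rbind(merged, acc[k, , drop = FALSE])
        }
      }
      acc <- merged
    }
    acc
  }
  hstats <- cpp_ks_segment_stats(vals, segment_len)
  vstats <- cpp_ks_segment_stats(t(vals), segment_len)
  hb <- pick(hstats)
  vb <- pick(vstats)
  out <- rbind(
    if (nrow(hb)) cbind(orientation = "horizontal", hb) else NULL,
    if (nrow(vb)) cbind(orientation = "vertical", vb) else NULL
  )
  if (is.null(out)) {
    out <- data.frame(orientation = character(), index = integer(),
                      start = integer(), end = integer(), statistic = numeric())
  }
  out <- out[order(-out$statistic), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("transition_boundaries", "data.frame")
  out
}

# expand a boundary table into the two logical interface masks used by ICM:
# hb[i, c] marks a boundary between rows i and i+1 at column c; vb[r, j]
# between columns j and j+1 at row r
boundary_masks <- function(boundaries, n) {
  hb <- matrix(FALSE, max(n - 1L, 1L), n)
  vb <- matrix(FALSE, n, max(n - 1L, 1L))
  if (!is.null(boundaries) && nrow(boundaries) > 0L) {
    for (k in seq_len(nrow(boundaries))) {
      b <- boundaries[k, ]
      cols <- b$start:b$end
      if (b$orientation == "horizontal") {
        hb[b$index, cols] <- TRUE
      } else {
        vb[cols, b$index] <- TRUE
      }
    }
  }
  list(hb = hb, vb = vb)
}

#' Parameters for the Markov-random-field estimator
#'
#' @param alpha Prior-strength coefficient: the log-normal prior variance is
#'   `max(alpha * log(MedNeigh), 0.01)` (default 0.2).
#' @param likelihood `"poisson"` or `"nb"` (negative binomial).
#' @param nb_variance_multiplier Variance multiplier `v >= 1` for the
#'   negative-binomial likelihood; `v = 1` is the Poisson limit.
#' @param grid_factors Multiplicative update candidates; must contain 1.
#'   Default nine geometric factors `2^(k/4)`, k = -4..4 (0.5x to 2x).
#' @param tol Relative joint-log-probability change declaring convergence
#'   (default 1e-4).
#' @param max_iter Sweep cap (default 50).
#' @param ks_threshold Transition-boundary threshold (default 1.5).
#' @param segment_len Boundary segment length in cells (default 8).
#' @param sweep_order `"raster"` or `"random"` cell visiting order.
#' @return List of class `mrf_params`.
#' @export
mrf_params <- function(alpha = 0.2, likelihood = c("poisson", "nb"),
                       nb_variance_multiplier = 1,
                       grid_factors = 2^(seq(-4, 4) / 4), tol = 1e-4,
                       max_iter = 50, ks_threshold = 1.5, segment_len = 8,
                       sweep_order = c("raster", "random")) {
  likelihood <- match.arg(likelihood)
  if (alpha <= 0) stop("alpha must be > 0")
  if (tol <= 0) stop("tol must be > 0")
  if (!any(abs(grid_factors - 1) < 1e-12)) stop("grid_factors must contain 1")
  if (likelihood == "nb" && nb_variance_multiplier < 1) {
    stop("nb_variance_multiplier must be >= 1")
  }
  structure(list(alpha = alpha, likelihood = likelihood,
                 nb_variance_multiplier = nb_variance_multiplier,
                 grid_factors = grid_factors, tol = tol, max_iter = max_iter,
                 ks_threshold = ks_threshold, segment_len = segment_len,
                 sweep_order = match.arg(sweep_order)),
            class = "mrf_params")
}

# variance multiplier actually passed to the likelihood (<= 1 selects Poisson)
mrf_vmult <- function(params) {
  if (params$likelihood == "poisson") 1 else params$nb_variance_multiplier
}

#' Local MRF objective at one cell
#'
#' The joint-log-probability terms that depend on the value of the symmetric
#' cell pair {(i,j), (j,i)}: both cells' log-normal neighbourhood priors and
#' count likelihoods, plus the priors of every neighbour of either cell
#' (whose neighbourhood medians see the candidate value). The prior of a cell
#' with no usable neighbour is skipped.
#'
#' @param ifm Current estimate ([if_matrix()], normalized scale).
#' @param rc Raw [rc_matrix()].
#' @param bias Vector from [compute_fragment_bias()].
#' @param i,j Cell (1-based).
#' @param value Candidate IF value for the cell.
#' @param params [mrf_params()].
#' @param boundaries Optional [detect_transition_boundaries()] table.
#' @return Scalar log-probability contribution.
#' @export
mrf_local_objective <- function(ifm, rc, bias, i, j, value, params = mrf_params(),
                                boundaries = NULL) {
  n <- nrow(ifm)
  bm <- boundary_masks(boundaries, n)
  mask <- if_mask(ifm) | bias_mask(bias)
  if (mask[i] || mask[j]) stop("cell (", i, ",", j, ") is masked")
  cpp_mrf_local_objective(unclass(ifm), unclass(rc), as.numeric(bias), mask,
                          bm$hb, bm$vb, i - 1L, j - 1L, value, params$alpha,
                          mrf_vmult(params))
}

#' Joint log probability of an MRF configuration
#'
#' Sum over unmasked cells of the log-normal neighbourhood prior and the
#' count likelihood. Used to monitor ICM convergence.
#'
#' @inheritParams mrf_local_objective
#' @export
mrf_joint_logp <- function(ifm, rc, bias, params = mrf_params(),
                           boundaries = NULL) {
  bm <- boundary_masks(boundaries, nrow(ifm))
  mask <- if_mask(ifm) | bias_mask(bias)
  cpp_mrf_joint_logp(unclass(ifm), unclass(rc), as.numeric(bias), mask,
                     bm$hb, bm$vb, params$alpha, mrf_vmult(params))
}

#' Markov-random-field interaction-frequency estimate
#'
#' Maximum a posteriori estimate of the latent IF matrix under a log-normal
#' neighbourhood prior (centred on the boundary-respecting median of the
#' eight neighbours, variance `alpha * log(MedNeigh)` floored at 0.01) and a
#' Poisson (or negative-binomial) read-count likelihood with fragment biases.
#' Optimised by iterated conditional modes (ICM): each sweep revises every
#' unmasked cell by grid search over multiplicative factors of its current
#' value, which never decreases the joint log probability; sweeps stop when
#' the relative change of the joint log probability drops below `tol`.
#' Transition boundaries are detected once on the normalised counts before
#' ICM and held fixed. Cells with zero raw reads anywhere in their `h_max`
#' coverage window are left at their initialisation value and flagged.
#'
#' @param rc Raw [rc_matrix()].
#' @param bias Vector from [compute_fragment_bias()].
#' @param init Initial estimate; default (`NULL`) uses [estimate_akde()] of
#'   the bias-normalised counts.
#' @param params [mrf_params()].
#' @param nrc Normalised counts for boundary detection and default
#'   initialisation; computed from `rc` and `bias` when `NULL`.
#' @param minimum_count,h_max Passed to [estimate_akde()] for the default
#'   initialisation and to flag zero-coverage cells.
#' @param seed Seed for the randomized sweep order (only used when
#'   `params$sweep_order == "random"`).
#' @return An [if_matrix()] (normalized) with attributes `sweeps`, `logp`
#'   (joint log-probability trace, initial state first), `boundaries`, and
#'   `frozen` (logical matrix of zero-coverage cells left at initialisation).
#' @export
estimate_mrf <- function(rc, bias, init = NULL, params = mrf_params(),
                         nrc = NULL, minimum_count = 100, h_max = 64,
                         seed = 1L) {
  n <- nrow(rc)
  if (is.null(nrc)) nrc <- normalize_counts(rc, bias)
  if (is.null(init)) init <- estimate_akde(rc, nrc, minimum_count, h_max)
  mask <- if_mask(init) | bias_mask(bias)
  boundaries <- detect_transition_boundaries(nrc, params$ks_threshold,
                                             params$segment_len)
  bm <- boundary_masks(boundaries, n)
  bw <- attr(init, "bandwidth")
  uncovered <- if (!is.null(bw)) attr(bw, "uncovered") else
    attr(adaptive_bandwidth(rc, minimum_count, h_max), "uncovered")
  updatable <- !uncovered
  ord <- seq_len(n * n) - 1L
  if (params$sweep_order == "random") {
    ord <- withr_seed_sample(ord, seed)
  }
  vals <- unclass(init)
  vals[vals <= 0] <- 1e-12  # multiplicative updates need a positive start
  res <- cpp_mrf_icm(vals, unclass(rc), as.numeric(bias), mask, bm$hb, bm$vb,
                     updatable, params$grid_factors, params$alpha,
                     mrf_vmult(params), params$tol, params$max_iter, ord)
  if (res$skipped > 0) {
    warning(res$skipped, " cells had non-finite objectives and were skipped")
  }
  out <- if_matrix(res$values, normalized = TRUE, mask = mask)
  attr(out, "sweeps") <- res$sweeps
  attr(out, "logp") <- res$logp
  attr(out, "logp_final") <- res$final_logp
  attr(out, "boundaries") <- boundaries
  attr(out, "frozen") <- uncovered
  out
}

# seeded permutation that does not disturb the caller's RNG stream
withr_seed_sample <- function(x, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  sample(x)
}
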