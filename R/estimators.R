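#' Fixed-binning interaction-frequency estimate
#'
#' Pools bias-normalised counts over consecutive runs of `bin_size` fragments:
#' `IF(i,j)` is the mean nRC over the `bin(i) x bin(j)` block, with
#' `bin(i) = floor(i / bin_size)`. A trailing partial bin divides by its
#' actual cell count rather than `bin_size^2`.
#'
#' @param nrc Normalised count matrix ([if_matrix()] from
#'   [normalize_counts()]).
#' @param bin_size Number of consecutive fragments per bin (>= 1).
#' @return An [if_matrix()] (same normalisation flag and mask as the input).
#' @export
estimate_fixed_binning <- function(nrc, bin_size) {
  if (bin_size < 1) stop("bin_size must be >= 1")
  bin_size <- as.integer(bin_size)
  n <- nrow(nrc)
  if (bin_size == 1L) return(nrc)
  g <- (seq_len(n) - 1L) %/% bin_size
  vals <- unclass(nrc)
  sums <- rowsum(t(rowsum(vals, g)), g)           # bin-pair sums
  cnt <- as.numeric(table(factor(g, levels = sort(unique(g)))))
  means <- sums / outer(cnt, cnt)
  out <- means[g + 1L, g + 1L, drop = FALSE]
  if_matrix(out, normalized = is_normalized(nrc), mask = if_mask(nrc))
}

#' Fixed-bandwidth Gaussian kernel density estimate
#'
#' Smooths the normalised count matrix with a two-dimensional Gaussian kernel
#' of bandwidth `h`, truncated at +/- 3h cells. Indices outside the matrix
#' (and masked cells) are excluded from both the numerator and the
#' denominator, so edges renormalise rather than fade.
#'
#' @param nrc Normalised count matrix ([if_matrix()]).
#' @param h Integer bandwidth in cells (>= 1).
#' @return An [if_matrix()].
#' @export
estimate_kde <- function(nrc, h) {
  if (h < 1) stop("bandwidth h must be >= 1")
  mask <- if_mask(nrc)
  cm <- cell_mask(mask)
  vals <- unclass(nrc)
  vals[cm] <- 0
  ind <- matrix(1, nrow(nrc), ncol(nrc))
  ind[cm] <- 0
  out <- cpp_kde_smooth(vals, ind, as.integer(h))
  out[cm] <- 0
  out[is.na(out)] <- 0
  if_matrix(out, normalized = is_normalized(nrc), mask = mask)
}

#' Cumulative (prefix-sum) matrix of raw read counts
#'
#' `cum[i, j] = sum(rc[1:i, 1:j])`, padded with a leading row/column of
#' zeros so that any clipped rectangular window sum is four lookups.
#'
#' @param rc An [rc_matrix()].
#' @return `(n+1) x (n+1)` numeric matrix of class `cumulative_matrix`.
#' @export
build_cumulative <- function(rc) {
  n <- nrow(rc)
  cum <- matrix(0, n + 1L, n + 1L)
  cum[-1L, -1L] <- t(apply(apply(unclass(rc), 2L, cumsum), 1L, cumsum))
  structure(cum, class = c("cumulative_matrix", "matrix", "array"), n = n)
}

#' Raw-read coverage of the +/-3h window around every cell
#'
#' Inclusion-exclusion on the cumulative matrix; window edges clamp to the
#' matrix boundary.
#' @param cum A [build_cumulative()] result.
#' @param h Integer bandwidth.
#' @return n x n numeric matrix of window read counts.
#' @export
window_coverage <- function(cum, h) {
  cpp_window_coverage(unclass(cum), attr(cum, "n"), as.integer(h))
}

#' Per-cell adaptive bandwidths
#'
#' For every cell, the smallest integer bandwidth `h` such that the
#' `(6h+1)^2` window (clipped to the matrix) holds at least `minimum_count`
#' raw reads, capped at `h_max`. Coverage is counted on the raw RC matrix,
#' not the bias-normalised one.
#'
#' @param rc An [rc_matrix()].
#' @param minimum_count Read-count threshold per window (default 100).
#' @param h_max Bandwidth cap (default 64); cells that never reach
#'   `minimum_count` use `h_max`.
#' @return Integer matrix of bandwidths with attribute `uncovered` (logical
#'   matrix marking cells with zero reads even in the `h_max` window).
#' @export
adaptive_bandwidth <- function(rc, minimum_count = 100, h_max = 64) {
  if (minimum_count < 1) stop("minimum_count must be >= 1")
  cum <- build_cumulative(rc)
  h <- cpp_adaptive_bandwidth(unclass(cum), nrow(rc), minimum_count,
                              as.integer(h_max))
  uncovered <- window_coverage(cum, h_max) == 0
  structure(h, uncovered = uncovered)
}

#' Adaptive-bandwidth kernel density estimate
#'
#' Per-cell Gaussian smoothing where each cell uses the bandwidth from
#' [adaptive_bandwidth()]: dense regions keep fine resolution, sparse regions
#' borrow strength from wider windows.
#'
#' @param rc Raw [rc_matrix()] (drives the bandwidth choice).
#' @param nrc Normalised [if_matrix()] (the values being smoothed).
#' @param minimum_count Read-count threshold per window (default 100).
#' @param h_max Bandwidth cap (default 64).
#' @return An [if_matrix()] with attribute `bandwidth` (the field used).
#' @export
estimate_akde <- function(rc, nrc, minimum_count = 100, h_max = 64) {
  h <- adaptive_bandwidth(rc, minimum_count, h_max)
  mask <- if_mask(nrc)
  cm <- cell_mask(mask)
  vals <- unclass(nrc)
  vals[cm] <- 0
  ind <- matrix(1, nrow(nrc), ncol(nrc))
  ind[cm] <- 0
  n <- nrow(nrc)
  out <- matrix(0, n, n)
  for (hv in sort(unique(as.vector(h)))) {
    sel <- which(unclass(h) == hv)
    # full-matrix separable smoothing costs ~2*n^2*(6h+1) operations; the
    # per-cell window sum costs |cells|*(6h+1)^2 — take the cheaper route
    if (length(sel) * (6 * hv + 1) < 2 * n * n) {
      rows <- (sel - 1L) %% n
      cols <- (sel - 1L) %/% n
      out[sel] <- cpp_kde_at_cells(vals, ind, as.integer(hv), rows, cols)
    } else {
      sm <- cpp_kde_smooth(vals, ind, as.integer(hv))
      out[sel] <- sm[sel]
    }
  }
  out[cm] <- 0
  out[is.na(out)] <- 0
  res <- if_matrix(out, normalized = is_normalized(nrc), mask = mask)
  attr(res, "bandwidth") <- h
  res
}
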