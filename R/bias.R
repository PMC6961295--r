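#' Estimate per-fragment multiplicative biases
#'
#' Fragment size, GC content and mappability modulate how often each
#' restriction fragment is observed; their combined effect is summarised by a
#' single multiplicative bias per fragment, estimated from the marginal
#' coverage of the count matrix:
#'
#'   bias_i = rowSum_i / total * n_fragments
#'
#' with both the row sums and the grand total taken over the full symmetric
#' matrix (off-diagonal pairs contribute to both row sums). Under this
#' convention the biases of covered fragments average exactly to one.
#' Fragments whose row sum falls below `min_row_sum` get bias 0 and are
#' masked; masking keeps indices stable rather than dropping rows.
#'
#' @param rc An [rc_matrix()].
#' @param min_row_sum Minimum full-matrix row sum for a fragment to remain
#'   unmasked (default 1, i.e. only zero-coverage fragments are masked).
#' @param zero_diagonal Zero out self-ligation (diagonal) counts before
#'   computing sums (default `FALSE`).
#' @return Numeric vector of biases with attribute `mask` (logical).
#' @export
compute_fragment_bias <- function(rc, min_row_sum = 1, zero_diagonal = FALSE) {
  m <- unclass(rc)
  if (zero_diagonal) diag(m) <- 0
  total <- sum(m)
  if (total == 0) stop("no reads")
  rs <- rowSums(m)
  mask <- rs < min_row_sum
  n_unmasked <- sum(!mask)
  # restrict the total to unmasked fragments so mean-one holds after masking
  tot_um <- sum(rs[!mask])
  bias <- ifelse(mask, 0, rs / tot_um * n_unmasked)
  structure(bias, mask = mask)
}

#' Mask of a bias vector
#' @param bias Vector from [compute_fragment_bias()].
#' @export
bias_mask <- function(bias) {
  m <- attr(bias, "mask")
  if (is.null(m)) bias <= 0 else m
}

#' Bias-normalise a read-count matrix
#'
#' Divides each count by the product of its two fragment biases:
#' `nRC(i,j) = RC(i,j) / (bias_i * bias_j)`. Cells touching a masked fragment
#' are set to 0 and masked.
#'
#' @param rc An [rc_matrix()].
#' @param bias Vector from [compute_fragment_bias()].
#' @return A normalized [if_matrix()] (nRC).
#' @export
normalize_counts <- function(rc, bias) {
  mask <- bias_mask(bias)
  if (any(bias[!mask] <= 0)) stop("zero bias at unmasked fragment")
  b <- ifelse(mask, 1, bias)  # placeholder to avoid 0/0; cells zeroed below
  nrc <- unclass(rc) / outer(b, b)
  nrc[cell_mask(mask)] <- 0
  if_matrix(nrc, normalized = TRUE, mask = mask)
}

#' Restore fragment biases into a normalised IF matrix
#'
#' Inverse of [normalize_counts()] on the estimate scale:
#' `value(i,j) * bias_i * bias_j`, clearing the normalisation flag.
#'
#' @param ifm A normalized [if_matrix()].
#' @param bias Vector from [compute_fragment_bias()].
#' @return A non-normalized [if_matrix()].
#' @export
denormalize <- function(ifm, bias) {
  if (!is_normalized(ifm)) stop("matrix is already non-normalized")
  mask <- if_mask(ifm) | bias_mask(bias)
  vals <- unclass(ifm) * outer(as.numeric(bias), as.numeric(bias))
  vals[cell_mask(mask)] <- 0
  if_matrix(vals, normalized = FALSE, mask = mask)
}
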