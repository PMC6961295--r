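#' Construct a read-count matrix
#'
#' A symmetric nonnegative-integer matrix of Hi-C read-pair counts between
#' restriction-fragment pairs of one chromosome. Stored dense; the on-disk
#' format is the sparse TSV dialect (see [read_sparse_matrix()]).
#'
#' @param values An n x n matrix of nonnegative integers, or an upper-triangle
#'   specification that will be symmetrised.
#' @return Integer matrix of class `rc_matrix`.
#' @export
rc_matrix <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("read-count matrix must be square")
  if (any(values < 0)) stop("negative read count")
  if (any(values != round(values))) stop("non-integer read count")
  if (!isSymmetric(unname(values))) {
    # accept an upper-triangle specification
    low <- values[lower.tri(values)]
    if (all(low == 0)) {
      values[lower.tri(values)] <- t(values)[lower.tri(values)]
    } else {
      stop("read-count matrix is not symmetric")
    }
  }
  structure(unname(values), class = c("rc_matrix", "matrix", "array"))
}

#' Total read pairs in a count matrix
#'
#' Sum over the full symmetric matrix: off-diagonal pairs contribute twice
#' (once per orientation), diagonal entries once. This is the convention under
#' which the fragment-bias formula has exactly mean-one biases.
#' @param rc An [rc_matrix()].
#' @export
rc_total <- function(rc) sum(rc)

#' Construct an interaction-frequency matrix
#'
#' Dense real-valued symmetric estimate of the latent interaction frequency
#' between fragment pairs, with a normalisation flag (fragment biases divided
#' out or not) and a per-fragment mask of fragments excluded from estimation.
#'
#' @param values n x n numeric matrix, symmetric, nonnegative at unmasked
#'   entries.
#' @param normalized Logical; `TRUE` if fragment biases have been divided out.
#' @param mask Logical vector of length n; `TRUE` marks excluded fragments.
#' @return Numeric matrix of class `if_matrix` with attributes `normalized`
#'   and `mask`.
#' @export
if_matrix <- function(values, normalized = TRUE, mask = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("IF matrix must be square")
  n <- nrow(values)
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (length(mask) != n) stop("mask length must equal matrix dimension")
  ok <- !mask
  if (any(values[ok, ok, drop = FALSE] < 0, na.rm = TRUE)) {
    stop("negative IF at unmasked entry")
  }
  structure(unname(values), class = c("if_matrix", "matrix", "array"),
            normalized = isTRUE(normalized), mask = mask)
}

#' @export
print.if_matrix <- function(x, ...) {
  cat(sprintf("if_matrix: %d x %d, %s, %d masked fragments\n", nrow(x), ncol(x),
              if (is_normalized(x)) "normalized" else "non-normalized",
              sum(if_mask(x))))
  invisible(x)
}

#' @export
print.rc_matrix <- function(x, ...) {
  cat(sprintf("rc_matrix: %d x %d, %d read pairs (full-matrix total)\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Query the normalisation flag of an IF matrix
#' @param ifm An [if_matrix()].
#' @export
is_normalized <- function(ifm) isTRUE(attr(ifm, "normalized"))

#' Query the fragment mask of an IF matrix
#' @param ifm An [if_matrix()].
#' @export
if_mask <- function(ifm) {
  m <- attr(ifm, "mask")
  if (is.null(m)) rep(FALSE, nrow(ifm)) else m
}

# matrix of cells excluded because either fragment is masked
cell_mask <- function(mask) outer(mask, mask, `|`)
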