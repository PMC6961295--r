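#' Directionality-index profile at fragment resolution
#'
#' For each fragment i, sums the interaction frequencies to fragments within
#' `delta` bp upstream (A) and downstream (B) of its position, with
#' E = (A+B)/2, and reports both the classical directionality index
#'
#'   DI(i) = sign(B-A) * ((A-E)^2/E + (B-E)^2/E)
#'
#' and the scale-normalised variant used at fragment resolution,
#'
#'   DI'(i) = sign(B-A) * ((A-E)^2/E^2 + (B-E)^2/E^2),
#'
#' whose relative-rate terms bound it to [-2, 2] for nonnegative A, B.
#' Fragments with A + B = 0 (or masked fragments) are undefined (NA).
#'
#' @param ifm An [if_matrix()].
#' @param fmap The [fragment_map()].
#' @param delta Window span in bp on each side (default 500000).
#' @return Data frame (class `di_profile`) with columns `fragment`, `A`, `B`,
#'   `E`, `di`, `di_prime`; attribute `delta`.
#' @export
directionality_profile <- function(ifm, fmap, delta = 5e5) {
  if (delta <= 0) stop("delta must be > 0")
  n <- n_fragments(fmap)
  stopifnot(nrow(ifm) == n)
  pos <- frag_pos(fmap)
  mask <- if_mask(ifm)
  vals <- unclass(ifm)
  A <- B <- numeric(n)
  for (i in seq_len(n)) {
    up <- which(pos >= pos[i] - delta & seq_len(n) < i)
    dn <- which(pos <= pos[i] + delta & seq_len(n) > i)
    A[i] <- sum(vals[up, i])
    B[i] <- sum(vals[i, dn])
  }
  E <- (A + B) / 2
  undef <- mask | (A + B) == 0
  di <- ifelse(undef, NA_real_,
               sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E))
  dip <- ifelse(undef, NA_real_,
                sign(B - A) * ((A - E)^2 / E^2 + (B - E)^2 / E^2))
  out <- data.frame(fragment = seq_len(n), A = A, B = B, E = E,
                    di = di, di_prime = dip)
  attr(out, "delta") <- delta
  class(out) <- c("di_profile", "data.frame")
  out
}

#' Call domain boundaries from a directionality profile
#'
#' Boundaries are fragments whose DI' is a strict local maximum or minimum
#' within a centered window of `window` fragments. Fragments within
#' `exclusion_bp` of either chromosome end (low coverage near telomeres and
#' centromeres makes DI' unreliable there) are removed, the rest ranked by
#' |DI'| descending and truncated to `top_k`.
#'
#' @param prof A [directionality_profile()].
#' @param fmap The [fragment_map()].
#' @param window Odd window width in fragments (default 21, the six-cutter
#'   setting; 51 suits four-cutter digests).
#' @param top_k Maximum number of boundaries returned (default all).
#' @param exclusion_bp Exclusion zone at each chromosome end in bp
#'   (default 2e6).
#' @param mask_intervals Optional data.frame of `start`, `end` (bp) intervals
#'   to exclude additionally (e.g. centromeres).
#' @return Data frame (class `domain_boundaries`) with columns `fragment`,
#'   `di_prime`, `sign`, sorted by |DI'| descending.
#' @export
call_domain_boundaries <- function(prof, fmap, window = 21, top_k = Inf,
                                   exclusion_bp = 2e6, mask_intervals = NULL) {
  if (window %% 2 == 0) stop("window must be odd")
  if (window < 3) stop("window must be >= 3")
  n <- nrow(prof)
  x <- prof$di_prime
  half <- (window - 1L) / 2L
  is_ext <- logical(n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    others <- x[setdiff(lo:hi, i)]
    others <- others[!is.na(others)]
    if (length(others) == 0L) next
    is_ext[i] <- all(x[i] > others) || all(x[i] < others)
  }
  pos <- frag_pos(fmap)
  chrom_lo <- min(fmap$start)
  chrom_hi <- max(fmap$end)
  near_end <- pos < chrom_lo + exclusion_bp | pos > chrom_hi - exclusion_bp
  drop <- near_end
  if (!is.null(mask_intervals) && nrow(mask_intervals) > 0L) {
    for (k in seq_len(nrow(mask_intervals))) {
      drop <- drop | (pos >= mask_intervals$start[k] &
                        pos <= mask_intervals$end[k])
    }
  }
  idx <- which(is_ext & !drop)
  idx <- idx[order(-abs(x[idx]))]
  if (is.finite(top_k)) idx <- head(idx, top_k)
  out <- data.frame(fragment = idx, di_prime = x[idx],
                    sign = sign(x[idx]))
  class(out) <- c("domain_boundaries", "data.frame")
  out
}
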