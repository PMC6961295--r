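#' Distance-normalise an interaction-frequency matrix
#'
#' Divides every cell by the mean IF of its genomic-distance stratum, where
#' the stratum of cell (i, j) is `floor((pos(j) - pos(i)) / stratum_bp)`.
#' The result (IFnorm) has expected value 1 at every distance, so point
#' enrichments stand out against the distance decay. Strata with no unmasked
#' cells, or zero mean, are undefined (NA).
#'
#' @param ifm An [if_matrix()].
#' @param fmap The [fragment_map()].
#' @param stratum_bp Stratum width in bp (default 10000).
#' @param min_stratum_cells Strata with fewer unmasked cells than this are
#'   undefined (default 30): at the extreme distances of a chromosome a
#'   stratum holds only a handful of cells and its mean is too unstable to
#'   normalise against.
#' @return An [if_matrix()] of IFnorm values (NA at undefined cells).
#' @export
distance_normalize <- function(ifm, fmap, stratum_bp = 1e4,
                               min_stratum_cells = 30) {
  if (stratum_bp <= 0) stop("stratum_bp must be > 0")
  n <- n_fragments(fmap)
  stopifnot(nrow(ifm) == n)
  pos <- frag_pos(fmap)
  strat <- floor(abs(outer(pos, pos, `-`)) / stratum_bp)
  mask <- if_mask(ifm)
  cm <- cell_mask(mask)
  vals <- unclass(ifm)
  f <- factor(strat)
  use <- !cm
  fu <- factor(strat[use], levels = levels(f))
  means <- tapply(vals[use], fu, mean)
  cnt <- table(fu)
  means[cnt < min_stratum_cells] <- NA_real_
  mvec <- as.numeric(means)[as.integer(f)]
  out <- matrix(vals / mvec, n, n)
  out[cm] <- NA_real_
  out[!is.finite(out)] <- NA_real_
  if_matrix(out, normalized = is_normalized(ifm), mask = mask)
}

# rectangular block sums from a 0-padded prefix matrix, vectorised over
# equally-shaped index matrices; empty blocks (r1 > r2 or c1 > c2) give 0
block_sum <- function(pref, r1, r2, c1, c2) {
  np <- nrow(pref)
  empty <- r1 > r2 | c1 > c2
  r1c <- pmax(pmin(r1, np - 1L), 1L); r2c <- pmax(pmin(r2, np - 1L), 1L)
  c1c <- pmax(pmin(c1, np - 1L), 1L); c2c <- pmax(pmin(c2, np - 1L), 1L)
  s <- pref[cbind(as.vector(r2c + 1L), as.vector(c2c + 1L))] -
    pref[cbind(as.vector(r1c), as.vector(c2c + 1L))] -
    pref[cbind(as.vector(r2c + 1L), as.vector(c1c))] +
    pref[cbind(as.vector(r1c), as.vector(c1c))]
  s[as.vector(empty)] <- 0
  matrix(s, nrow(r1), ncol(r1))
}

#' Donut-filter peak scores for every cell
#'
#' For each cell (i, j), compares the mean IFnorm of the peak square (the
#' fragments whose positions fall within +/- `p` bp of `pos(i)` and `pos(j)`)
#' to the means of four local-background regions inside the +/- `w` bp
#' window: the donut D (the window minus the peak rows/columns), the
#' horizontal flanks H (peak rows, window columns left and right of the
#' peak), the vertical flanks V, and the bottom-left block BL (rows below the
#' peak, columns left of the window... i.e. between the peak and the
#' diagonal). The score is `P / max(D, H, V, BL)`. Because regions are
#' defined in bp through fragment positions, the number of cells per region
#' varies with local fragment sizes. Cells with any empty background region
#' are undefined (NA).
#'
#' @param ifnorm Distance-normalised matrix from [distance_normalize()].
#' @param fmap The [fragment_map()].
#' @param p Peak half-width in bp.
#' @param w Window half-width in bp (> p).
#' @return n x n numeric matrix of scores (NA where undefined), with
#'   attribute `peak_mean` (the matrix of P values).
#' @export
score_candidate_peaks <- function(ifnorm, fmap, p, w) {
  if (p >= w) stop("p must be < w")
  n <- n_fragments(fmap)
  pos <- frag_pos(fmap)
  vals <- unclass(ifnorm)
  ok <- is.finite(vals)
  sv <- ifelse(ok, vals, 0)
  # prefix sums of values and of defined-cell counts
  pref_v <- matrix(0, n + 1L, n + 1L)
  pref_v[-1L, -1L] <- t(apply(apply(sv, 2L, cumsum), 1L, cumsum))
  pref_c <- matrix(0, n + 1L, n + 1L)
  pref_c[-1L, -1L] <- t(apply(apply(ok + 0, 2L, cumsum), 1L, cumsum))

  rng <- function(half) {
    lo <- findInterval(pos - half, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + half, pos)
    list(lo = lo, hi = hi)
  }
  rp <- rng(p); rw <- rng(w)
  # index matrices: rows indexed by i, columns by j
  ones <- rep(1L, n)
  RPL <- outer(rp$lo, ones); RPH <- outer(rp$hi, ones)
  RWL <- outer(rw$lo, ones); RWH <- outer(rw$hi, ones)
  CPL <- outer(ones, rp$lo); CPH <- outer(ones, rp$hi)
  CWL <- outer(ones, rw$lo); CWH <- outer(ones, rw$hi)

  reg <- function(pref) {
    W <- block_sum(pref, RWL, RWH, CWL, CWH)
    P <- block_sum(pref, RPL, RPH, CPL, CPH)
    RB <- block_sum(pref, RPL, RPH, CWL, CWH)
    CB <- block_sum(pref, RWL, RWH, CPL, CPH)
    list(P = P, D = W - RB - CB + P, H = RB - P, V = CB - P,
         BL = block_sum(pref, RPH + 1L, RWH, CWL, CPL - 1L))
  }
  v <- reg(pref_v)
  c_ <- reg(pref_c)
  mean_of <- function(nm) {
    m <- v[[nm]] / c_[[nm]]
    m[c_[[nm]] <= 0] <- NA_real_
    m
  }
  Pm <- mean_of("P"); Dm <- mean_of("D"); Hm <- mean_of("H")
  Vm <- mean_of("V"); BLm <- mean_of("BL")
  denom <- pmax(Dm, Hm, Vm, BLm)
  score <- Pm / denom
  score[!is.finite(score)] <- NA_real_
  score[is.na(Dm) | is.na(Hm) | is.na(Vm) | is.na(BLm)] <- NA_real_
  attr(score, "peak_mean") <- Pm
  score
}

# diagonal-wise permutation of a symmetric matrix: values are shuffled within
# each index diagonal, preserving fragment distance structure
permute_diagonalwise <- function(vals, seed) {
  n <- nrow(vals)
  out <- vals
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  for (d in 0:(n - 1L)) {
    i <- seq_len(n - d)
    j <- i + d
    idx <- cbind(i, j)
    perm <- if (length(i) > 1L) sample(length(i)) else 1L
    out[idx] <- vals[idx[perm, , drop = FALSE]]
    out[idx[, 2:1, drop = FALSE]] <- out[idx]
  }
  out
}

# gamma upper-tail FDR of observed scores against permuted-matrix null
# scores, stratified by genomic-distance bins; sparse bins are widened until
# they hold at least min_null null scores
gamma_fdr <- function(score, dist_bin, null_score, null_bin, min_null = 30) {
  fdr <- rep(NA_real_, length(score))
  for (b in unique(dist_bin)) {
    sel <- dist_bin == b
    width <- 0
    repeat {
      ns <- null_score[null_bin >= b - width & null_bin <= b + width]
      ns <- ns[is.finite(ns)]
      if (length(ns) >= min_null || width > max(null_bin, na.rm = TRUE)) break
      width <- width + 1
    }
    if (length(ns) < 2L) next  # FDR undefined for this bin
    m <- mean(ns)
    v <- stats::var(ns)
    if (!is.finite(v) || m <= 0 || sqrt(v) < 0.01 * m) {
      # (near-)degenerate null, e.g. a noise-free far field: a gamma tail
      # would declare meaninglessly small excursions significant, so use the
      # add-one empirical tail instead
      fdr[sel] <- vapply(score[sel],
                         function(s) (1 + sum(ns >= s)) / (1 + length(ns)), 0)
    } else {
      shape <- m^2 / v
      rate <- m / v
      fdr[sel] <- stats::pgamma(score[sel], shape = shape, rate = rate,
                                lower.tail = FALSE)
    }
  }
  fdr
}

#' Call chromatin loops with the donut filter
#'
#' Scores every cell at each (p, w) scale with [score_candidate_peaks()],
#' keeps cells with score >= `min_score`, sets each candidate's
#' representative fragment pair to the argmax of IFnorm inside its peak
#' square, and greedily eliminates candidates lying within `min_dist` bp
#' (Chebyshev distance in the (pos(i), pos(j)) plane) of a higher-scoring
#' retained candidate (ties broken by smaller genomic distance, then smaller
#' indices). A false discovery rate is attached to each call by rerunning
#' the scoring on a diagonal-wise permuted matrix (fragment distances
#' preserved), fitting a gamma distribution (method of moments) to the null
#' scores in each 10-kb distance bin, and taking the upper-tail probability
#' of the observed score. Calls from all scales are combined and sorted by
#' FDR.
#'
#' @param ifm An [if_matrix()] (typically an MRF or AKDE estimate).
#' @param fmap The [fragment_map()].
#' @param scales List of `c(p, w)` pairs in bp; defaults to the two scales
#'   (30 kb, 60 kb) and (50 kb, 100 kb).
#' @param min_score Candidate threshold on the donut score (default 1).
#' @param min_dist Minimum distance between retained candidates in bp
#'   (default 20000).
#' @param seed Seed for the diagonal-wise permutation.
#' @param stratum_bp Distance-normalisation stratum width in bp
#'   (default 10000).
#' @param fdr_bin_bp Distance-bin width for the gamma null fits
#'   (default 10000).
#' @param min_null Minimum null scores per bin before pooling with
#'   neighbouring bins (default 30).
#' @param min_stratum_cells Passed to [distance_normalize()].
#' @return Data frame (class `loop_calls`) with columns `anchor1`, `anchor2`
#'   (representative fragment indices), `i`, `j` (candidate cell), `score`,
#'   `fdr`, `fdr_defined`, `p`, `w`, `distance_bp`, sorted by FDR.
#' @export
call_loops <- function(ifm, fmap, scales = list(c(3e4, 6e4), c(5e4, 1e5)),
                       min_score = 1, min_dist = 2e4, seed = 1L,
                       stratum_bp = 1e4, fdr_bin_bp = 1e4, min_null = 30,
                       min_stratum_cells = 30) {
  if (length(scales) == 0L) stop("at least one (p, w) scale is required")
  n <- n_fragments(fmap)
  pos <- frag_pos(fmap)
  ifnorm <- distance_normalize(ifm, fmap, stratum_bp, min_stratum_cells)
  perm_vals <- permute_diagonalwise(unclass(ifm), seed)
  perm_ifm <- if_matrix(perm_vals, normalized = is_normalized(ifm),
                        mask = if_mask(ifm))
  perm_norm <- distance_normalize(perm_ifm, fmap, stratum_bp,
                                  min_stratum_cells)
  nv <- unclass(ifnorm)
  ut <- upper.tri(nv)

  all_calls <- list()
  for (s in scales) {
    p <- s[[1]]; w <- s[[2]]
    sc <- score_candidate_peaks(ifnorm, fmap, p, w)
    null_sc <- score_candidate_peaks(perm_norm, fmap, p, w)
    cand <- which(ut & !is.na(sc) & sc >= min_score, arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    ci <- cand[, 1L]; cj <- cand[, 2L]
    cs <- sc[cand]
    cd <- pos[cj] - pos[ci]
    # elimination: greedy from the best score; ties by distance then indices
    o <- order(-cs, cd, ci, cj)
    keep <- eliminate_close(ci[o], cj[o], pos, min_dist)
    sel <- o[keep]
    ci <- ci[sel]; cj <- cj[sel]; cs <- cs[sel]; cd <- cd[sel]
    # representative pair: argmax IFnorm inside the peak square
    lo_r <- findInterval(pos[ci] - p, pos, left.open = TRUE) + 1L
    hi_r <- findInterval(pos[ci] + p, pos)
    lo_c <- findInterval(pos[cj] - p, pos, left.open = TRUE) + 1L
    hi_c <- findInterval(pos[cj] + p, pos)
    a1 <- integer(length(ci)); a2 <- integer(length(ci))
    for (k in seq_along(ci)) {
      rr <- lo_r[k]:hi_r[k]; cc <- lo_c[k]:hi_c[k]
      sub <- nv[rr, cc, drop = FALSE]
      if (all(is.na(sub))) {
        a1[k] <- ci[k]; a2[k] <- cj[k]
      } else {
        am <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)[1L, ]
        a1[k] <- rr[am[1L]]; a2[k] <- cc[am[2L]]
      }
    }
    nb <- unclass(null_sc)[ut]
    nd <- (outer(pos, pos, function(a, b) b - a))[ut]
    finite_null <- is.finite(nb)
    fdr <- gamma_fdr(cs, floor(cd / fdr_bin_bp), nb[finite_null],
                     floor(nd[finite_null] / fdr_bin_bp), min_null)
    all_calls[[length(all_calls) + 1L]] <-
      data.frame(anchor1 = a1, anchor2 = a2, i = ci, j = cj, score = cs,
                 fdr = fdr, fdr_defined = !is.na(fdr), p = p, w = w,
                 distance_bp = cd)
  }
  if (length(all_calls) == 0L) {
    out <- data.frame(anchor1 = integer(), anchor2 = integer(), i = integer(),
                      j = integer(), score = numeric(), fdr = numeric(),
                      fdr_defined = logical(), p = numeric(), w = numeric(),
                      distance_bp = numeric())
  } else {
    out <- do.call(rbind, all_calls)
    out <- out[order(out$fdr, -out$score, na.last = TRUE), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("loop_calls", "data.frame")
  out
}

# greedy proximity elimination on candidates already sorted best-first;
# spatial hashing on a min_dist grid keeps it near-linear
eliminate_close <- function(ci, cj, pos, min_dist) {
  k <- length(ci)
  keep <- logical(k)
  buckets <- new.env(hash = TRUE, parent = emptyenv())
  gx <- floor(pos[ci] / min_dist)
  gy <- floor(pos[cj] / min_dist)
  px <- pos[ci]; py <- pos[cj]
  for (t in seq_len(k)) {
    ok <- TRUE
    for (dx in -1:1) {
      for (dy in -1:1) {
        key <- paste(gx[t] + dx, gy[t] + dy)
        ids <- buckets[[key]]
        if (!is.null(ids)) {
          if (any(pmax(abs(px[ids] - px[t]), abs(py[ids] - py[t])) < min_dist)) {
            ok <- FALSE
            break
          }
        }
      }
      if (!ok) break
    }
    if (ok) {
      keep[t] <- TRUE
      key <- paste(gx[t], gy[t])
      buckets[[key]] <- c(buckets[[key]], t)
    }
  }
  keep
}
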