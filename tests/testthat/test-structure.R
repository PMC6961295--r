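test_that("directionality index matches its closed form", {
  # three fragments; the centre sees A = 10 upstream, B = 30 downstream
  fm <- uniform_fmap(3)
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 10
  m[2, 3] <- m[3, 2] <- 30
  prof <- directionality_profile(if_matrix(m), fm, delta = 5000)
  expect_equal(prof$A[2], 10)
  expect_equal(prof$B[2], 30)
  expect_equal(prof$di[2], 10)        # sign(B-A) * ((A-E)^2 + (B-E)^2)/E
  expect_equal(prof$di_prime[2], 0.5) # same with E^2 in the denominator

  # uniform matrix: interior fragments have A = B, so DI = DI' = 0
  u <- if_matrix(matrix(1, 9, 9))
  pu <- directionality_profile(u, uniform_fmap(9), delta = 2500)
  expect_equal(pu$di[4:6], rep(0, 3))
  expect_equal(pu$di_prime[4:6], rep(0, 3))

  # masked where no signal in the window
  z <- if_matrix(matrix(0, 5, 5))
  expect_true(all(is.na(directionality_profile(z, uniform_fmap(5))$di_prime)))

  # the default window span is 500 kb on each side
  expect_equal(formals(directionality_profile)$delta, 5e5)
})

test_that("DI' is antisymmetric under fragment-order reversal", {
  n <- 30
  fm <- uniform_fmap(n, size = 2000)
  ifm <- random_ifm(n, seed = 9)
  fwd <- directionality_profile(ifm, fm, delta = 10000)$di_prime
  rev_ifm <- if_matrix(unclass(ifm)[n:1, n:1])
  bwd <- directionality_profile(rev_ifm, fm, delta = 10000)$di_prime
  ok <- !is.na(fwd) & !is.na(rev(bwd))
  expect_equal(fwd[ok], -rev(bwd)[ok])
})

test_that("domain boundaries are strict DI' extrema away from ends", {
  # all-zero profile (uniform matrix, symmetric windows): no strict extremum
  fm <- uniform_fmap(30)
  pz <- directionality_profile(if_matrix(matrix(1, 30, 30)), fm, delta = 5000)
  expect_equal(nrow(call_domain_boundaries(pz, fm, window = 5,
                                           exclusion_bp = 5000)), 0)
  expect_error(call_domain_boundaries(pz, fm, window = 6), "odd")

  # planted two-domain chromosome: the junction is the top extremum
  p <- sim_params(n_fragments = 500, size_shape = 200, n_tads = 2,
                  tad_factor = 4, n_subtads = 0, n_loops = 0)
  hits <- 0
  for (s in c(2, 7, 21, 33, 44)) {
    truth <- simulate_true_if(p, seed = s)
    prof <- directionality_profile(truth$if_true, truth$fmap, delta = 1e5)
    b <- call_domain_boundaries(prof, truth$fmap, window = 21,
                                exclusion_bp = 1e5)
    if (abs(b$fragment[1] - truth$tad_boundaries) <= 1) hits <- hits + 1
    # ranking is by |DI'| descending
    expect_true(all(diff(abs(b$di_prime)) <= 1e-12))
  }
  expect_gte(hits, 4)

  # exclusion zones remove chromosome ends; top_k truncates
  truth <- simulate_true_if(p, seed = 2)
  prof <- directionality_profile(truth$if_true, truth$fmap, delta = 1e5)
  b2 <- call_domain_boundaries(prof, truth$fmap, window = 21,
                               exclusion_bp = 2e5, top_k = 3)
  expect_lte(nrow(b2), 3)
  pos <- frag_pos(truth$fmap)
  expect_true(all(pos[b2$fragment] >= 2e5 &
                    pos[b2$fragment] <= max(truth$fmap$end) - 2e5))
})

test_that("distance normalisation makes every stratum mean one", {
  n <- 40
  fm <- uniform_fmap(n, size = 2500)
  ifm <- random_ifm(n, seed = 12)
  ifn <- distance_normalize(ifm, fm, stratum_bp = 1e4, min_stratum_cells = 1)
  pos <- frag_pos(fm)
  strat <- floor(abs(outer(pos, pos, `-`)) / 1e4)
  v <- unclass(ifn)
  for (s in unique(as.vector(strat))) {
    vals <- v[strat == s]
    if (all(is.na(vals))) next
    expect_equal(mean(vals), 1, tolerance = 1e-12)
  }
  # brute-force per-cell oracle
  raw <- unclass(ifm)
  for (cell in list(c(3, 17), c(10, 30), c(5, 5))) {
    i <- cell[1]; j <- cell[2]
    expect_equal(v[i, j], raw[i, j] / mean(raw[strat == strat[i, j]]))
  }

  # an IF that is a pure function of the stratum normalises to exactly 1
  pure <- if_matrix(matrix((strat + 1)^-1, n, n))
  pn <- distance_normalize(pure, fm, 1e4, min_stratum_cells = 1)
  expect_equal(unclass(pn), matrix(1, n, n), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("donut scores compare the peak with its local background", {
  n <- 60
  fm <- uniform_fmap(n, size = 10000)
  flat <- matrix(1, n, n)
  sc <- score_candidate_peaks(if_matrix(flat), fm, p = 30000, w = 60000)
  expect_equal(sc[20, 40], 1)
  expect_equal(sc[10, 50], 1)
  expect_error(score_candidate_peaks(if_matrix(flat), fm, 60000, 30000),
               "p must be < w")

  # planted square of 5x background at a clean location scores exactly 5
  pk <- flat
  ri <- which(abs(frag_pos(fm) - frag_pos(fm)[20]) <= 30000)
  ci <- which(abs(frag_pos(fm) - frag_pos(fm)[45]) <= 30000)
  pk[ri, ci] <- 5
  sc2 <- score_candidate_peaks(if_matrix(pk), fm, p = 30000, w = 60000)
  expect_equal(sc2[20, 45], 5)

  # brute-force region-mean oracle on a random matrix
  ifm <- random_ifm(n, seed = 21)
  v <- unclass(ifm)
  pos <- frag_pos(fm)
  p <- 25000; w <- 55000
  sc3 <- score_candidate_peaks(ifm, fm, p, w)
  for (cell in list(c(15, 40), c(25, 50))) {
    i <- cell[1]; j <- cell[2]
    rw <- which(pos >= pos[i] - w & pos <= pos[i] + w)
    cw <- which(pos >= pos[j] - w & pos <= pos[j] + w)
    rp <- which(pos >= pos[i] - p & pos <= pos[i] + p)
    cp <- which(pos >= pos[j] - p & pos <= pos[j] + p)
    P <- mean(v[rp, cp])
    H <- mean(v[rp, setdiff(cw, cp)])
    V <- mean(v[setdiff(rw, rp), cp])
    D <- mean(v[setdiff(rw, rp), setdiff(cw, cp)])
    BL <- mean(v[rw[rw > max(rp)], cw[cw < min(cp)]])
    expect_equal(sc3[i, j], P / max(D, H, V, BL), tolerance = 1e-10)
  }
})

test_that("loop calling recovers a planted loop and respects its contracts", {
  p <- sim_params(n_fragments = 500, n_tads = 1, n_subtads = 0, n_loops = 1,
                  loop_factor = 10)
  hits <- 0
  for (s in c(11, 17, 23)) {
    truth <- simulate_true_if(p, seed = s)
    calls <- call_loops(truth$if_true, truth$fmap, seed = s)
    expect_gt(nrow(calls), 0)
    if (abs(calls$anchor1[1] - truth$loops$anchor1) <= 1 &&
        abs(calls$anchor2[1] - truth$loops$anchor2) <= 1) hits <- hits + 1
    # retained same-scale calls are farther than min_dist apart (Chebyshev)
    pos <- frag_pos(truth$fmap)
    for (sc in unique(calls$p)) {
      cs <- calls[calls$p == sc, ]
      if (nrow(cs) > 1) {
        d <- pmax(abs(outer(pos[cs$i], pos[cs$i], `-`)),
                  abs(outer(pos[cs$j], pos[cs$j], `-`)))
        expect_true(all(d[upper.tri(d)] >= 20000))
      }
    }
    # within a scale and distance bin, FDR is monotone in score
    cs <- calls[calls$p == 30000, ]
    cs$bin <- floor(cs$distance_bp / 1e4)
    for (b in unique(cs$bin)) {
      cb <- cs[cs$bin == b, ]
      if (nrow(cb) > 1) {
        o <- order(-cb$score)
        expect_true(all(diff(cb$fdr[o]) >= -1e-12))
      }
    }
  }
  expect_equal(hits, 3)

  # flat matrix: null self-consistency, no calls at FDR < 0.1
  fm <- uniform_fmap(100, size = 4000)
  flat <- if_matrix(matrix(5, 100, 100))
  fc <- call_loops(flat, fm, seed = 2, min_stratum_cells = 4)
  expect_equal(sum(fc$fdr < 0.1, na.rm = TRUE), 0)
})
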