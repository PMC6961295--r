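test_that("simulation is bit-identical under a fixed seed", {
  p <- sim_params(n_fragments = 60)
  a <- simulate_true_if(p, seed = 5)
  b <- simulate_true_if(p, seed = 5)
  expect_identical(a$fmap, b$fmap)
  expect_identical(unclass(a$if_true), unclass(b$if_true))
  expect_identical(a$bias, b$bias)
  expect_identical(a$loops, b$loops)
  c <- simulate_true_if(p, seed = 6)
  expect_false(identical(unclass(a$if_true), unclass(c$if_true)))

  rc1 <- sample_read_counts(a$if_true, a$bias, 2000, seed = 3)
  rc2 <- sample_read_counts(a$if_true, a$bias, 2000, seed = 3)
  expect_identical(unclass(rc1), unclass(rc2))
})

test_that("the generator plants the structure it reports", {
  p <- sim_params(n_fragments = 120, n_tads = 3, n_loops = 2)
  truth <- simulate_true_if(p, seed = 9)
  expect_length(truth$tad_boundaries, 2)
  expect_equal(nrow(truth$loops), 2)
  expect_equal(mean(truth$bias), 1, tolerance = 1e-12)
  expect_true(isSymmetric(unname(unclass(truth$if_true))))
  expect_true(all(unclass(truth$if_true) > 0))

  # without structure and gamma = 1, IF depends only on distance, so
  # distance normalisation is ~1 everywhere it is defined
  p0 <- sim_params(n_fragments = 100, n_tads = 1, n_subtads = 0, n_loops = 0)
  t0 <- simulate_true_if(p0, seed = 4)
  ifn <- distance_normalize(t0$if_true, t0$fmap)
  v <- unclass(ifn)
  pos <- frag_pos(t0$fmap)
  far <- abs(outer(pos, pos, `-`)) > 1e5  # strata wide relative to decay
  expect_lt(sd(v[far & !is.na(v)]), 0.05)
  expect_equal(mean(v[!is.na(v)]), 1, tolerance = 0.02)
})

test_that("read sampling follows the Poisson observation model", {
  p <- sim_params(n_fragments = 12, n_tads = 1, n_subtads = 0, n_loops = 0)
  truth <- simulate_true_if(p, seed = 2)
  expect_equal(sum(sample_read_counts(truth$if_true, truth$bias, 0, seed = 1)), 0)

  # Monte-Carlo check of E[RC_ij] = lambda_ij over 200 seeds
  depth <- 500
  s <- unclass(truth$if_true) * outer(truth$bias, truth$bias)
  lam_pair <- depth * s / sum(s)  # unordered-pair rate
  acc <- matrix(0, 12, 12)
  for (k in 1:200) {
    acc <- acc + unclass(sample_read_counts(truth$if_true, truth$bias, depth,
                                            seed = k))
  }
  mean_rc <- acc / 200
  for (cell in list(c(1, 2), c(3, 9), c(5, 6))) {
    i <- cell[1]; j <- cell[2]
    se <- sqrt(lam_pair[i, j] / 200)
    expect_lt(abs(mean_rc[i, j] - lam_pair[i, j]), 3 * se + 1e-9)
  }
  # expected full-matrix total equals the requested depth
  tot <- vapply(1:200, function(k)
    sum(sample_read_counts(truth$if_true, truth$bias, depth, seed = k + 500)), 0)
  expect_lt(abs(mean(tot) - depth), 3 * sqrt(depth / 200) * sqrt(2))

  # constant IF, unit bias: per-cell counts look Poisson (variance ~ mean)
  const <- if_matrix(matrix(1, 40, 40))
  ub <- rep(1, 40)
  rc <- sample_read_counts(const, ub, 8000, seed = 11)
  ut <- upper.tri(rc)
  expect_equal(var(unclass(rc)[ut]) / mean(unclass(rc)[ut]), 1,
               tolerance = 0.15)
})

test_that("binomial thinning splits conserve reads exactly", {
  rc <- random_rc(25, lambda = 3, seed = 14)
  sp <- split_read_counts(rc, 0.8, seed = 3)
  expect_identical(unclass(sp$input) + unclass(sp$test), unclass(rc))
  expect_true(all(unclass(sp$input) >= 0) && all(unclass(sp$test) >= 0))
  expect_identical(unclass(sp$input), t(unclass(sp$input)))

  # input share is ~80%: binomial z-test on the upper-triangle total
  n_reads <- sum(unclass(rc)[upper.tri(rc, diag = TRUE)])
  got <- sum(unclass(sp$input)[upper.tri(rc, diag = TRUE)])
  expect_lt(abs(got - 0.8 * n_reads), 3 * sqrt(n_reads * 0.8 * 0.2))
  expect_error(split_read_counts(rc, 0), "fraction")

  expect_identical(unclass(downsample_read_counts(rc, 1)), unclass(rc))
})

test_that("SSE evaluation matches a brute-force double loop", {
  a <- random_ifm(15, seed = 3)
  rc <- random_rc(15, lambda = 2, seed = 4)
  expect_equal(sse_eval(if_matrix(unclass(rc)), rc), 0)

  one <- unclass(rc) + 0
  one[2, 9] <- one[2, 9] + 1
  one[9, 2] <- one[9, 2] + 1
  expect_equal(sse_eval(if_matrix(one), rc), 1)

  brute <- 0
  for (i in 1:14) for (j in (i + 1):15) brute <- brute + (a[i, j] - rc[i, j])^2
  expect_equal(sse_eval(a, rc), brute)
  expect_error(sse_eval(a, random_rc(10)), "shape")

  sc <- scale_to_test(a, rc)
  ut <- upper.tri(sc)
  expect_equal(sum(unclass(sc)[ut]), sum(unclass(rc)[ut]))
})

test_that("cross-validation ranks estimators and records failures", {
  p <- sim_params(n_fragments = 150, depth = 8 * 150^2)
  cv <- cross_validate(p, list(cv_fixed(2), cv_fixed(32)),
                       depth_fractions = c(0.002, 1), seeds = 1:3)
  expect_equal(nrow(cv), 12)  # 3 seeds x 2 fractions x 2 methods
  expect_true(all(!is.na(cv$sse)))
  agg <- aggregate(sse ~ method + depth_fraction, cv, mean)
  # at low coverage coarse bins win; at high coverage fine bins win
  low <- agg[agg$depth_fraction == 0.002, ]
  high <- agg[agg$depth_fraction == 1, ]
  expect_lt(low$sse[low$method == "fixed_32"], low$sse[low$method == "fixed_2"])
  expect_lt(high$sse[high$method == "fixed_2"], high$sse[high$method == "fixed_32"])

  # an unknown method is recorded as NA and the run continues
  expect_warning(
    cv2 <- cross_validate(p, list(cv_fixed(2), list(label = "bad", method = "nope")),
                          seeds = 1),
    "failed")
  expect_true(is.na(cv2$sse[cv2$method == "bad"]))
  expect_false(is.na(cv2$sse[cv2$method == "fixed_2"]))
})

test_that("MRF estimates recover the ground truth better than raw counts", {
  p <- sim_params(n_fragments = 150)
  wins <- 0
  for (s in 1:10) {
    truth <- simulate_true_if(p, seed = s)
    rc <- sample_read_counts(truth$if_true, truth$bias, p$depth, seed = s + 100)
    bias <- compute_fragment_bias(rc)
    nrc <- normalize_counts(rc, bias)
    mrf <- estimate_mrf(rc, bias, nrc = nrc)
    truth_scaled <- function(pred) {
      ut <- upper.tri(pred)
      tv <- unclass(truth$if_true)
      sum((unclass(pred)[ut] / sum(unclass(pred)[ut]) -
             tv[ut] / sum(tv[ut]))^2)
    }
    if (truth_scaled(mrf) < truth_scaled(nrc)) wins <- wins + 1
  }
  expect_gte(wins, 9)
})
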