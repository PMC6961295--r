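test_that("KS scan flags sharp steps and nothing else", {
  flat <- if_matrix(matrix(1, 20, 20))
  expect_equal(nrow(detect_transition_boundaries(flat)), 0)

  # step matrix: rows 1..10 constant 10, rows 11..20 constant 1
  step <- matrix(1, 20, 20)
  step[1:10, ] <- 10
  tb <- detect_transition_boundaries(if_matrix(step, mask = rep(FALSE, 20)),
                                     ks_threshold = 1.5, segment_len = 8)
  expect_equal(nrow(tb), 1)
  expect_equal(tb$orientation, "horizontal")
  expect_equal(tb$index, 10)        # boundary between rows 10 and 11
  expect_equal(tb$start, 1)
  # greedy segments tile 1-8 and 9-16; the trailing 4 columns cannot hold a
  # further non-overlapping segment, so the merged boundary spans 1-16
  expect_equal(tb$end, 16)
  # fully separated samples: D = 1, scaled statistic sqrt(8*8/16) = 2
  expect_equal(tb$statistic, 2)

  expect_equal(nrow(detect_transition_boundaries(if_matrix(step,
                mask = rep(FALSE, 20)), ks_threshold = Inf)), 0)
  expect_error(detect_transition_boundaries(flat, segment_len = 1),
               "segment_len")
})

test_that("local MRF objective peaks where prior and likelihood agree", {
  n <- 9
  c0 <- 4
  rc <- rc_matrix(matrix(c0, n, n))
  bias <- structure(rep(1, n), mask = rep(FALSE, n))
  ifm <- if_matrix(matrix(c0, n, n))
  params <- mrf_params()
  # constant field with RC = c and unit bias: factor 1 maximises the
  # objective over the multiplicative grid
  objs <- vapply(params$grid_factors, function(f) {
    mrf_local_objective(ifm, rc, bias, 5, 5, c0 * f, params)
  }, 0)
  expect_equal(which.max(objs), which(params$grid_factors == 1))

  # prior-vanishing limit (variance alpha*log(MedNeigh) grows with alpha):
  # the argmax approaches the Poisson ML estimate RC/(b_i b_j)
  m2 <- matrix(4, 9, 9)
  m2[5, 5] <- 9
  rc2 <- rc_matrix(m2)
  weak <- mrf_params(alpha = 1e6)
  cand <- seq(1, 15, by = 0.1)
  o <- vapply(cand, function(v)
    mrf_local_objective(ifm, rc2, bias, 5, 5, v, weak), 0)
  expect_equal(cand[which.max(o)], 9, tolerance = 0.11)

  # negative binomial with variance multiplier 1 equals the Poisson branch
  nb1 <- mrf_params(likelihood = "nb", nb_variance_multiplier = 1)
  expect_equal(mrf_local_objective(ifm, rc, bias, 4, 6, 3.7, nb1),
               mrf_local_objective(ifm, rc, bias, 4, 6, 3.7, params),
               tolerance = 1e-9)
  # larger variance multipliers flatten the likelihood around the mode
  nb4 <- mrf_params(likelihood = "nb", nb_variance_multiplier = 4)
  drop_p <- mrf_local_objective(ifm, rc, bias, 4, 6, 4, params) -
    mrf_local_objective(ifm, rc, bias, 4, 6, 8, params)
  drop_nb <- mrf_local_objective(ifm, rc, bias, 4, 6, 4, nb4) -
    mrf_local_objective(ifm, rc, bias, 4, 6, 8, nb4)
  expect_lt(drop_nb, drop_p)
})

test_that("ICM keeps a constant field fixed and shrinks outliers", {
  n <- 12
  c0 <- 4
  rc <- rc_matrix(matrix(c0, n, n))
  bias <- compute_fragment_bias(rc)
  init <- if_matrix(matrix(c0, n, n))
  out <- estimate_mrf(rc, bias, init = init)
  expect_equal(unclass(out), matrix(c0, n, n), tolerance = 1e-12,
               ignore_attr = TRUE)

  # single outlier count: estimate lies strictly between the field and the
  # maximum-likelihood value (shrinkage toward the neighbourhood median)
  m <- matrix(c0, n, n)
  m[4, 9] <- m[9, 4] <- 100
  rc2 <- rc_matrix(m)
  bias2 <- compute_fragment_bias(rc2)
  nrc2 <- normalize_counts(rc2, bias2)
  out2 <- estimate_mrf(rc2, bias2, init = nrc2, nrc = nrc2)
  ml <- 100 / (bias2[4] * bias2[9])
  expect_gt(out2[4, 9], c0)
  expect_lt(out2[4, 9], ml)
  expect_equal(out2[4, 9], out2[9, 4])
})

test_that("ICM never decreases the joint log probability", {
  p <- sim_params(n_fragments = 80, n_tads = 2, n_subtads = 2, n_loops = 1)
  truth <- simulate_true_if(p, seed = 6)
  rc <- sample_read_counts(truth$if_true, truth$bias, p$depth, seed = 7)
  bias <- compute_fragment_bias(rc)
  nrc <- normalize_counts(rc, bias)
  init <- estimate_akde(rc, nrc, minimum_count = 50, h_max = 16)
  out <- estimate_mrf(rc, bias, init = init, nrc = nrc,
                      minimum_count = 50, h_max = 16)
  lp <- attr(out, "logp")
  expect_true(all(diff(lp) >= 0))
  expect_lte(attr(out, "sweeps"), mrf_params()$max_iter)

  # the incremental trace agrees with independent joint-log-probability
  # evaluations of the initial and final configurations
  mask <- if_mask(init) | bias_mask(bias)
  bnd <- attr(out, "boundaries")
  init_m <- if_matrix(pmax(unclass(init), 1e-12), mask = mask)
  expect_equal(mrf_joint_logp(init_m, rc, bias, boundaries = bnd), lp[1],
               tolerance = 1e-8)
  expect_equal(attr(out, "logp_final"), lp[length(lp)], tolerance = 1e-8)

  # randomized sweep order also converges monotonically to a similar logP
  out_r <- estimate_mrf(rc, bias, init = init, nrc = nrc,
                        minimum_count = 50, h_max = 16, seed = 42,
                        params = mrf_params(sweep_order = "random"))
  expect_true(all(diff(attr(out_r, "logp")) >= 0))
  expect_equal(attr(out_r, "logp_final") / lp[length(lp)], 1,
               tolerance = 0.05)
})

test_that("transition boundaries block neighbour sharing across a step", {
  # two blocks with very different levels; a boundary between rows k,k+1
  # keeps the MRF from bleeding across the junction
  n <- 30
  k <- 15
  lv <- matrix(1, n, n)
  lv[1:k, 1:k] <- 12
  lv[(k + 1):n, (k + 1):n] <- 12
  rc <- rc_matrix(round(lv))
  bias <- compute_fragment_bias(rc)
  nrc <- normalize_counts(rc, bias)
  tb <- detect_transition_boundaries(nrc, 1.5, 8)
  expect_gt(nrow(tb), 0)
  out <- estimate_mrf(rc, bias, init = nrc, nrc = nrc)
  # block interiors stay at their level instead of averaging across
  expect_gt(mean(out[2:6, 2:6]), 5 * mean(out[2:6, 20:25]))
})
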