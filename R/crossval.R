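#' Method descriptors for cross-validation
#'
#' Convenience constructors naming an estimator and its hyperparameters for
#' [cross_validate()].
#' @param bin_size Fragments per bin for the fixed-binning estimator.
#' @name cv_methods
#' @export
cv_fixed <- function(bin_size) {
  list(label = paste0("fixed_", bin_size), method = "fixed",
       bin_size = bin_size)
}

#' @rdname cv_methods
#' @param h Bandwidth for the fixed-bandwidth KDE.
#' @export
cv_kde <- function(h) list(label = paste0("kde_", h), method = "kde", h = h)

#' @rdname cv_methods
#' @param minimum_count,h_max Adaptive-KDE coverage threshold and bandwidth
#'   cap.
#' @export
cv_akde <- function(minimum_count = 100, h_max = 64) {
  list(label = "akde", method = "akde", minimum_count = minimum_count,
       h_max = h_max)
}

#' @rdname cv_methods
#' @param params [mrf_params()] for the MRF estimator.
#' @export
cv_mrf <- function(params = mrf_params(), minimum_count = 100, h_max = 64) {
  list(label = "mrf", method = "mrf", params = params,
       minimum_count = minimum_count, h_max = h_max)
}

# run one estimator on an input count matrix; returns a non-normalized
# prediction on the read-count scale
run_estimator <- function(m, rc_input, bias, nrc) {
  est <- switch(m$method,
    fixed = estimate_fixed_binning(nrc, m$bin_size),
    kde = estimate_kde(nrc, m$h),
    akde = estimate_akde(rc_input, nrc, m$minimum_count, m$h_max),
    mrf = estimate_mrf(rc_input, bias, params = m$params, nrc = nrc,
                       minimum_count = m$minimum_count, h_max = m$h_max),
    stop("unknown method: ", m$method)
  )
  out <- denormalize(est, bias)
  attr(out, "sweeps") <- attr(est, "sweeps")
  out
}

#' Cross-validate interaction-frequency estimators on synthetic data
#'
#' For each seed: simulate a ground-truth chromosome, sample reads at the
#' parameterised depth, split them 80/20 into input and test sets, optionally
#' downsample the input set, run every estimator on the (bias-normalised)
#' input matrix, scale each prediction to the test total, and score it by
#' the sum of squared errors against the held-out counts.
#'
#' @param params A [sim_params()].
#' @param methods List of method descriptors ([cv_fixed()], [cv_kde()],
#'   [cv_akde()], [cv_mrf()]).
#' @param depth_fractions Fractions of the input set to retain (default 1).
#' @param seeds Integer vector of simulation seeds.
#' @param split_fraction Input-set share of the reads (default 0.8).
#' @return Data frame with columns `seed`, `depth_fraction`, `method`,
#'   `sse`, `sweeps` (MRF only, NA otherwise); estimator failures are
#'   recorded as NA SSE and the run continues.
#' @export
cross_validate <- function(params = sim_params(), methods,
                           depth_fractions = 1, seeds = 1:10,
                           split_fraction = 0.8) {
  if (length(methods) == 0L || length(seeds) == 0L ||
      length(depth_fractions) == 0L) {
    stop("methods, seeds, and depth_fractions must be nonempty")
  }
  rows <- list()
  for (seed in seeds) {
    truth <- simulate_true_if(params, seed = seed)
    rc <- sample_read_counts(truth$if_true, truth$bias, params$depth,
                             seed = seed + 1000L)
    sp <- split_read_counts(rc, split_fraction, seed = seed + 2000L)
    for (f in depth_fractions) {
      rc_in <- downsample_read_counts(sp$input, f, seed = seed + 3000L)
      bias <- compute_fragment_bias(rc_in)
      nrc <- normalize_counts(rc_in, bias)
      for (m in methods) {
        sse <- NA_real_
        sweeps <- NA_integer_
        res <- tryCatch({
          pred <- run_estimator(m, rc_in, bias, nrc)
          if (!is.null(attr(pred, "sweeps"))) sweeps <- attr(pred, "sweeps")
          pred <- scale_to_test(pred, sp$test)
          sse_eval(pred, sp$test)
        }, error = function(e) {
          warning("estimator ", m$label, " failed on seed ", seed, ": ",
                  conditionMessage(e))
          NA_real_
        })
        sse <- res
        rows[[length(rows) + 1L]] <-
          data.frame(seed = seed, depth_fraction = f, method = m$label,
                     sse = sse, sweeps = sweeps)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a cross-validation table as TSV
#' @param cv Data frame from [cross_validate()].
#' @param path Output path.
#' @export
write_crossval_table <- function(cv, path) {
  utils::write.table(cv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Held-out accuracy gain of the MRF estimator over fixed binning
#'
#' Runs the read-split cross-validation experiment on the default synthetic
#' chromosome: for each seed, reads are sampled at the parameterised depth,
#' split 80/20, fixed binning at several bin sizes plus the MRF estimator are
#' fit on the input set, and each prediction's SSE against the held-out
#' counts is recorded. Returns the percentage reduction in mean SSE achieved
#' by the MRF estimator relative to the best-performing bin size.
#'
#' @param seeds Simulation seeds (one chromosome each).
#' @param bins Fixed-binning bin sizes to scan.
#' @param params A [sim_params()].
#' @return List with `reduction_pct`, `best_bin`, `mean_sse` (by method),
#'   `sweeps` (MRF sweep counts per seed), and the full `table`.
#' @export
mrf_vs_binning_reduction <- function(seeds = 1:10,
                                     bins = c(1, 2, 4, 8, 16, 32),
                                     params = sim_params()) {
  methods <- c(lapply(bins, cv_fixed), list(cv_mrf()))
  cv <- cross_validate(params, methods, seeds = seeds)
  agg <- stats::aggregate(sse ~ method, cv, mean)
  fixed <- agg[grepl("^fixed_", agg$method), ]
  best <- fixed[which.min(fixed$sse), ]
  mrf_sse <- agg$sse[agg$method == "mrf"]
  list(reduction_pct = 100 * (1 - mrf_sse / best$sse),
       best_bin = as.integer(sub("fixed_", "", best$method)),
       mean_sse = agg,
       sweeps = cv$sweeps[cv$method == "mrf"],
       table = cv)
}
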