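# fixtures built in code: tiny fragment maps and matrices

# fragment map with constant fragment size
uniform_fmap <- function(n, size = 1000, chrom = "chrT") {
  fragment_map(chrom, (0:(n - 1)) * size, (1:n) * size)
}

# random symmetric nonnegative-integer count matrix
random_rc <- function(n, lambda = 2, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(0L, n, n)
    ut <- upper.tri(m, diag = TRUE)
    m[ut] <- rpois(sum(ut), lambda)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    rc_matrix(m)
  })
}

# random symmetric positive real matrix wrapped as a normalized IF matrix
random_ifm <- function(n, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(0, n, n)
    ut <- upper.tri(m, diag = TRUE)
    m[ut] <- rexp(sum(ut)) + 0.1
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    if_matrix(m, normalized = TRUE)
  })
}

# write lines to a temp file and return its path
tmp_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
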