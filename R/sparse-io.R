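#' Read a sparse matrix in the chrom/i/j/value TSV dialect
#'
#' Rows are `chrom<TAB>i<TAB>j<TAB>value` with 0-based fragment indices
#' i <= j (the upper triangle; symmetry is implied). Duplicate (i, j) rows are
#' summed; unlisted pairs are zero. A header line starting with `#` is
#' permitted and ignored. One chromosome per file; intrachromosomal only.
#'
#' @param path Path to the TSV file.
#' @param fmap [fragment_map()] providing the fragment count and chromosome.
#' @param type `"counts"` to return an [rc_matrix()] (values must be
#'   nonnegative integers) or `"if"` to return an [if_matrix()].
#' @param normalized For `type = "if"`, the normalisation flag to set.
#' @return An [rc_matrix()] or [if_matrix()].
#' @export
read_sparse_matrix <- function(path, fmap, type = c("counts", "if"),
                               normalized = TRUE) {
  type <- match.arg(type)
  n <- n_fragments(fmap)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  m <- matrix(0, n, n)
  if (length(lines) > 0L) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 4L)) {
      bad <- which(lengths(fields) < 4L)[1L]
      stop(sprintf("line %d of %s: expected 4 tab-separated fields",
                   which(keep)[bad], path))
    }
    i <- as.integer(vapply(fields, `[[`, "", 2L))
    j <- as.integer(vapply(fields, `[[`, "", 3L))
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
    if (anyNA(i) || anyNA(j) || anyNA(v)) stop("malformed row in ", path)
    if (any(i < 0L) || any(j < 0L) || any(i >= n) || any(j >= n)) {
      stop(sprintf("fragment index out of range [0, %d) in %s", n, path))
    }
    if (any(i > j)) stop("rows must satisfy i <= j in ", path)
    if (type == "counts" && (any(v < 0) || any(v != round(v)))) {
      stop("counts must be nonnegative integers in ", path)
    }
    # accumulate duplicates, then symmetrise
    idx <- i * n + j + 1  # 1-based linear index into t(m): row i, col j
    acc <- rowsum(v, idx)
    pos <- as.numeric(rownames(acc))
    jj <- as.integer((pos - 1) %% n)      # 0-based col
    ii <- as.integer((pos - 1 - jj) / n)  # 0-based row
    m[cbind(ii + 1L, jj + 1L)] <- acc[, 1L]
    m[cbind(jj + 1L, ii + 1L)] <- acc[, 1L]
  }
  if (type == "counts") rc_matrix(m) else {
    if_matrix(m, normalized = normalized, mask = rowSums(m) == 0)
  }
}

#' Write a matrix in the sparse TSV dialect
#'
#' Emits only the upper triangle (i <= j), rows sorted by (i, j). For count
#' matrices zero entries are omitted and values printed as integers; for IF
#' matrices values are printed with 6 significant digits and zero cells are
#' also omitted.
#'
#' @param m An [rc_matrix()] or [if_matrix()].
#' @param path Output path.
#' @param chrom Chromosome label for column 1.
#' @export
write_sparse_matrix <- function(m, path, chrom = "chr") {
  n <- nrow(m)
  ut <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  i <- ut[, 1L] - 1L
  j <- ut[, 2L] - 1L
  o <- order(i, j)
  i <- i[o]; j <- j[o]
  v <- m[ut][o]
  if (inherits(m, "rc_matrix")) {
    rows <- sprintf("%s\t%d\t%d\t%d", chrom, i, j, as.integer(v))
  } else {
    rows <- sprintf("%s\t%d\t%d\t%s", chrom, i, j, formatC(v, digits = 6, format = "g"))
  }
  writeLines(rows, path)
  invisible(path)
}

#' Write a per-fragment bias vector as a 2-column TSV
#' @param bias Numeric vector of fragment biases.
#' @param path Output path.
#' @export
write_bias_vector <- function(bias, path) {
  writeLines(sprintf("%d\t%s", seq_along(bias) - 1L,
                     formatC(bias, digits = 6, format = "g")), path)
  invisible(path)
}

#' Write domain boundaries as BED
#'
#' One row per boundary fragment: interval, |DI'| as the score, and the sign
#' of DI' in the strand column.
#' @param boundaries Data frame from [call_domain_boundaries()].
#' @param fmap The [fragment_map()].
#' @param path Output path.
#' @export
write_boundaries_bed <- function(boundaries, fmap, path) {
  i <- boundaries$fragment
  writeLines(sprintf("%s\t%d\t%d\tboundary_%d\t%s\t%s",
                     fmap$chrom[i], as.integer(fmap$start[i]),
                     as.integer(fmap$end[i]), seq_along(i),
                     formatC(abs(boundaries$di_prime), digits = 6, format = "g"),
                     ifelse(boundaries$sign >= 0, "+", "-")), path)
  invisible(path)
}

#' Write loop calls as BEDPE
#' @param loops Data frame from [call_loops()].
#' @param fmap The [fragment_map()].
#' @param path Output path.
#' @export
write_loops_bedpe <- function(loops, fmap, path) {
  a <- loops$anchor1
  b <- loops$anchor2
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d\tloop_%d\t%s\t.\t.\t%s\t%d\t%d",
                     fmap$chrom[a], as.integer(fmap$start[a]), as.integer(fmap$end[a]),
                     fmap$chrom[b], as.integer(fmap$start[b]), as.integer(fmap$end[b]),
                     seq_along(a),
                     formatC(loops$score, digits = 6, format = "g"),
                     formatC(loops$fdr, digits = 6, format = "g"),
                     as.integer(loops$p), as.integer(loops$w)), path)
  invisible(path)
}
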