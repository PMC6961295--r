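#' Construct a fragment map
#'
#' A fragment map holds the ordered restriction-fragment (RF) intervals of a
#' single chromosome. Coordinates are 0-based half-open (BED convention); the
#' "position" of a fragment, used throughout for genomic-distance computations,
#' is its end coordinate (its 3'-most base on the forward strand).
#'
#' @param chrom Chromosome identifier (single string).
#' @param start,end Integer vectors of fragment start/end coordinates in bp.
#' @param sort Sort fragments by start before validation (default `TRUE`).
#' @return An object of class `fragment_map`: a data.frame with columns
#'   `chrom`, `start`, `end`, one row per fragment in genomic order.
#' @examples
#' fm <- fragment_map("chr1", c(0, 1000, 2500), c(1000, 2500, 2600))
#' n_fragments(fm)
#' frag_pos(fm)
#' @export
fragment_map <- function(chrom, start, end, sort = TRUE) {
  if (length(start) != length(end)) stop("start and end lengths differ")
  if (length(start) == 0L) stop("no fragments")
  if (length(unique(chrom)) != 1L) stop("a fragment map covers one chromosome")
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (sort) {
    o <- order(start)
    start <- start[o]
    end <- end[o]
  }
  if (any(end <= start)) {
    bad <- which(end <= start)[1L]
    stop(sprintf("fragment %d has end <= start (%g <= %g)", bad, end[bad], start[bad]))
  }
  if (length(start) > 1L && any(start[-1L] < end[-length(end)])) {
    bad <- which(start[-1L] < end[-length(end)])[1L]
    stop(sprintf("fragments %d and %d overlap", bad, bad + 1L))
  }
  fm <- data.frame(chrom = chrom[1L], start = start, end = end,
                   stringsAsFactors = FALSE)
  class(fm) <- c("fragment_map", "data.frame")
  fm
}

#' Read a fragment map from a BED-like file
#'
#' Expects at least three tab-separated columns (chrom, start, end), 0-based
#' half-open, one chromosome per file. Lines starting with `#` are ignored.
#' Fragments are sorted by start; overlaps and empty intervals are errors.
#'
#' @param path Path to the BED-like file.
#' @return A [fragment_map()].
#' @export
load_fragment_map <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("no fragments in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1L]
    stop(sprintf("line %d of %s: expected >= 3 tab-separated fields", lineno[bad], path))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1L]
    stop(sprintf("line %d of %s: non-numeric coordinate", lineno[bad], path))
  }
  if (length(unique(chrom)) != 1L) {
    stop("fragment map must contain a single chromosome, found: ",
         paste(unique(chrom), collapse = ", "))
  }
  fragment_map(chrom, start, end)
}

#' Write a fragment map as BED
#' @param fmap A [fragment_map()].
#' @param path Output path.
#' @export
write_fragment_map <- function(fmap, path) {
  stopifnot(inherits(fmap, "fragment_map"))
  writeLines(sprintf("%s\t%d\t%d", fmap$chrom, as.integer(fmap$start),
                     as.integer(fmap$end)), path)
  invisible(path)
}

#' Number of fragments in a map
#' @param fmap A [fragment_map()].
#' @export
n_fragments <- function(fmap) nrow(fmap)

#' Fragment positions (3' ends)
#'
#' The representative genomic position of each fragment: its end coordinate on
#' the forward strand. Strictly increasing by construction.
#' @param fmap A [fragment_map()].
#' @export
frag_pos <- function(fmap) fmap$end

#' Fragment sizes in bp
#' @param fmap A [fragment_map()].
#' @export
frag_sizes <- function(fmap) fmap$end - fmap$start

#' @export
print.fragment_map <- function(x, ...) {
  cat(sprintf("fragment_map: %d fragments on %s [%d, %d), mean size %.0f bp\n",
              nrow(x), x$chrom[1L], as.integer(min(x$start)),
              as.integer(max(x$end)), mean(frag_sizes(x))))
  invisible(x)
}
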