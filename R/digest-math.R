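#' Expected restriction-fragment spacing for a recognition site length
#'
#' Under a uniform i.i.d. base model each position starts a cut site with
#' probability (1/4)^k for a k-bp recognition sequence, so cut sites form an
#' approximate Poisson process with expected spacing 4^k bp. A 4-cutter
#' (e.g. MboI) therefore yields 4^2 = 16-fold more fragments per chromosome
#' than a 6-cutter (e.g. HindIII), and 256-fold more fragment pairs.
#'
#' @param site_length Recognition-site length in bp (4 for a 4-cutter).
#' @return Expected fragment length in bp (4^site_length).
#' @export
expected_rf_spacing <- function(site_length) 4^site_length

#' Lengths of the hg19 reference chromosomes
#'
#' Canonical chromosome lengths (bp) of the human hg19/GRCh37 assembly,
#' chr1-chr22, chrX, chrY. Public reference constants used for sparsity
#' arithmetic.
#' @return Named numeric vector of 24 chromosome lengths.
#' @export
hg19_chrom_lengths <- function() {
  c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566)
}

#' Expected read pairs per intrachromosomal fragment-pair entry
#'
#' Given a total sequencing depth and a mean restriction-fragment size, the
#' number of distinct intrachromosomal fragment pairs across the genome is
#' sum over chromosomes of n_c(n_c + 1)/2 with n_c = L_c / fragment_bp; the
#' expected read pairs per entry is `total_pairs` divided by that, assuming
#' all pairs were intrachromosomal (an upper bound on the true per-entry
#' coverage).
#'
#' @param total_pairs Total read pairs sequenced.
#' @param fragment_bp Mean fragment size in bp (434 for an MboI digest of
#'   hg19; 3700 for HindIII).
#' @param chrom_lengths Named vector of chromosome lengths (default hg19).
#' @return Expected read pairs per matrix entry (scalar).
#' @export
expected_pairs_per_entry <- function(total_pairs, fragment_bp,
                                     chrom_lengths = hg19_chrom_lengths()) {
  n_c <- chrom_lengths / fragment_bp
  entries <- sum(n_c * (n_c + 1) / 2)
  total_pairs / entries
}
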