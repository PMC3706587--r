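# Genome layout: 22 autosomes + X with centromere positions.

.CHROM_TABLE <- data.frame(
  chrom = c(as.character(1:22), "X"),
  length = c(
    247249719L, 242951149L, 199501827L, 191273063L, 180857866L,
    170899992L, 158821424L, 146274826L, 140273252L, 135374737L,
    134452384L, 132349534L, 114142980L, 106368585L, 100338915L,
    88827254L, 78774742L, 76117153L, 63811651L, 62435964L,
    46944323L, 49691432L, 154913754L
  ),
  centromere = c(
    125000000L, 93300000L, 91000000L, 50400000L, 48400000L,
    61000000L, 59900000L, 45600000L, 49000000L, 40200000L,
    53700000L, 35800000L, 17900000L, 17600000L, 19000000L,
    36600000L, 24000000L, 17200000L, 26500000L, 27500000L,
    13200000L, 14700000L, 60600000L
  ),
  stringsAsFactors = FALSE
)

# Acrocentric chromosomes: the short arm carries no markers on real panels.
.ACROCENTRIC <- c("13", "14", "15", "21", "22")

#' Genome layout for the analysis
#'
#' Chromosome lengths and centromere positions for the 22 autosomes and the
#' X chromosome (hg18-like coordinates). For simulation and testing the
#' genome can be scaled down; the default divides all coordinates by 100 so
#' that synthetic cohorts segment in seconds while keeping realistic
#' relative arm sizes.
#'
#' @param scale positive divisor applied to all coordinates (default 100;
#'   use 1 for full-size coordinates).
#' @return A data frame of class `genome_layout` with columns `chrom`,
#'   `length`, `centromere` and an `acrocentric` logical column marking
#'   chromosomes whose p arm carries no SNPs.
#' @examples
#' g <- genome_layout()
#' sum(g$length)
#' @export
genome_layout <- function(scale = 100) {
  stopifnot(is.numeric(scale), length(scale) == 1, scale > 0)
  g <- .CHROM_TABLE
  g$length <- as.integer(round(g$length / scale))
  g$centromere <- as.integer(round(g$centromere / scale))
  g$acrocentric <- g$chrom %in% .ACROCENTRIC
  stopifnot(all(g$length > 0), all(g$centromere > 0),
            all(g$centromere < g$length), !anyDuplicated(g$chrom))
  class(g) <- c("genome_layout", "data.frame")
  g
}

#' Chromosome arm table
#'
#' Expands a genome layout into one row per chromosome arm with its bp
#' interval (1-based inclusive). Acrocentric p arms are retained but
#' flagged, since the SNP panel places no markers there.
#'
#' @param genome a `genome_layout`.
#' @return data frame with columns `chrom`, `arm` ("p"/"q"), `arm_name`
#'   (e.g. "2q"), `start`, `end`, `has_snps`.
#' @export
chrom_arms <- function(genome) {
  p <- data.frame(chrom = genome$chrom, arm = "p",
                  start = 1L, end = genome$centromere,
                  stringsAsFactors = FALSE)
  q <- data.frame(chrom = genome$chrom, arm = "q",
                  start = genome$centromere + 1L, end = genome$length,
                  stringsAsFactors = FALSE)
  arms <- rbind(p, q)
  arms <- arms[order(match(arms$chrom, genome$chrom), arms$arm), ]
  arms$arm_name <- paste0(arms$chrom, arms$arm)
  arms$has_snps <- !(arms$arm == "p" & arms$chrom %in% .ACROCENTRIC)
  rownames(arms) <- NULL
  arms
}

#' Assign positions to chromosome arms
#'
#' @param chrom,pos vectors of chromosome names and bp positions.
#' @param genome a `genome_layout`.
#' @return character vector "p"/"q".
#' @export
assign_arm <- function(chrom, pos, genome) {
  cen <- genome$centromere[match(chrom, genome$chrom)]
  ifelse(pos <= cen, "p", "q")
}
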