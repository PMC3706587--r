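# SNP panel generation with population-differentiated allele frequencies.

#' Generate a SNP panel
#'
#' Places SNPs on the genome proportionally to chromosome length (largest
#' remainder apportionment, at least one SNP per chromosome), assigns each
#' SNP to one of four sub-arrays round-robin, and draws population allele-A
#' frequencies under a Balding-Nichols model: the ancestral frequency is
#' Uniform(0.05, 0.95) and each population's frequency is Beta distributed
#' around it with divergence `fst`. Acrocentric short arms (13p, 14p, 15p,
#' 21p, 22p) carry no SNPs, matching real linkage panels.
#'
#' @param n_snps total number of SNPs (>= number of chromosomes).
#' @param genome a [genome_layout()].
#' @param fst divergence parameter in [0, 1); 0 makes every population
#'   frequency equal the ancestral frequency.
#' @param populations population labels (default EUR, AFR, ASI).
#' @param n_subarrays number of sub-arrays the assay is split over.
#' @param seed integer seed fixing all randomness.
#' @return data frame of class `snp_panel` with columns `snp_id`, `chrom`,
#'   `pos`, `subarray`, plus one `freq_<pop>` column per population and an
#'   `ancestral` column. Rows ordered by genome position.
#' @examples
#' panel <- generate_snp_panel(600, genome_layout(), seed = 1)
#' table(panel$subarray)
#' @export
generate_snp_panel <- function(n_snps, genome = genome_layout(), fst = 0.15,
                               populations = c("EUR", "AFR", "ASI"),
                               n_subarrays = 4, seed = NULL) {
  if (n_snps < nrow(genome)) stop("panel too sparse")
  stopifnot(fst >= 0, fst < 1)
  if (!is.null(seed)) set.seed(seed)

  # apportion SNPs per chromosome by length, largest remainder, min 1
  share <- n_snps * genome$length / sum(genome$length)
  cnt <- pmax(1L, floor(share))
  rem <- n_snps - sum(cnt)
  if (rem > 0) {
    ord <- order(share - floor(share), decreasing = TRUE)
    add <- ord[seq_len(rem)]
    cnt[add] <- cnt[add] + 1L
  } else if (rem < 0) {
    ord <- order(share - floor(share))
    k <- 0L
    for (i in ord) {
      if (k == -rem) break
      if (cnt[i] > 1L) { cnt[i] <- cnt[i] - 1L; k <- k + 1L }
    }
  }

  chrom <- rep(genome$chrom, cnt)
  lo <- ifelse(genome$acrocentric, genome$centromere + 1L, 1L)
  pos <- unlist(lapply(seq_len(nrow(genome)), function(i) {
    sort(sample.int(genome$length[i] - lo[i] + 1L, cnt[i], replace = FALSE) +
           lo[i] - 1L)
  }))
  n <- length(pos)
  panel <- data.frame(
    snp_id = sprintf("snp%05d", seq_len(n)),
    chrom = chrom, pos = as.integer(pos),
    subarray = as.integer((seq_len(n) - 1L) %% n_subarrays + 1L),
    stringsAsFactors = FALSE
  )

  panel$ancestral <- stats::runif(n, 0.05, 0.95)
  for (p in populations) {
    if (fst < 1e-12) {
      f <- panel$ancestral
    } else {
      a <- panel$ancestral * (1 - fst) / fst
      b <- (1 - panel$ancestral) * (1 - fst) / fst
      f <- stats::rbeta(n, a, b)
    }
    panel[[paste0("freq_", p)]] <- pmin(pmax(f, 0), 1)
  }
  attr(panel, "populations") <- populations
  attr(panel, "fst") <- fst
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("SNP panel: %d SNPs on %d chromosomes, %d sub-arrays, populations %s (FST %.3g)\n",
              nrow(x), length(unique(x$chrom)), length(unique(x$subarray)),
              paste(attr(x, "populations"), collapse = "/"), attr(x, "fst")))
  invisible(x)
}

#' Draw genotypes from panel population frequencies
#'
#' Genotypes are drawn per SNP under Hardy-Weinberg proportions for the
#' given population's allele-A frequency. Coding: AA / AB / BB.
#'
#' @param panel a `snp_panel`.
#' @param population one of the panel's population labels.
#' @return character vector of genotypes, one per panel SNP.
#' @export
draw_genotypes <- function(panel, population) {
  col <- paste0("freq_", population)
  if (!col %in% names(panel)) stop("unknown population: ", population)
  f <- panel[[col]]
  u <- stats::runif(nrow(panel))
  ifelse(u < f^2, "AA", ifelse(u < f^2 + 2 * f * (1 - f), "AB", "BB"))
}
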