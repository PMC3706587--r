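# SNP and assay quality control.

#' QC configuration
#'
#' Thresholds for the three QC rules: Hardy-Weinberg equilibrium in the
#' control (normal) samples at significance level `hwe_alpha` divided by
#' the number of SNPs analyzed, a minimum genotype call rate of 95% in
#' controls, and a minimum raw median intensity of 2000 instrument units
#' per allele channel for an assay to be accepted.
#'
#' @param hwe_alpha family-wise HWE significance level (default 0.05).
#' @param call_rate_min minimum control call rate (default 0.95).
#' @param min_median_intensity minimum per-channel raw median (default 2000).
#' @return list of class `qc_config`.
#' @export
qc_config <- function(hwe_alpha = 0.05, call_rate_min = 0.95,
                      min_median_intensity = 2000) {
  stopifnot(hwe_alpha > 0, call_rate_min > 0, min_median_intensity > 0)
  structure(list(hwe_alpha = hwe_alpha, call_rate_min = call_rate_min,
                 min_median_intensity = min_median_intensity),
            class = "qc_config")
}

#' Hardy-Weinberg chi-square test from genotype counts
#'
#' One-degree-of-freedom chi-square without continuity correction.
#' Monomorphic SNPs (allele frequency 0 or 1) have statistic 0, p = 1.
#'
#' @param n_aa,n_ab,n_bb genotype counts (vectorized).
#' @return list with `chisq` and `p` vectors.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  fa <- (2 * n_aa + n_ab) / (2 * n)
  e_aa <- n * fa^2
  e_ab <- n * 2 * fa * (1 - fa)
  e_bb <- n * (1 - fa)^2
  chisq <- ifelse(n == 0 | fa == 0 | fa == 1, 0,
                  (n_aa - e_aa)^2 / pmax(e_aa, .Machine$double.eps) +
                  (n_ab - e_ab)^2 / pmax(e_ab, .Machine$double.eps) +
                  (n_bb - e_bb)^2 / pmax(e_bb, .Machine$double.eps))
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' HWE SNP filter
#'
#' Removes SNPs whose HWE chi-square p-value in the control genotypes falls
#' below `hwe_alpha / n_snps_analyzed`, where the denominator counts SNPs
#' with at least one called genotype. SNPs with no called genotypes are
#' removed with reason "no data".
#'
#' @param genotypes SNPs x controls character matrix (AA/AB/BB/NC), row
#'   names = SNP ids.
#' @param hwe_alpha significance level before division.
#' @return list: `kept` (SNP ids), `table` (snp_id, chisq, p, decision,
#'   reason), `threshold`.
#' @export
hwe_filter <- function(genotypes, hwe_alpha = 0.05) {
  cnt <- function(g) rowSums(genotypes == g, na.rm = TRUE)
  n_aa <- cnt("AA"); n_ab <- cnt("AB"); n_bb <- cnt("BB")
  called <- n_aa + n_ab + n_bb
  analyzed <- sum(called > 0)
  threshold <- hwe_alpha / analyzed
  h <- hwe_test(n_aa, n_ab, n_bb)
  decision <- ifelse(called == 0, "removed",
                     ifelse(h$p < threshold, "removed", "kept"))
  reason <- ifelse(called == 0, "no data",
                   ifelse(decision == "removed", "HWE deviation", ""))
  tab <- data.frame(snp_id = rownames(genotypes), chisq = h$chisq, p = h$p,
                    decision = decision, reason = reason,
                    stringsAsFactors = FALSE)
  list(kept = tab$snp_id[tab$decision == "kept"], table = tab,
       threshold = threshold)
}

#' Call-rate SNP filter
#'
#' Keeps a SNP iff the fraction of non-missing (non-NC) genotype calls
#' across controls is at least `call_rate_min`.
#'
#' @inheritParams hwe_filter
#' @param call_rate_min minimum call rate.
#' @return list: `kept`, `table` (snp_id, call_rate, decision).
#' @export
call_rate_filter <- function(genotypes, call_rate_min = 0.95) {
  stopifnot(ncol(genotypes) >= 1)
  rate <- rowSums(matrix(genotypes %in% c("AA", "AB", "BB"),
                         nrow(genotypes))) / ncol(genotypes)
  tab <- data.frame(snp_id = rownames(genotypes), call_rate = rate,
                    decision = ifelse(rate >= call_rate_min, "kept",
                                      "removed"),
                    stringsAsFactors = FALSE)
  list(kept = tab$snp_id[tab$decision == "kept"], table = tab)
}

#' Assay intensity QC
#'
#' An assay fails if the raw median intensity of either allele channel is
#' below `min_median_intensity` (applied before any normalization).
#'
#' @param assay a `snp_assay` with raw intensities.
#' @param min_median_intensity threshold in raw instrument units.
#' @return list: `pass` (logical), `median_A`, `median_B`.
#' @export
assay_intensity_qc <- function(assay, min_median_intensity = 2000) {
  mA <- stats::median(assay$I_A)
  mB <- stats::median(assay$I_B)
  list(pass = mA >= min_median_intensity && mB >= min_median_intensity,
       median_A = mA, median_B = mB)
}

#' Combined SNP QC
#'
#' Applies the HWE filter then the call-rate filter to the control
#' genotypes; the kept set is the intersection and does not depend on
#' evaluation order.
#'
#' @inheritParams hwe_filter
#' @param config a [qc_config()].
#' @return list: `kept` SNP ids, `hwe`, `call_rate` (the per-rule results).
#' @export
snp_qc <- function(genotypes, config = qc_config()) {
  h <- hwe_filter(genotypes, config$hwe_alpha)
  cr <- call_rate_filter(genotypes, config$call_rate_min)
  list(kept = intersect(h$kept, cr$kept), hwe = h, call_rate = cr)
}
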