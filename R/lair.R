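# B-allele ratio and lesser allele intensity ratio (LAIR).

#' Informative SNP selection
#'
#' A SNP is informative for allelic-balance measurement iff the patient's
#' matched normal genotype is heterozygous (AB). Missing or no-call normal
#' genotypes make the SNP uninformative.
#'
#' @param normal_genotype character vector of AA/AB/BB/NC (NA allowed).
#' @return logical vector.
#' @export
select_informative <- function(normal_genotype) {
  !is.na(normal_genotype) & normal_genotype == "AB"
}

#' B-allele ratio
#'
#' `I_B / (I_A + I_B)`; undefined (NA) where the total intensity is not
#' positive.
#'
#' @param I_A,I_B channel intensities.
#' @return numeric vector in [0, 1] with NAs.
#' @export
compute_baf <- function(I_A, I_B) {
  tot <- I_A + I_B
  ifelse(tot > 0, I_B / tot, NA_real_)
}

#' Lesser allele intensity ratio
#'
#' The ratio of the weaker to the stronger allele intensity,
#' `min(I_A, I_B) / max(I_A, I_B)`: 1 for a balanced heterozygous SNP, 0
#' when only one allele is present (LOH). Equivalently the B-allele ratio
#' mirrored at its symmetry axis 0.5 and rescaled to [0, 1]:
#' `min(b, 1-b) / max(b, 1-b)`. For a segment with allele copies (p, q),
#' p >= q, the noise-free expectation is q/p. NA when both intensities
#' are 0.
#'
#' @param I_A,I_B channel intensities (only meaningful at informative SNPs).
#' @return numeric vector in [0, 1] with NAs.
#' @export
compute_lair <- function(I_A, I_B) {
  lo <- pmin(I_A, I_B)
  hi <- pmax(I_A, I_B)
  ifelse(hi > 0, lo / hi, NA_real_)
}

#' LAIR from a B-allele ratio
#'
#' @param b B-allele ratio in [0, 1].
#' @return `min(b, 1-b) / max(b, 1-b)`.
#' @export
lair_from_baf <- function(b) {
  lo <- pmin(b, 1 - b)
  hi <- pmax(b, 1 - b)
  ifelse(hi > 0, lo / hi, NA_real_)
}
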