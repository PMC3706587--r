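# Four-step normalization of two-channel SNP intensities:
#   I   quantile normalization between dyes (channels A and B)
#   II  quantile normalization between the 4 sub-arrays within a sample
#   III scale each channel's median to 1 within the sample
#   IV  per-SNP scaling to the reference normals plus correction of the
#       allele-specific bias (linear trend of total intensity on BAF).

# Quantile-normalize a list of numeric vectors against the mean quantile
# function. Equal-length vectors reduce to mean-of-sorted with tie ranks
# averaged; unequal lengths are handled by linear interpolation of each
# vector's empirical quantile function on [0, 1].
.quantile_normalize <- function(xs) {
  stopifnot(length(xs) >= 2)
  grid_u <- function(n) if (n == 1) 0.5 else (seq_len(n) - 1) / (n - 1)
  qf <- lapply(xs, function(x) list(u = grid_u(length(x)), s = sort(x)))
  target <- function(u) {
    rowMeans(vapply(qf, function(f) {
      if (length(f$s) == 1) rep(f$s, length(u))
      else stats::approx(f$u, f$s, xout = u, rule = 2)$y
    }, numeric(length(u))))
  }
  lapply(xs, function(x) {
    n <- length(x)
    r <- rank(x, ties.method = "average")
    u <- if (n == 1) 0.5 else (r - 1) / (n - 1)
    target(u)
  })
}

#' Step I: between-dye quantile normalization
#'
#' Makes the intensity distributions of the two dye channels identical by
#' replacing each quantile with the mean of the two channels' quantiles
#' (ties receive the mean of their ranks' targets). Preserves within-channel
#' rank order.
#'
#' @param assay a `snp_assay`.
#' @return the assay with normalized `I_A`, `I_B`.
#' @export
normalize_dye <- function(assay) {
  qn <- .quantile_normalize(list(assay$I_A, assay$I_B))
  assay$I_A <- qn[[1]]
  assay$I_B <- qn[[2]]
  attr(assay, "steps") <- c(attr(assay, "steps"), "dye")
  assay
}

#' Step II: between-sub-array quantile normalization
#'
#' Pools the two channels per sub-array and quantile-normalizes the
#' sub-array distributions within the sample, interpolating when sub-array
#' sizes differ. Empty sub-arrays are skipped with a warning.
#'
#' @param assay a `snp_assay` with a `subarray` column.
#' @return the assay with normalized intensities.
#' @export
normalize_between_subarrays <- function(assay) {
  subs <- sort(unique(assay$subarray))
  empty <- setdiff(seq_len(max(subs)), subs)
  if (length(empty) > 0)
    warning("sub-array(s) with 0 SNPs skipped: ", paste(empty, collapse = ","))
  if (length(subs) < 2) return(assay)
  pooled <- lapply(subs, function(s) {
    i <- assay$subarray == s
    c(assay$I_A[i], assay$I_B[i])
  })
  qn <- .quantile_normalize(pooled)
  for (k in seq_along(subs)) {
    i <- which(assay$subarray == subs[k])
    m <- length(i)
    assay$I_A[i] <- qn[[k]][seq_len(m)]
    assay$I_B[i] <- qn[[k]][m + seq_len(m)]
  }
  attr(assay, "steps") <- c(attr(assay, "steps"), "subarray")
  assay
}

#' Step III: within-sample median scaling
#'
#' Divides each channel by its median so that both allele channels have
#' sample median 1. Idempotent; errors on a zero median.
#'
#' @param assay a `snp_assay`.
#' @return the assay on the median-1 scale.
#' @export
normalize_within_sample <- function(assay) {
  mA <- stats::median(assay$I_A)
  mB <- stats::median(assay$I_B)
  if (mA <= 0 || mB <= 0) stop("degenerate channel")
  assay$I_A <- assay$I_A / mA
  assay$I_B <- assay$I_B / mB
  attr(assay, "steps") <- c(attr(assay, "steps"), "median")
  assay
}

#' Steps I-III for one sample
#'
#' @param assay a raw `snp_assay`.
#' @return normalized `snp_assay` (per-channel median 1).
#' @export
normalize_sample <- function(assay) {
  normalize_within_sample(normalize_between_subarrays(normalize_dye(assay)))
}

#' Step IV: per-SNP between-sample normalization
#'
#' Uses the reference normal samples to put every SNP on a common diploid
#' scale: (a) the total intensity of each SNP is scaled in all samples so
#' that the mean total across references equals 2; (b) the allele-specific
#' bias is corrected by fitting a least-squares line of total intensity on
#' B-allele ratio across the heterozygous references and dividing out the
#' fitted trend (each sample's total is multiplied by 2/predicted-total at
#' its own BAF), so the corrected total is independent of BAF at the
#' reference level. The B-allele ratio of every sample is preserved.
#' Homozygous-only SNPs receive scaling (a) only. SNPs with no usable
#' reference data are scaled by the global median total and flagged.
#'
#' @param samples named list of `snp_assay` (steps I-III applied), all on
#'   the same SNP panel; typically tumors plus normals.
#' @param reference_ids names of `samples` to use as reference normals
#'   (>= 2 required).
#' @param min_het minimum heterozygous references for the bias fit.
#' @return list: `samples` (corrected assays), `flagged` (SNP indices
#'   scaled by fallback).
#' @export
normalize_per_snp <- function(samples, reference_ids, min_het = 3) {
  stopifnot(length(reference_ids) >= 2,
            all(reference_ids %in% names(samples)))
  n_snp <- nrow(samples[[1]])
  A <- vapply(samples, function(s) s$I_A, numeric(n_snp))
  B <- vapply(samples, function(s) s$I_B, numeric(n_snp))
  tot <- A + B
  ref <- which(colnames(A) %in% reference_ids)
  ref_geno <- vapply(samples[reference_ids], function(s) s$genotype,
                     character(n_snp))

  # (a) scale reference mean total to 2
  ref_mean <- rowMeans(tot[, ref, drop = FALSE])
  flagged <- which(!(ref_mean > 0) | !is.finite(ref_mean))
  if (length(flagged) > 0)
    ref_mean[flagged] <- stats::median(tot[, ref, drop = FALSE], na.rm = TRUE) / 1
  fac <- 2 / ref_mean
  A <- A * fac
  B <- B * fac
  tot <- A + B

  # (b) divide out the BAF trend fitted on heterozygous references
  baf <- B / tot
  for (i in seq_len(n_snp)) {
    het <- which(ref_geno[i, ] == "AB")
    if (length(het) < min_het) next
    x <- baf[i, ref[het]]
    y <- tot[i, ref[het]]
    if (stats::var(x) < 1e-12) next
    fit <- stats::lm.fit(cbind(1, x), y)
    co <- fit$coefficients
    # predict only within the reference BAF range: the fit is supported
    # there, and unclamped extrapolation to BAF 0/1 (LOH regions in the
    # tumors) would amplify slope noise into large intensity distortions
    bafc <- pmin(pmax(baf[i, ], min(x)), max(x))
    pred <- co[1] + co[2] * bafc
    ok <- is.finite(pred) & pred > 0.1
    adj <- ifelse(ok, 2 / pred, 1)
    newtot <- tot[i, ] * adj
    A[i, ] <- newtot * (1 - baf[i, ])
    B[i, ] <- newtot * baf[i, ]
    A[i, !is.finite(baf[i, ])] <- 0
    B[i, !is.finite(baf[i, ])] <- 0
    tot[i, ] <- A[i, ] + B[i, ]
  }

  for (j in seq_along(samples)) {
    samples[[j]]$I_A <- A[, j]
    samples[[j]]$I_B <- B[, j]
    attr(samples[[j]], "steps") <- c(attr(samples[[j]], "steps"), "per_snp")
  }
  list(samples = samples, flagged = flagged)
}

#' QC + full normalization for a cohort
#'
#' Runs the SNP filters on the control genotypes, the assay intensity QC on
#' every raw assay, restricts all assays to the kept SNPs, applies
#' normalization steps I-III per sample and step IV across samples with the
#' normals as references.
#'
#' @param cohort a `snp_cohort` (or the list returned by [read_cohort()]).
#' @param config a [qc_config()].
#' @return list: `tumor`, `normal` (normalized assays), `panel` (kept
#'   SNPs), `qc` (filter tables), `assay_qc` (per-assay pass/fail),
#'   `flagged_snps`.
#' @export
normalize_cohort <- function(cohort, config = qc_config()) {
  qc <- snp_qc(cohort$normal_genotypes, config)
  keep <- cohort$panel$snp_id %in% qc$kept

  assay_qc <- data.frame(
    sample_id = rep(names(cohort$tumor), 2),
    role = rep(c("tumor", "normal"), each = length(cohort$tumor)),
    pass = NA, median_A = NA_real_, median_B = NA_real_,
    stringsAsFactors = FALSE)
  k <- 1
  for (role in c("tumor", "normal")) for (id in names(cohort$tumor)) {
    q <- assay_intensity_qc(cohort[[role]][[id]], config$min_median_intensity)
    i <- assay_qc$role == role & assay_qc$sample_id == id
    assay_qc$pass[i] <- q$pass
    assay_qc$median_A[i] <- q$median_A
    assay_qc$median_B[i] <- q$median_B
  }

  sub <- function(a) {
    out <- a[keep, , drop = FALSE]
    rownames(out) <- NULL
    attributes(out)[c("sample_id", "role")] <-
      attributes(a)[c("sample_id", "role")]
    class(out) <- c("snp_assay", "data.frame")
    out
  }
  tumors <- lapply(cohort$tumor, function(a) normalize_sample(sub(a)))
  normals <- lapply(cohort$normal, function(a) normalize_sample(sub(a)))
  names(normals) <- paste0(names(normals), "_N")

  all_samples <- c(tumors, normals)
  res <- normalize_per_snp(all_samples, reference_ids = names(normals))
  nt <- length(tumors)
  panel <- cohort$panel[keep, , drop = FALSE]
  class(panel) <- c("snp_panel", "data.frame")
  list(tumor = res$samples[seq_len(nt)],
       normal = res$samples[nt + seq_along(normals)],
       panel = panel, qc = qc, assay_qc = assay_qc,
       flagged_snps = res$flagged)
}
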