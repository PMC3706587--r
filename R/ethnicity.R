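# Ancestry assignment from genotypes by PCA against a reference panel.

#' Generate a reference genotype panel
#'
#' Draws reference individuals per population from the panel's population
#' allele frequencies under Hardy-Weinberg proportions, coded 0/1/2 copies
#' of allele A. Used as the known-ancestry anchor for [ethnicity_pca()] in
#' synthetic cohorts.
#'
#' @param panel a `snp_panel`.
#' @param n_per_pop individuals per population.
#' @param seed integer seed.
#' @return list: `geno` (individuals x SNPs matrix), `labels`.
#' @export
generate_reference_panel <- function(panel, n_per_pop = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- attr(panel, "populations")
  geno <- do.call(rbind, lapply(pops, function(p) {
    f <- panel[[paste0("freq_", p)]]
    t(vapply(seq_len(n_per_pop), function(i)
      stats::rbinom(length(f), 2, f), numeric(length(f))))
  }))
  colnames(geno) <- panel$snp_id
  labels <- rep(pops, each = n_per_pop)
  rownames(geno) <- paste0(labels, "_", seq_len(nrow(geno)))
  list(geno = geno, labels = labels)
}

#' Genotype dosage coding
#'
#' Converts AA/AB/BB calls to 0/1/2 copies of allele A (NC/NA become NA).
#'
#' @param genotypes character matrix or vector.
#' @return numeric matrix/vector of dosages.
#' @export
genotype_dosage <- function(genotypes) {
  d <- ifelse(genotypes == "AA", 2,
              ifelse(genotypes == "AB", 1,
                     ifelse(genotypes == "BB", 0, NA_real_)))
  if (is.matrix(genotypes))
    dimnames(d) <- dimnames(genotypes)
  d
}

#' Ancestry assignment by PCA against a reference panel
#'
#' Combines patient and reference genotype dosages on the shared SNPs,
#' centers and scales per SNP, takes the top two principal components, and
#' assigns each patient the label of the nearest reference-population
#' centroid in PC space. Populations listed in `merge` are merged a priori
#' (e.g. Chinese and Japanese references into one Asian cluster).
#'
#' @param patient_geno patients x SNPs dosage matrix (0/1/2; columns named
#'   by SNP id). Character genotype matrices are converted.
#' @param ref_geno reference individuals x SNPs dosage matrix.
#' @param ref_labels population label per reference individual.
#' @param merge named character vector mapping reference labels to merged
#'   cluster labels (e.g. `c(CHB = "ASI", JPT = "ASI")`); unlisted labels
#'   pass through.
#' @param min_shared minimum shared SNPs (error below).
#' @return list of class `ethnicity_pca`: `labels` (per patient), `scores`
#'   (PC1/PC2 for patients and references), `centroids`.
#' @export
ethnicity_pca <- function(patient_geno, ref_geno, ref_labels,
                          merge = c(CHB = "ASI", JPT = "ASI"),
                          min_shared = 100) {
  if (is.character(patient_geno)) patient_geno <- genotype_dosage(patient_geno)
  if (is.character(ref_geno)) ref_geno <- genotype_dosage(ref_geno)
  shared <- intersect(colnames(patient_geno), colnames(ref_geno))
  if (length(shared) < min_shared) stop("insufficient markers")
  X <- rbind(patient_geno[, shared, drop = FALSE],
             ref_geno[, shared, drop = FALSE])
  X[is.na(X)] <- mean(X, na.rm = TRUE)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd < 1e-9] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd, "/")
  pc <- stats::prcomp(Xs, rank. = 2, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1:2, drop = FALSE]
  np <- nrow(patient_geno)
  lab <- ref_labels
  m <- merge[lab]
  lab[!is.na(m)] <- m[!is.na(m)]
  ref_scores <- scores[np + seq_along(lab), , drop = FALSE]
  cent <- do.call(rbind, lapply(split(seq_along(lab), lab), function(i)
    colMeans(ref_scores[i, , drop = FALSE])))
  pat_scores <- scores[seq_len(np), , drop = FALSE]
  d2 <- outer(seq_len(np), seq_len(nrow(cent)), Vectorize(function(i, k)
    sum((pat_scores[i, ] - cent[k, ])^2)))
  labels <- rownames(cent)[apply(d2, 1, which.min)]
  names(labels) <- rownames(patient_geno)
  out <- list(labels = labels, scores = scores, centroids = cent)
  class(out) <- "ethnicity_pca"
  out
}

#' @export
print.ethnicity_pca <- function(x, ...) {
  cat("Ancestry assignment:\n")
  print(table(x$labels))
  invisible(x)
}
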