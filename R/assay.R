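# Two-channel intensity simulation and cohort assembly.

# (p,q) state of each panel SNP under a truth profile
.truth_state_at_snps <- function(truth, panel) {
  p <- integer(nrow(panel)); q <- integer(nrow(panel))
  for (ch in unique(panel$chrom)) {
    idx <- which(panel$chrom == ch)
    segs <- truth$segments[truth$segments$chrom == ch, , drop = FALSE]
    segs <- segs[order(segs$start), , drop = FALSE]
    k <- findInterval(panel$pos[idx], segs$start)
    p[idx] <- segs$p[k]
    q[idx] <- segs$q[k]
  }
  data.frame(p = p, q = q)
}

#' Simulate a two-channel SNP assay
#'
#' Converts a ground-truth (p,q) profile into raw two-dye intensities for
#' every panel SNP. At SNPs heterozygous in the matched normal, the major
#' and minor allele counts are assigned to channels A/B uniformly at random
#' per SNP (so the B-allele ratio is symmetric around 0.5, as in real
#' data); homozygous SNPs carry all copies on the called allele. The raw
#' intensity of a channel is
#' `gain * dose * dye_bias * subarray_factor * exp(N(0, sd_m)) + N(0, sd_a)`,
#' floored at zero; the dye bias applies to channel A only. The matched
#' normal assay uses doses (1,1) at heterozygous and (2,0) at homozygous
#' SNPs.
#'
#' @param truth a [generate_truth_profile()] result.
#' @param panel a `snp_panel`.
#' @param normal_genotype character vector of AA/AB/BB (one per panel SNP).
#' @param config a [sim_config()] providing the noise model.
#' @param role "tumor" or "normal".
#' @return data frame of class `snp_assay` with columns `snp_id`, `I_A`,
#'   `I_B`, `genotype`, `subarray` and attributes `sample_id`, `role`.
#' @export
simulate_assay <- function(truth, panel, normal_genotype, config,
                           role = c("tumor", "normal")) {
  role <- match.arg(role)
  if (config$sd_m < 0 || config$sd_a < 0) stop("negative noise sd")
  stopifnot(length(normal_genotype) == nrow(panel),
            all(normal_genotype %in% c("AA", "AB", "BB", "NC")))
  n <- nrow(panel)

  if (role == "tumor") {
    st <- .truth_state_at_snps(truth, panel)
    major <- pmax(st$p, st$q); minor <- pmin(st$p, st$q)
  } else {
    major <- rep(1L, n); minor <- rep(1L, n) # diploid normal (1,1)/(2,0)
  }

  het <- normal_genotype == "AB"
  flip <- stats::runif(n) < 0.5 # major allele -> channel A or B, per SNP
  dose_A <- numeric(n); dose_B <- numeric(n)
  dose_A[het] <- ifelse(flip[het], major[het], minor[het])
  dose_B[het] <- ifelse(flip[het], minor[het], major[het])
  homA <- normal_genotype == "AA"
  homB <- normal_genotype %in% c("BB", "NC")
  tot <- major + minor
  if (role == "normal") tot <- rep(2L, n)
  dose_A[homA] <- tot[homA]; dose_B[homA] <- 0
  dose_B[homB] <- tot[homB]; dose_A[homB] <- 0
  if (role == "normal") { dose_A[het] <- 1; dose_B[het] <- 1 }

  sub_f <- config$subarray_factors[panel$subarray]
  noise <- function(k) exp(stats::rnorm(k, 0, config$sd_m))
  I_A <- config$gain * dose_A * config$dye_bias * sub_f * noise(n) +
    stats::rnorm(n, 0, config$sd_a)
  I_B <- config$gain * dose_B * sub_f * noise(n) +
    stats::rnorm(n, 0, config$sd_a)
  I_A <- pmax(I_A, 0); I_B <- pmax(I_B, 0)

  geno <- ifelse(dose_A > 0 & dose_B > 0, "AB",
                 ifelse(dose_B == 0 & dose_A > 0, "AA",
                        ifelse(dose_A == 0 & dose_B > 0, "BB", "NC")))
  out <- data.frame(snp_id = panel$snp_id, I_A = I_A, I_B = I_B,
                    genotype = geno, subarray = panel$subarray,
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- truth$sample_id
  attr(out, "role") <- role
  class(out) <- c("snp_assay", "data.frame")
  out
}

#' Simulate a full tumor/normal cohort
#'
#' Generates the SNP panel, per-sample ancestry, ground-truth profiles,
#' matched-normal genotypes, tumor and normal raw assays, a clinical table
#' and a DNA-index table, all from one seed. This is the entry point used
#' by the tests and by `lairseg simulate` on the command line.
#'
#' @param config a [sim_config()].
#' @param genome a [genome_layout()].
#' @return list of class `snp_cohort` with elements `panel`, `genome`,
#'   `truth` (list of truth profiles), `tumor`, `normal` (lists of
#'   `snp_assay`), `clinical` (data frame), `di` (sample_id, true_di,
#'   measured_di), `config`.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_per_group = c(a = 3, b = 2), n_snps = 300, seed = 7)
#' coh <- simulate_cohort(cfg)
#' coh$di
#' }
#' @export
simulate_cohort <- function(config = sim_config(), genome = genome_layout()) {
  set.seed(config$seed)
  panel <- generate_snp_panel(config$n_snps, genome, fst = config$fst)

  groups <- rep(names(config$n_per_group), config$n_per_group)
  n <- length(groups)
  ids <- sprintf("t%03d", seq_len(n))
  pops <- sample(names(config$pop_probs), n, replace = TRUE,
                 prob = config$pop_probs)

  truth <- vector("list", n); names(truth) <- ids
  tumor <- vector("list", n); names(tumor) <- ids
  normal <- vector("list", n); names(normal) <- ids
  geno <- matrix("", nrow(panel), n, dimnames = list(panel$snp_id, ids))

  for (i in seq_len(n)) {
    truth[[i]] <- generate_truth_profile(config, groups[i], pops[i],
                                         genome, sample_id = ids[i])
    g <- draw_genotypes(panel, pops[i])
    geno[, i] <- g
    tumor[[i]] <- simulate_assay(truth[[i]], panel, g, config, "tumor")
    normal[[i]] <- simulate_assay(truth[[i]], panel, g, config, "normal")
    attr(normal[[i]], "sample_id") <- ids[i]
  }

  true_di <- vapply(truth, function(x) x$true_di, 0)
  measured_di <- true_di * (1 + stats::rnorm(n, 0, config$sd_di))
  clinical <- data.frame(
    sample_id = ids,
    histology = groups,
    growth_pattern = sample(c("exophytic", "barrel"), n, TRUE, c(0.49, 0.51)),
    infiltration_depth = sample(c("0-5", "6-10", "11-15", ">15"), n, TRUE,
                                c(0.05, 0.14, 0.20, 0.61)),
    lymph_nodes = stats::rbinom(n, 1, 0.42),
    parametria = stats::rbinom(n, 1, 0.30),
    vaso_invasion = ifelse(stats::runif(n) < 0.074, NA_integer_,
                           stats::rbinom(n, 1, 0.52)),
    ethnic_cluster = pops,
    di = measured_di,
    stringsAsFactors = FALSE
  )
  di <- data.frame(sample_id = ids, true_di = unname(true_di),
                   measured_di = unname(measured_di),
                   stringsAsFactors = FALSE)
  out <- list(panel = panel, genome = genome, truth = truth, tumor = tumor,
              normal = normal, normal_genotypes = geno, clinical = clinical,
              di = di, config = config)
  class(out) <- "snp_cohort"
  out
}

#' @export
print.snp_cohort <- function(x, ...) {
  cat(sprintf("Synthetic SNP cohort: %d tumors (+matched normals), %d SNPs, groups: %s\n",
              length(x$tumor), nrow(x$panel),
              paste(names(x$config$n_per_group), x$config$n_per_group,
                    sep = "=", collapse = ", ")))
  cat(sprintf("DNA index range %.2f-%.2f\n", min(x$di$measured_di),
              max(x$di$measured_di)))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Emits `panel.tsv`, `truth_segments.tsv` (sample_id, chrom, start, end,
#' p, q; 1-based inclusive), `di.tsv` (sample_id, true_di, measured_di),
#' `clinical.csv`, and one intensity TSV per assay under `intensities/`
#' (`<sample>_tumor.tsv`, `<sample>_normal.tsv` with columns snp_id, I_A,
#' I_B, genotype, subarray). Output is byte-identical for a fixed seed.
#'
#' @param cohort a `snp_cohort`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, out_dir) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  dir.create(file.path(out_dir, "intensities"), showWarnings = FALSE)
  wt <- function(d, f) {
    utils::write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  files <- c(
    wt(as.data.frame(cohort$panel), file.path(out_dir, "panel.tsv")),
    wt(do.call(rbind, lapply(cohort$truth, function(t)
      data.frame(sample_id = t$sample_id, t$segments))),
      file.path(out_dir, "truth_segments.tsv")),
    wt(cohort$di, file.path(out_dir, "di.tsv"))
  )
  utils::write.csv(cohort$clinical, file.path(out_dir, "clinical.csv"),
                   row.names = FALSE)
  files <- c(files, file.path(out_dir, "clinical.csv"))
  for (id in names(cohort$tumor)) {
    files <- c(files,
      wt(as.data.frame(cohort$tumor[[id]]),
         file.path(out_dir, "intensities", paste0(id, "_tumor.tsv"))),
      wt(as.data.frame(cohort$normal[[id]]),
         file.path(out_dir, "intensities", paste0(id, "_normal.tsv"))))
  }
  invisible(files)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @param genome the genome layout the cohort was simulated on.
#' @return a list with the same core elements as [simulate_cohort()]
#'   (`panel`, `tumor`, `normal`, `normal_genotypes`, `clinical`, `di`,
#'   `truth_segments`).
#' @export
read_cohort <- function(dir, genome = genome_layout()) {
  rd <- function(f) utils::read.table(f, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE,
                                      colClasses = NA)
  panel <- rd(file.path(dir, "panel.tsv"))
  class(panel) <- c("snp_panel", "data.frame")
  attr(panel, "populations") <-
    sub("^freq_", "", grep("^freq_", names(panel), value = TRUE))
  di <- rd(file.path(dir, "di.tsv"))
  clinical <- utils::read.csv(file.path(dir, "clinical.csv"),
                              stringsAsFactors = FALSE)
  truth_segments <- rd(file.path(dir, "truth_segments.tsv"))
  ids <- di$sample_id
  tumor <- list(); normal <- list()
  geno <- matrix("", nrow(panel), length(ids),
                 dimnames = list(panel$snp_id, ids))
  for (id in ids) {
    tu <- rd(file.path(dir, "intensities", paste0(id, "_tumor.tsv")))
    no <- rd(file.path(dir, "intensities", paste0(id, "_normal.tsv")))
    for (d in list(tu, no))
      if (!identical(d$snp_id, panel$snp_id))
        stop("intensity file SNP set mismatch for sample ", id)
    attr(tu, "sample_id") <- id; attr(tu, "role") <- "tumor"
    attr(no, "sample_id") <- id; attr(no, "role") <- "normal"
    class(tu) <- c("snp_assay", "data.frame")
    class(no) <- c("snp_assay", "data.frame")
    tumor[[id]] <- tu; normal[[id]] <- no
    geno[, id] <- no$genotype
  }
  list(panel = panel, genome = genome, tumor = tumor, normal = normal,
       normal_genotypes = geno, clinical = clinical, di = di,
       truth_segments = truth_segments)
}
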