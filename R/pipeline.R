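# End-to-end pipeline: QC -> normalize -> LAIR -> segment -> call ->
# cohort tests -> frequency profiles.

#' Validate pipeline inputs
#'
#' Checks that every tumor has a matched normal (or designated stroma
#' reference), that every assay covers exactly the panel SNP set, and that
#' a DNA index is present for every tumor.
#'
#' @param cohort a `snp_cohort` or the list returned by [read_cohort()].
#' @return invisibly TRUE; errors describe every offending sample.
#' @export
validate_inputs <- function(cohort) {
  ids <- names(cohort$tumor)
  missing_ref <- setdiff(ids, names(cohort$normal))
  if (length(missing_ref) > 0)
    stop("tumor(s) without matched normal or stroma reference: ",
         paste(missing_ref, collapse = ", "))
  for (id in ids) {
    for (role in c("tumor", "normal")) {
      a <- cohort[[role]][[id]]
      bad <- sum(!a$snp_id %in% cohort$panel$snp_id)
      if (bad > 0)
        stop(bad, " unknown snp_id(s) in ", role, " assay of ", id)
      if (!setequal(a$snp_id, cohort$panel$snp_id))
        stop("assay of ", id, " (", role, ") does not cover the panel")
    }
  }
  missing_di <- setdiff(ids, cohort$di$sample_id[
    is.finite(cohort$di$measured_di)])
  if (length(missing_di) > 0)
    stop("tumor(s) without DNA index: ", paste(missing_di, collapse = ", "))
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: SNP/assay QC, four-step normalization, informative
#' SNP selection and LAIR, per-sample segmentation with LAIR
#' sub-segmentation, DNA-index-anchored allelic-state calling, breakpoint
#' unification, the genome-wide parameter scan, arm-level tests with FDR
#' for the scan's significant results, and frequency profiles. All
#' randomness derives from `seed`.
#'
#' @param cohort a `snp_cohort` or [read_cohort()] result.
#' @param qc a [qc_config()].
#' @param seg a [seg_params()].
#' @param c_max,di_tolerance caller settings (see [caller_params()]).
#' @param parameters,n_perm_scan settings of [run_parameter_scan()].
#' @param arm_fdr_alpha genome-wide p threshold triggering arm-level
#'   localization.
#' @param reference_panel optional list with `geno` (individuals x SNPs
#'   dosage matrix) and `labels`, as from [generate_reference_panel()];
#'   when given, ethnic clusters are (re)assigned by [ethnicity_pca()] on
#'   the control genotypes instead of taken from the clinical table.
#' @param seed integer master seed.
#' @param out_dir if non-NULL, result tables are written there
#'   (segments.tsv, calls.tsv, results.tsv, freq.tsv, qc_report.tsv,
#'   manifest.txt).
#' @param verbose print one progress line per stage.
#' @return list of class `lairseg_result`: `norm`, `segments`, `calls`,
#'   `cohort` (unified matrices), `scan`, `arm_tests`, `freq`, `manifest`.
#' @export
run_pipeline <- function(cohort, qc = qc_config(), seg = seg_params(),
                         c_max = 8, di_tolerance = 0.15,
                         parameters = c("histology", "growth_pattern",
                                        "lymph_nodes", "parametria",
                                        "vaso_invasion"),
                         n_perm_scan = 1000, arm_fdr_alpha = 0.05,
                         reference_panel = NULL,
                         seed = 1, out_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  validate_inputs(cohort)
  if (!is.null(reference_panel)) {
    pat <- t(genotype_dosage(cohort$normal_genotypes))
    eth <- ethnicity_pca(pat, reference_panel$geno, reference_panel$labels)
    cohort$clinical$ethnic_cluster <-
      unname(eth$labels[cohort$clinical$sample_id])
    say("stage ethnicity: %s", paste(names(table(eth$labels)),
                                     table(eth$labels), sep = "=",
                                     collapse = ", "))
  }
  manifest <- list(seed = seed, stages = character(0),
                   params = list(qc = qc, seg = seg, c_max = c_max,
                                 di_tolerance = di_tolerance,
                                 n_perm_scan = n_perm_scan))
  stage <- function(name) manifest$stages <<- c(manifest$stages, name)

  say("stage qc+normalize: %d tumors, %d SNPs", length(cohort$tumor),
      nrow(cohort$panel))
  norm <- normalize_cohort(cohort, qc)
  stage("qc"); stage("normalize")
  say("  kept %d/%d SNPs", nrow(norm$panel), nrow(cohort$panel))

  ids <- names(norm$tumor)
  keep_snp <- cohort$panel$snp_id %in% norm$panel$snp_id
  segments <- list(); calls <- list()
  di <- cohort$di
  for (id in ids) {
    geno <- cohort$normal_genotypes[keep_snp, id]
    seg$seed <- seed + match(id, ids)
    prof <- segment_sample(norm$tumor[[id]], geno, norm$panel,
                           cohort$genome, seg)
    prof$sample_id <- id
    segments[[id]] <- prof
    cp <- caller_params(di = di$measured_di[di$sample_id == id],
                        c_max = c_max, di_tolerance = di_tolerance,
                        k_min = seg$k_min)
    calls[[id]] <- call_profile(prof, cp)
  }
  stage("lair"); stage("segment"); stage("call")
  say("stage segment+call: done for %d samples", length(ids))

  cmat <- unify_breakpoints(calls, cohort$genome, norm$panel)
  stage("unify")
  say("stage cohort-test: %d unified cells", nrow(cmat$grid))
  scan <- run_parameter_scan(cmat, cohort$clinical, parameters = parameters,
                             n_perm = n_perm_scan, seed = seed)
  stage("cohort-test")

  arm_tests <- list()
  sig <- which(!is.na(scan$p) & scan$p < arm_fdr_alpha)
  for (i in sig) {
    key <- paste(scan$parameter[i], scan$measure[i], sep = ".")
    arm_tests[[key]] <- arm_tests_with_fdr(
      cmat, cohort$clinical, scan$parameter[i], scan$measure[i],
      n_perm = n_perm_scan, seed = seed)
  }
  freq <- frequency_profiles(cmat)
  stage("freq")

  out <- list(norm = norm, segments = segments, calls = calls,
              cohort = cmat, scan = scan, arm_tests = arm_tests,
              freq = freq, manifest = manifest)
  class(out) <- "lairseg_result"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(d, f) utils::write.table(
      d, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(do.call(rbind, lapply(segments, as.data.frame)), "segments.tsv")
    wt(do.call(rbind, lapply(calls, as.data.frame)), "calls.tsv")
    wt(scan, "results.tsv")
    qc_rep <- merge(norm$qc$hwe$table,
                    norm$qc$call_rate$table[, c("snp_id", "call_rate")],
                    by = "snp_id")
    wt(qc_rep, "qc_report.tsv")
    wt(norm$assay_qc, "assay_qc.tsv")
    wt(freq$freq, "freq.tsv")
    if (length(arm_tests) > 0)
      wt(do.call(rbind, lapply(names(arm_tests), function(k)
        cbind(test = k, as.data.frame(arm_tests[[k]])))), "arm_tests.tsv")
    writeLines(c(sprintf("seed: %d", seed),
                 sprintf("stages: %s", paste(manifest$stages, collapse = " -> ")),
                 sprintf("samples: %d", length(ids)),
                 sprintf("snps_kept: %d", nrow(norm$panel))),
               file.path(out_dir, "manifest.txt"))
  }
  out
}

#' @export
print.lairseg_result <- function(x, ...) {
  cat(sprintf("lairseg pipeline result: %d samples, %d kept SNPs, %d unified cells\n",
              length(x$calls), nrow(x$norm$panel), nrow(x$cohort$grid)))
  cat(sprintf("stages: %s\n", paste(x$manifest$stages, collapse = " -> ")))
  ok <- !is.na(x$scan$p)
  if (any(ok)) {
    cat("Genome-wide scan (top results):\n")
    s <- x$scan[ok, c("parameter", "measure", "Q", "p", "confounders")]
    print(utils::head(s[order(s$p), ], 5), row.names = FALSE)
  }
  invisible(x)
}
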