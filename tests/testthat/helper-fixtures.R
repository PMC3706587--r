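# Shared fixtures: tiny genomes, assays and cohorts built in code.

# single-chromosome toy genome
toy_genome <- function(length = 300L, centromere = 100L, chrom = "1") {
  g <- data.frame(chrom = chrom, length = as.integer(length),
                  centromere = as.integer(centromere),
                  acrocentric = FALSE, stringsAsFactors = FALSE)
  class(g) <- c("genome_layout", "data.frame")
  g
}

# snp_assay from explicit intensities
make_assay <- function(I_A, I_B, genotype = rep("AB", length(I_A)),
                       subarray = rep(1L, length(I_A)),
                       sample_id = "s1", role = "tumor") {
  a <- data.frame(snp_id = sprintf("snp%05d", seq_along(I_A)),
                  I_A = I_A, I_B = I_B, genotype = genotype,
                  subarray = subarray, stringsAsFactors = FALSE)
  attr(a, "sample_id") <- sample_id
  attr(a, "role") <- role
  class(a) <- c("snp_assay", "data.frame")
  a
}

# evenly spaced panel on a toy genome
make_panel <- function(n, genome = toy_genome(), subarray = rep(1L, n)) {
  pos <- round(seq(1, genome$length[1], length.out = n))
  p <- data.frame(snp_id = sprintf("snp%05d", seq_len(n)),
                  chrom = genome$chrom[1], pos = as.integer(pos),
                  subarray = as.integer(subarray), stringsAsFactors = FALSE)
  class(p) <- c("snp_panel", "data.frame")
  p
}

# truth profile from an explicit segment table
make_truth <- function(segments, sample_id = "s1", group = "g1",
                       population = "EUR", genome = genome_layout()) {
  prof <- list(sample_id = sample_id, segments = segments, group = group,
               population = population, wgd = FALSE)
  class(prof) <- "truth_profile"
  prof$true_di <- compute_true_di(prof, genome)
  prof
}

# minimal allelic_calls-like table for cohort-level tests
make_calls <- function(chrom, start_bp, end_bp, r, lair_seg = NA_real_,
                       p = 1L, q = 1L, sample_id = "s1") {
  n <- length(start_bp)
  rec <- function(x) rep_len(x, n)
  data.frame(sample_id = sample_id, chrom = rec(chrom),
             start_bp = start_bp, end_bp = end_bp,
             r = rec(r), lair_seg = rec(lair_seg),
             p = rec(p), q = rec(q), c = rec(p) + rec(q),
             balance_state = .bal(rec(p), rec(q)),
             gainloss = classify_gain_loss(rec(r)),
             stringsAsFactors = FALSE)
}

.bal <- function(p, q) {
  ifelse(p + q == 0, "unknown",
         ifelse(q == 0, "LOH", ifelse(p == q, "balanced", "imbalance")))
}

# small synthetic cohort for pipeline-level tests
small_cohort <- function(n1 = 4, n2 = 3, n_snps = 400, seed = 42, ...) {
  cfg <- sim_config(n_per_group = c(squamous = n1, adenosquamous = n2),
                    n_snps = n_snps, seed = seed, ...)
  simulate_cohort(cfg)
}
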