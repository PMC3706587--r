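test_that("breakpoint unification takes the union of sample breakpoints", {
  tg <- toy_genome(length = 300, centromere = 100)
  calls <- list(
    s1 = make_calls("1", c(1, 101), c(100, 300), r = c(0.8, 1.1),
                    sample_id = "s1"),
    s2 = make_calls("1", c(1, 201), c(200, 300), r = c(1.0, 1.3),
                    sample_id = "s2"))
  cm <- unify_breakpoints(calls, tg)
  expect_equal(cm$grid$start, c(1, 101, 201))
  expect_equal(cm$grid$end, c(100, 200, 300))
  # each sample's values copied across the cells its segments span
  expect_equal(unname(cm$r["s1", ]), c(0.8, 1.1, 1.1))
  expect_equal(unname(cm$r["s2", ]), c(1.0, 1.0, 1.3))
  # single sample: grid equals its own segmentation
  cm1 <- unify_breakpoints(calls["s1"], tg)
  expect_equal(cm1$grid$end, c(100, 300))
})

test_that("reindexing conserves each sample's length-weighted mean of every measure", {
  coh <- small_cohort(n1 = 3, n2 = 2, n_snps = 300, seed = 51)
  norm <- normalize_cohort(coh)
  keep <- coh$panel$snp_id %in% norm$panel$snp_id
  calls <- list()
  for (id in names(norm$tumor)) {
    prof <- segment_sample(norm$tumor[[id]], coh$normal_genotypes[keep, id],
                           norm$panel, coh$genome,
                           seg_params(n_perm = 300, seed = 1))
    calls[[id]] <- call_profile(prof, caller_params(
      di = coh$di$measured_di[coh$di$sample_id == id]))
  }
  cm <- unify_breakpoints(calls, coh$genome, norm$panel)
  glen <- cm$grid$end - cm$grid$start + 1
  for (id in names(calls)) {
    seg_len <- calls[[id]]$end_bp - calls[[id]]$start_bp + 1
    for (meas in c("r", "c")) {
      before <- sum(seg_len * calls[[id]][[meas]]) / sum(seg_len)
      M <- if (meas == "r") cm$r else cm$cn
      after <- sum(glen * M[id, ]) / sum(glen)
      expect_equal(after, before, tolerance = 1e-12)
    }
  }
})

test_that("grid cells never span the centromere and arms are labeled correctly", {
  tg <- toy_genome(length = 300, centromere = 150)
  calls <- list(s1 = make_calls("1", 1, 300, r = 1, sample_id = "s1"))
  cm <- unify_breakpoints(calls, tg)
  expect_equal(cm$grid$end, c(150, 300))
  expect_equal(cm$grid$arm, c("p", "q"))
  expect_equal(assign_arm("1", c(1, 150, 151, 300), tg),
               c("p", "p", "q", "q"))
})

test_that("acrocentric p arms have no SNPs and drop out of arm-level testing", {
  coh <- small_cohort(n1 = 3, n2 = 3, n_snps = 400, seed = 61)
  tr <- truth_cohort_matrix(coh$truth, coh$genome)
  # attach panel SNP counts
  tr$grid$n_snps <- vapply(seq_len(nrow(tr$grid)), function(i)
    sum(coh$panel$chrom == tr$grid$chrom[i] &
          coh$panel$pos >= tr$grid$start[i] &
          coh$panel$pos <= tr$grid$end[i]), 0L)
  arm_snps <- tapply(tr$grid$n_snps, paste0(tr$grid$chrom, tr$grid$arm), sum)
  for (a in c("13p", "14p", "15p", "21p", "22p"))
    expect_equal(unname(arm_snps[a]), 0L)
  clin <- data.frame(sample_id = rownames(tr$r),
                     histology = vapply(coh$truth, function(t) t$group, ""),
                     ethnic_cluster = vapply(coh$truth,
                                             function(t) t$population, ""),
                     di = coh$di$measured_di)
  tab <- arm_tests_with_fdr(tr, clin, "histology", "continuous_cn",
                            Z = NULL, n_perm = 50, seed = 1)
  expect_false(any(c("13p", "14p", "15p", "21p", "22p") %in% tab$arm))
})

test_that("frequency profiles count event fractions with threshold bins", {
  tg <- toy_genome(length = 100, centromere = 40)
  mk <- function(id, state, gl) {
    d <- make_calls("1", 1, 100, r = 1, sample_id = id)
    d$balance_state <- state
    d$gainloss <- gl
    d
  }
  calls <- c(lapply(1:4, function(i) mk(paste0("l", i), "LOH", "loss")),
             lapply(1:6, function(i) mk(paste0("b", i), "balanced",
                                        "neutral")))
  names(calls) <- vapply(calls, function(d) d$sample_id[1], "")
  fp <- frequency_profiles(unify_breakpoints(calls, tg))
  expect_equal(fp$freq$frac_loh, c(0.4, 0.4))
  expect_equal(as.character(fp$freq$frac_loh_bin), c(">30%", ">30%"))
  expect_equal(fp$freq$frac_gain, c(0, 0))
  # invariant to sample order
  fp2 <- frequency_profiles(unify_breakpoints(rev(calls), tg))
  expect_equal(fp2$freq$frac_loh, fp$freq$frac_loh)
})

test_that("balance-state matrices one-hot encode with mean imputation", {
  tg <- toy_genome(length = 100, centromere = 40)
  calls <- list(
    a = make_calls("1", 1, 100, r = 1, p = 2L, q = 0L, sample_id = "a"),
    b = make_calls("1", 1, 100, r = 1, p = 1L, q = 1L, sample_id = "b"),
    c = make_calls("1", 1, 100, r = 0.2, p = 0L, q = 0L, sample_id = "c"))
  cm <- unify_breakpoints(calls, tg)
  X <- measure_matrix(cm, "balance_state")
  # 2 cells x 3 states = 6 columns; rows a, b known; c unknown -> imputed
  expect_equal(dim(X), c(3, 6))
  expect_equal(unname(X["a", 3]), 0) # a is not imbalanced (cols 3:4)
  bal_cols <- 1:2; loh_cols <- 5:6
  expect_equal(unname(X["b", bal_cols]), c(1, 1))
  expect_equal(unname(X["a", loh_cols]), c(1, 1))
  expect_equal(unname(X["c", bal_cols]), c(0.5, 0.5)) # mean of known
})
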