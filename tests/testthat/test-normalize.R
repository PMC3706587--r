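test_that("between-dye quantile normalization equalizes the channel distributions", {
  a <- make_assay(c(1, 2, 3), c(2, 4, 6))
  out <- normalize_dye(a)
  expect_equal(sort(out$I_A), c(1.5, 3, 4.5))
  expect_equal(sort(out$I_B), c(1.5, 3, 4.5))
  # identical channels are unchanged
  b <- make_assay(c(5, 1, 3), c(5, 1, 3))
  outb <- normalize_dye(b)
  expect_equal(outb$I_A, b$I_A)
  expect_equal(outb$I_B, b$I_B)
  # post-condition on arbitrary input
  set.seed(1)
  cc <- make_assay(rexp(101, 1 / 1000), rexp(101, 1 / 1300))
  outc <- normalize_dye(cc)
  expect_equal(sort(outc$I_A), sort(outc$I_B))
  # rank order preserved within channel
  expect_equal(order(outc$I_A), order(cc$I_A))
})

test_that("between-sub-array normalization equalizes sub-array distributions", {
  set.seed(2)
  n <- 400
  sub <- rep(1:4, each = n / 4)
  base <- rexp(n, 1 / 1000)
  scale <- c(1, 2, 1, 1)[sub] # sub-array 2 doubled
  a <- make_assay(base * scale, base * scale * 0.9, subarray = sub)
  out <- normalize_between_subarrays(a)
  pooled <- function(x, s) c(x$I_A[x$subarray == s], x$I_B[x$subarray == s])
  meds <- vapply(1:4, function(s) stats::median(pooled(out, s)), 0)
  expect_lt(max(meds) - min(meds), 1e-9)
  # sorted pooled distributions identical across sub-arrays
  expect_equal(sort(pooled(out, 1)), sort(pooled(out, 2)))
  # identical sub-array distributions unchanged
  a2 <- make_assay(rep(c(1, 2, 3, 4), 4), rep(c(1, 2, 3, 4), 4),
                   subarray = rep(1:4, each = 4))
  out2 <- normalize_between_subarrays(a2)
  expect_equal(out2$I_A, a2$I_A)
})

test_that("within-sample scaling puts both channel medians at 1 and is idempotent", {
  set.seed(3)
  a <- make_assay(rexp(51, 1 / 2000), rexp(51, 1 / 3000))
  out <- normalize_within_sample(a)
  expect_equal(stats::median(out$I_A), 1, tolerance = 1e-12)
  expect_equal(stats::median(out$I_B), 1, tolerance = 1e-12)
  out2 <- normalize_within_sample(out)
  expect_equal(out2$I_A, out$I_A)
  z <- make_assay(rep(0, 5), rep(1, 5))
  expect_error(normalize_within_sample(z), "degenerate channel")
})

test_that("per-SNP normalization scales reference mean total to 2", {
  # 3 references with constant totals 1.6 at every SNP, one tumor at 3.2
  refs <- lapply(1:3, function(i)
    make_assay(rep(0.8, 20), rep(0.8, 20), sample_id = paste0("n", i),
               role = "normal"))
  names(refs) <- paste0("n", 1:3)
  tum <- list(t1 = make_assay(rep(1.6, 20), rep(1.6, 20)))
  res <- normalize_per_snp(c(tum, refs), reference_ids = names(refs))
  expect_equal(res$samples$n1$I_A + res$samples$n1$I_B, rep(2, 20))
  # scale factor 2/1.6 = 1.25 applied to the tumor too
  expect_equal(res$samples$t1$I_A + res$samples$t1$I_B, rep(4, 20))
  # BAF preserved
  expect_equal(compute_baf(res$samples$t1$I_A, res$samples$t1$I_B),
               rep(0.5, 20))
})

test_that("per-SNP bias correction removes a linear BAF trend at the references", {
  set.seed(4)
  n_snp <- 40; n_ref <- 12
  refs <- lapply(seq_len(n_ref), function(i) {
    baf <- runif(n_snp, 0.3, 0.7)
    tot <- 2 + 0.5 * (baf - 0.5) # planted allele-specific bias
    make_assay(tot * (1 - baf), tot * baf, sample_id = paste0("n", i),
               role = "normal")
  })
  names(refs) <- paste0("n", seq_len(n_ref))
  res <- normalize_per_snp(refs, reference_ids = names(refs))
  slopes <- vapply(seq_len(n_snp), function(i) {
    baf <- vapply(res$samples, function(s) compute_baf(s$I_A, s$I_B)[i], 0)
    tot <- vapply(res$samples, function(s) s$I_A[i] + s$I_B[i], 0)
    stats::coef(stats::lm(tot ~ baf))[2]
  }, 0)
  expect_lt(max(abs(slopes)), 0.01)
  # with zero slope in the references the correction is the identity
  refs0 <- lapply(1:4, function(i) {
    baf <- runif(n_snp, 0.3, 0.7)
    make_assay(2 * (1 - baf), 2 * baf, sample_id = paste0("m", i),
               role = "normal")
  })
  names(refs0) <- paste0("m", 1:4)
  res0 <- normalize_per_snp(refs0, reference_ids = names(refs0))
  expect_equal(res0$samples$m1$I_A + res0$samples$m1$I_B, rep(2, n_snp))
})

test_that("full normalization maps a balanced diploid normal to I_A = I_B = 1 at heterozygous SNPs", {
  # channel-symmetric construction: equal AA and BB counts, zero noise
  n <- 100
  geno <- rep(c("AA", "AB", "AB", "BB"), n / 4)
  dose_A <- ifelse(geno == "AA", 2, ifelse(geno == "AB", 1, 0))
  dose_B <- ifelse(geno == "BB", 2, ifelse(geno == "AB", 1, 0))
  mk <- function(id) make_assay(1000 * 1.3 * dose_A, 1000 * dose_B,
                                genotype = geno, sample_id = id,
                                role = "normal")
  samples <- list(n1 = mk("n1"), n2 = mk("n2"), n3 = mk("n3"))
  normed <- lapply(samples, normalize_sample)
  res <- normalize_per_snp(normed, reference_ids = names(samples))
  het <- geno == "AB"
  for (s in res$samples) {
    expect_equal(s$I_A[het], rep(1, sum(het)), tolerance = 1e-9)
    expect_equal(s$I_B[het], rep(1, sum(het)), tolerance = 1e-9)
  }
})

test_that("normalization preserves intensity rank order within each sub-array", {
  set.seed(5)
  a <- make_assay(rexp(200, 1 / 2500), rexp(200, 1 / 3000),
                  subarray = rep(1:4, 50))
  out <- normalize_sample(a)
  # steps I and III are channel-global monotone maps; step II corrects
  # sub-array effects, so order is guaranteed within sub-arrays only
  for (s in 1:4) {
    i <- a$subarray == s
    expect_equal(order(out$I_A[i]), order(a$I_A[i]))
    expect_equal(order(out$I_B[i]), order(a$I_B[i]))
  }
  # single sub-array: full within-channel rank preservation through I-III
  b <- make_assay(rexp(150, 1 / 2500), rexp(150, 1 / 3000))
  outb <- normalize_sample(b)
  expect_equal(order(outb$I_A), order(b$I_A))
  expect_equal(order(outb$I_B), order(b$I_B))
})
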