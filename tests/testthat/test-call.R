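test_that("state enumeration covers all (p,q) with p >= q and c <= c_max", {
  s2 <- enumerate_states(2)
  expect_equal(s2[, c("p", "q")],
               data.frame(p = c(0, 1, 1, 2), q = c(0, 0, 1, 0)),
               ignore_attr = TRUE)
  s8 <- enumerate_states(8)
  expect_true(all(s8$p >= s8$q))
  expect_true(all(s8$c <= 8))
  expect_equal(s8$expected_lair[s8$p == 2 & s8$q == 1], 0.5)
  expect_true(is.na(s8$expected_lair[s8$c == 0]))
  expect_equal(s8$label[s8$p == 2 & s8$q == 1], "AAB")
  expect_equal(s8$label[s8$c == 0], "-")
})

test_that("segment calls reproduce the canonical worked examples", {
  # copy number 1 with LOH: state A
  c1 <- call_segment(0.5, 0.02, caller_params(di = 1))
  expect_equal(c1$state_label, "A")
  expect_equal(c1$c, 1)
  expect_equal(c1$balance_state, "LOH")
  # copy number 2 with balance: state AB
  c2 <- call_segment(1.0, 0.97, caller_params(di = 1))
  expect_equal(c2$state_label, "AB")
  expect_equal(c2$balance_state, "balanced")
  # triploid sample: r = 1, LAIR = 0.5 is AAB
  c3 <- call_segment(1.0, 0.5, caller_params(di = 1.5))
  expect_equal(c3$state_label, "AAB")
  expect_equal(c3$balance_state, "imbalance")
})

test_that("missing segment LAIR falls back to the intensity term with parsimonious ties", {
  # r = 1 at di = 1: (1,1) and (2,0) share c = 2; smaller p - q wins
  c1 <- call_segment(1.0, NA, caller_params(di = 1))
  expect_equal(c(c1$p, c1$q), c(1, 1))
  # homozygous deletion gated by r < 0.25/di
  c2 <- call_segment(0.1, NA, caller_params(di = 1))
  expect_equal(c2$c, 0)
  expect_equal(c2$balance_state, "unknown")
  c3 <- call_segment(0.3, NA, caller_params(di = 1))
  expect_gt(c3$c, 0)
})

test_that("gain/loss classification uses the 15% rule", {
  expect_equal(classify_gain_loss(c(1.20, 0.90, 0.84, 1.15, 0.85)),
               c("gain", "neutral", "loss", "neutral", "neutral"))
  expect_equal(classify_gain_loss(1.2, sample_mean_r = 2), "loss")
})

test_that("calling is consistent under genome doubling of truth and DI", {
  states <- enumerate_states(8)
  set.seed(1)
  for (i in 1:20) {
    p <- sample(0:2, 1); q <- sample(0:p, 1) # doubled states stay within c_max
    if (p + q == 0) next
    di <- runif(1, 0.9, 1.3)
    r <- (p + q) / (2 * di)
    lair <- if (p > 0) q / p else NA
    base <- call_segment(r, lair, caller_params(di = di), states)
    doubled <- call_segment((2 * (p + q)) / (2 * (2 * di)), lair,
                            caller_params(di = 2 * di), states)
    expect_equal(c(base$p, base$q), c(p, q))
    expect_equal(c(doubled$p, doubled$q), c(2 * p, 2 * q))
  }
})

test_that("ploidy validation passes consistent calls and rescales inconsistent ones", {
  tg <- toy_genome(length = 1000, centromere = 300)
  ok <- make_calls("1", c(1, 501), c(500, 1000), r = 1, p = 1L, q = 1L)
  rep1 <- validate_ploidy(ok, caller_params(di = 1))
  expect_true(rep1$pass)
  expect_equal(rep1$m, 2)
  rep2 <- validate_ploidy(make_calls("1", 1, 1000, r = 1, p = 2L, q = 2L),
                          caller_params(di = 2))
  expect_true(rep2$pass)
  expect_equal(rep2$m, 4)

  # a profile whose r is globally deflated triggers the rescale grid
  prof <- data.frame(sample_id = "s1", chrom = "1",
                     start_snp = c(1, 51), end_snp = c(50, 100),
                     start_bp = c(1, 501), end_bp = c(500, 1000),
                     n_snps = 50, n_informative = 30,
                     r = c(0.65, 0.65), lair_seg = NA_real_)
  class(prof) <- c("segment_profile", "data.frame")
  calls <- call_profile(prof, caller_params(di = 1))
  repflag <- attr(calls, "ploidy_report")
  expect_true(repflag$flagged)
  expect_true(repflag$rescale != 1)
  expect_true(repflag$pass)
})

test_that("balance states partition the genome length", {
  coh <- small_cohort(n1 = 3, n2 = 2, n_snps = 300, seed = 31)
  norm <- normalize_cohort(coh)
  keep <- coh$panel$snp_id %in% norm$panel$snp_id
  id <- names(norm$tumor)[1]
  prof <- segment_sample(norm$tumor[[id]], coh$normal_genotypes[keep, id],
                         norm$panel, coh$genome,
                         seg_params(n_perm = 500, seed = 1))
  calls <- call_profile(prof, caller_params(
    di = coh$di$measured_di[coh$di$sample_id == id]))
  len <- calls$end_bp - calls$start_bp + 1
  shares <- tapply(len, calls$balance_state, sum) / sum(len)
  expect_equal(sum(shares), 1)
  expect_true(all(calls$balance_state %in%
                    c("balanced", "imbalance", "LOH", "unknown")))
})
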