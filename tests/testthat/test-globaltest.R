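test_that("constant features give Q = 0 and p = 1", {
  X <- matrix(5, 8, 3)
  y <- rep(c(0, 1), 4)
  gt <- global_test(X, y, n_perm = 200, seed = 1)
  expect_equal(gt$Q, 0)
  expect_equal(gt$p, 1)
})

test_that("exhaustive enumeration reproduces the closed-form worked example", {
  X <- matrix(c(1, 1, 1, 2, 2, 2), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  gt <- global_test(X, y, permutations = "exhaustive")
  expect_equal(gt$p, 2 / 20)
  expect_equal(gt$n_perm, 20)
})

test_that("sampled permutation p converges to the exhaustive value", {
  set.seed(2)
  X <- matrix(rnorm(8 * 5), 8, 5)
  y <- rep(c("a", "b"), each = 4)
  ex <- global_test(X, y, permutations = "exhaustive")
  sa <- global_test(X, y, n_perm = 20000, seed = 3)
  # Monte-Carlo error at 20000 draws
  expect_lt(abs(sa$p - ex$p), 3 * sqrt(ex$p * (1 - ex$p) / 20000) + 1e-4)
})

test_that("Q is invariant under column permutation and duplication", {
  set.seed(4)
  X <- matrix(rnorm(12 * 6), 12, 6)
  y <- rep(c(0, 1), 6)
  q1 <- global_test(X, y, n_perm = 10, seed = 1)$Q
  q2 <- global_test(X[, sample(6)], y, n_perm = 10, seed = 1)$Q
  q3 <- global_test(cbind(X, X), y, n_perm = 10, seed = 1)$Q
  expect_equal(q2, q1)
  expect_equal(q3, q1)
})

test_that("multi-level outcomes are handled by one-vs-rest indicators", {
  set.seed(5)
  X <- matrix(rnorm(15 * 4), 15, 4)
  y <- rep(c("sq", "adeno", "adsq"), each = 5)
  gt <- global_test(X, y, n_perm = 500, seed = 6)
  expect_gt(gt$Q, 0)
  expect_true(gt$p > 0 && gt$p <= 1)
  expect_error(global_test(X, rep("sq", 15), n_perm = 10), "constant y")
})

test_that("confounders enter the null model and stratify the permutations", {
  set.seed(7)
  n <- 40
  strat <- rep(c("EUR", "AFR"), each = n / 2)
  # outcome strongly associated with stratum; X associated with stratum only
  y <- ifelse(strat == "EUR", rbinom(n / 2, 1, 0.8), rbinom(n / 2, 1, 0.2))
  X <- matrix(rnorm(n * 10, mean = ifelse(strat == "EUR", 1, -1)), n, 10)
  raw <- global_test(X, y, n_perm = 500, seed = 8)
  adj <- global_test(X, y, Z = data.frame(ethnic = strat), n_perm = 500,
                     seed = 8)
  expect_lt(raw$p, 0.05)    # confounded signal
  expect_gt(adj$p, 0.05)    # removed by the confounder
  # continuous confounder goes through the logistic null fit
  di <- rnorm(n, 1.5, 0.3)
  gt <- global_test(X, y, Z = data.frame(ethnic = strat, di = di),
                    n_perm = 200, seed = 9)
  expect_true(is.finite(gt$Q) && gt$p > 0 && gt$p <= 1)
  expect_equal(gt$confounders, c("ethnic", "di"))
})

test_that("BH adjustment matches stats::p.adjust and brute-force step-up", {
  brute <- function(p) {
    # literal step-up definition: adjusted p of the k-th smallest is
    # min over j >= k of p_(j) * n / j
    n <- length(p)
    vapply(seq_len(n), function(i) {
      k <- rank(p, ties.method = "max")[i]
      min(1, min(sort(p)[k:n] * n / (k:n)))
    }, 0)
  }
  expect_equal(bh_adjust(c(0.004, 0.04, 0.5)), c(0.012, 0.06, 0.5))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(10)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), brute(p))
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
    expect_true(all(bh_adjust(p) >= p))
  }
})

test_that("batched arm testing agrees with per-arm global tests", {
  coh <- small_cohort(n1 = 8, n2 = 7, n_snps = 300, seed = 81)
  tr <- truth_cohort_matrix(coh$truth, coh$genome, noise_sd = 0.05)
  clin <- data.frame(sample_id = rownames(tr$r),
                     histology = vapply(coh$truth, function(t) t$group, ""),
                     ethnic_cluster = vapply(coh$truth,
                                             function(t) t$population, ""))
  tab <- arm_tests_with_fdr(tr, clin, "histology", "continuous_cn",
                            Z = data.frame(e = clin$ethnic_cluster),
                            n_perm = 2000, seed = 4, k_min_snps = 0)
  arm <- paste0(tr$grid$chrom, tr$grid$arm)
  for (a in tab$arm[c(1, 10, 25)]) {
    X <- measure_matrix(tr, "continuous_cn", which(arm == a))
    gt <- global_test(X, clin$histology,
                      Z = data.frame(e = clin$ethnic_cluster),
                      n_perm = 2000, seed = 5)
    expect_equal(tab$Q[tab$arm == a], gt$Q, tolerance = 1e-12)
    # independent permutation draws: p agree within Monte-Carlo error
    se <- sqrt(gt$p * (1 - gt$p) / 2000)
    expect_lt(abs(tab$p[tab$arm == a] - gt$p), 4 * se + 2e-3)
  }
})

test_that("detection probability is non-decreasing in the planted effect size", {
  # clean single-arm design: carriers of a one-copy loss at rate p1 vs 0.10
  arm_p <- function(p1, k) {
    set.seed(3000 + k)
    x1 <- stats::rbinom(40, 1, p1)
    x2 <- stats::rbinom(20, 1, 0.10)
    r <- 1 - 0.5 * c(x1, x2) + stats::rnorm(60, 0, 0.05)
    global_test(matrix(r, ncol = 1), rep(c(1, 0), c(40, 20)),
                n_perm = 499, seed = k)$p
  }
  power_at <- vapply(c(0.10, 0.25, 0.45), function(p1)
    mean(vapply(1:40, function(k) arm_p(p1, k), 0) < 0.05), 0)
  expect_true(all(diff(power_at) >= 0))
  expect_gt(power_at[3], power_at[1])
})

test_that("parameter scan skips near-constant parameters and uses the right confounders", {
  coh <- small_cohort(n1 = 6, n2 = 4, n_snps = 200, seed = 71)
  tr <- truth_cohort_matrix(coh$truth, coh$genome, noise_sd = 0.02)
  clin <- coh$clinical
  clin$diameter <- c(rep(">40", 9), "<40") # 90% one level -> near-constant at 0.85 cutoff
  scan <- run_parameter_scan(tr, clin,
                             parameters = c("histology", "diameter"),
                             measures = c("continuous_cn", "lair"),
                             n_perm = 100, seed = 1, skip_frac = 0.85)
  d <- scan[scan$parameter == "diameter", ]
  expect_true(all(is.na(d$p)))
  expect_match(d$note[1], "near-constant")
  h <- scan[scan$parameter == "histology", ]
  expect_true(all(!is.na(h$p)))
  expect_equal(h$confounders[h$measure == "continuous_cn"],
               "ethnic_cluster+di")
  expect_equal(h$confounders[h$measure == "lair"], "ethnic_cluster")
})
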