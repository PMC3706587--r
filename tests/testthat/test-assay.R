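test_that("zero-noise intensities reflect allele doses exactly", {
  tg <- toy_genome(length = 1000, centromere = 300)
  panel <- make_panel(10, tg)
  panel$ancestral <- 0.5
  cfg <- sim_config(sd_m = 0, sd_a = 0, dye_bias = 1,
                    subarray_factors = rep(1, 4), gain = 1000, seed = 1)

  # diploid heterozygous genome: both channels at gain
  truth <- make_truth(data.frame(chrom = "1", start = 1, end = 1000,
                                 p = 1L, q = 1L), genome = tg)
  a <- simulate_assay(truth, panel, rep("AB", 10), cfg)
  expect_equal(a$I_A, rep(1000, 10))
  expect_equal(a$I_B, rep(1000, 10))

  # (2,1) state: intensity ratio exactly 2:1 at heterozygous SNPs
  truth21 <- make_truth(data.frame(chrom = "1", start = 1, end = 1000,
                                   p = 2L, q = 1L), genome = tg)
  set.seed(1)
  a21 <- simulate_assay(truth21, panel, rep("AB", 10), cfg)
  ratio <- pmax(a21$I_A, a21$I_B) / pmin(a21$I_A, a21$I_B)
  expect_equal(ratio, rep(2, 10))

  # homozygous SNPs put all copies on one channel
  ahom <- simulate_assay(truth21, panel, rep("AA", 10), cfg)
  expect_equal(ahom$I_A, rep(3000, 10))
  expect_equal(ahom$I_B, rep(0, 10))
})

test_that("dye bias scales channel A by construction", {
  tg <- toy_genome(length = 1000, centromere = 300)
  panel <- make_panel(200, tg)
  cfg <- sim_config(sd_m = 0, sd_a = 0, dye_bias = 1.3,
                    subarray_factors = rep(1, 4), gain = 1000, seed = 1)
  truth <- make_truth(data.frame(chrom = "1", start = 1, end = 1000,
                                 p = 1L, q = 1L), genome = tg)
  set.seed(2)
  a <- simulate_assay(truth, panel, rep("AB", 200), cfg)
  expect_equal(sort(a$I_A), 1.3 * sort(a$I_B))
})

test_that("major/minor-to-channel assignment is randomized so BAF is symmetric", {
  tg <- toy_genome(length = 1000, centromere = 300)
  panel <- make_panel(2000, tg)
  cfg <- sim_config(sd_m = 0, sd_a = 0, dye_bias = 1,
                    subarray_factors = rep(1, 4), seed = 1)
  truth <- make_truth(data.frame(chrom = "1", start = 1, end = 1000,
                                 p = 2L, q = 1L), genome = tg)
  set.seed(3)
  a <- simulate_assay(truth, panel, rep("AB", 2000), cfg)
  baf <- compute_baf(a$I_A, a$I_B)
  expect_true(abs(mean(baf > 0.5) - 0.5) < 0.05)
})

test_that("negative noise sd is rejected", {
  expect_error(sim_config(sd_m = -0.1), "sd_m")
  tg <- toy_genome()
  cfg <- sim_config(seed = 1)
  cfg$sd_a <- -1 # bypass constructor check
  truth <- make_truth(data.frame(chrom = "1", start = 1, end = 300,
                                 p = 1L, q = 1L), genome = tg)
  expect_error(simulate_assay(truth, make_panel(5, tg), rep("AB", 5), cfg),
               "negative")
})

test_that("write_cohort/read_cohort round-trip is numerically identical", {
  coh <- small_cohort(n1 = 2, n2 = 1, n_snps = 100, seed = 8, sd_di = 0)
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "clinical.csv")))
  expect_length(list.files(file.path(dir, "intensities")), 6)
  back <- read_cohort(dir, coh$genome)
  expect_equal(back$tumor[["t001"]]$I_A, coh$tumor[["t001"]]$I_A)
  expect_equal(back$normal[["t003"]]$I_B, coh$normal[["t003"]]$I_B)
  expect_equal(back$di$measured_di, coh$di$measured_di)
  expect_identical(back$normal_genotypes, coh$normal_genotypes)
  # sd_di = 0 means the measured DNA index equals the truth
  expect_equal(back$di$measured_di, back$di$true_di)
})

test_that("cohort simulation is reproducible and writes byte-identical files", {
  c1 <- small_cohort(n1 = 2, n2 = 1, n_snps = 80, seed = 15)
  c2 <- small_cohort(n1 = 2, n2 = 1, n_snps = 80, seed = 15)
  expect_identical(c1$di, c2$di)
  expect_identical(c1$tumor[["t002"]], c2$tumor[["t002"]])
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(c1, d1); write_cohort(c2, d2)
  f1 <- file.path(d1, "truth_segments.tsv")
  f2 <- file.path(d2, "truth_segments.tsv")
  expect_identical(readLines(f1), readLines(f2))
})
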