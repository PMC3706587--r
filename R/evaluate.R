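# Evaluation against ground truth: parameter recovery and truth-level
# cohort matrices for statistical power studies.

#' Fraction of genome length with correctly recovered allelic state
#'
#' Compares an `allelic_calls` segmentation with the sample's truth
#' profile: the returned fraction is the genome length (bp) on which the
#' called (p, q) equals the true (p, q), divided by total genome length.
#'
#' @param calls an `allelic_calls` data frame.
#' @param truth a `truth_profile`.
#' @param genome a [genome_layout()].
#' @return list: `fraction` correct, `by_chrom` data frame.
#' @export
state_recovery <- function(calls, truth, genome = genome_layout()) {
  by_chrom <- do.call(rbind, lapply(seq_len(nrow(genome)), function(ci) {
    ch <- genome$chrom[ci]
    cs <- calls[calls$chrom == ch, , drop = FALSE]
    ts <- truth$segments[truth$segments$chrom == ch, , drop = FALSE]
    if (nrow(cs) == 0)
      return(data.frame(chrom = ch, correct = 0, total = genome$length[ci]))
    bounds <- sort(unique(c(cs$end_bp, ts$end, genome$length[ci])))
    start <- c(1, utils::head(bounds, -1) + 1)
    kc <- findInterval(start, cs$start_bp); kc[kc < 1] <- 1
    kt <- findInterval(start, ts$start); kt[kt < 1] <- 1
    len <- bounds - start + 1
    ok <- cs$p[kc] == ts$p[kt] & cs$q[kc] == ts$q[kt]
    data.frame(chrom = ch, correct = sum(len[ok]), total = sum(len))
  }))
  list(fraction = sum(by_chrom$correct) / sum(by_chrom$total),
       by_chrom = by_chrom)
}

#' Cohort matrix built directly from truth profiles
#'
#' Builds the unified-breakpoint grid from the truth segments of a list of
#' profiles and fills the continuous CN matrix with the noise-free values
#' `(p+q) / (2 * DI)` plus optional Gaussian measurement noise. This is
#' the assay-free evaluation path used for power and calibration studies
#' of the cohort statistics, where simulating and segmenting intensities
#' for hundreds of cohorts would add nothing to the question under test.
#'
#' @param truths list of `truth_profile`.
#' @param genome a [genome_layout()].
#' @param noise_sd sd of additive Gaussian noise on the continuous CN.
#' @return list of class `cohort_matrix` with `grid` and matrices `r`,
#'   `cn`, `p`, `q`, `lair`, `balance`, `gainloss`.
#' @export
truth_cohort_matrix <- function(truths, genome = genome_layout(),
                                noise_sd = 0) {
  ids <- vapply(truths, function(t) t$sample_id, "")
  names(truths) <- ids
  grid <- list()
  for (ci in seq_len(nrow(genome))) {
    ch <- genome$chrom[ci]
    ends <- unlist(lapply(truths, function(t)
      t$segments$end[t$segments$chrom == ch]))
    bounds <- sort(unique(c(ends, genome$centromere[ci], genome$length[ci])))
    start <- c(1, utils::head(bounds, -1) + 1)
    grid[[ch]] <- data.frame(chrom = ch, start = start, end = bounds,
                             stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, grid)
  rownames(grid) <- NULL
  grid$arm <- assign_arm(grid$chrom, grid$start, genome)
  grid$n_snps <- NA_integer_

  ncell <- nrow(grid)
  mk <- function(ch = FALSE) matrix(if (ch) NA_character_ else NA_real_,
                                    length(ids), ncell,
                                    dimnames = list(ids, NULL))
  M <- list(r = mk(), lair = mk(), cn = mk(), p = mk(), q = mk(),
            balance = mk(TRUE), gainloss = mk(TRUE))
  for (s in ids) {
    t <- truths[[s]]
    di <- t$true_di
    for (ch in unique(grid$chrom)) {
      gi <- which(grid$chrom == ch)
      seg <- t$segments[t$segments$chrom == ch, , drop = FALSE]
      k <- findInterval(grid$start[gi], seg$start); k[k < 1] <- 1
      p <- seg$p[k]; q <- seg$q[k]
      M$p[s, gi] <- p; M$q[s, gi] <- q; M$cn[s, gi] <- p + q
      M$r[s, gi] <- (p + q) / (2 * di)
      M$lair[s, gi] <- ifelse(p > 0, q / p, NA_real_)
      M$balance[s, gi] <- ifelse(p + q == 0, "unknown",
                                 ifelse(q == 0, "LOH",
                                        ifelse(p == q, "balanced",
                                               "imbalance")))
    }
    M$gainloss[s, ] <- classify_gain_loss(M$r[s, ])
  }
  if (noise_sd > 0)
    M$r <- M$r + matrix(stats::rnorm(length(M$r), 0, noise_sd),
                        nrow(M$r))
  out <- c(list(grid = grid), M)
  class(out) <- "cohort_matrix"
  out
}
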