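# Cohort harmonization: unified breakpoint grid, measure matrices,
# frequency profiles.

#' Unify breakpoints across samples
#'
#' Applies every sample's breakpoints to all samples: the unified grid is,
#' per chromosome, the union of all samples' segment boundaries (plus the
#' centromere, so no grid cell spans both arms). Each sample's segment
#' values are copied onto every grid cell the segment spans, so samples
#' become directly comparable and each sample's length-weighted mean of
#' any measure is conserved exactly.
#'
#' @param calls named list of `allelic_calls` (one per sample, same
#'   genome).
#' @param genome a [genome_layout()].
#' @param panel optional `snp_panel` used to count SNPs per grid cell.
#' @return list of class `cohort_matrix`: `grid` (chrom, start, end, arm,
#'   n_snps), and samples x cells matrices `r`, `lair`, `cn`, `p`, `q`,
#'   plus character matrices `balance` and `gainloss`.
#' @export
unify_breakpoints <- function(calls, genome = genome_layout(),
                              panel = NULL) {
  stopifnot(length(calls) >= 1)
  ids <- names(calls)
  grid <- list()
  for (ci in seq_len(nrow(genome))) {
    ch <- genome$chrom[ci]
    ends <- unlist(lapply(calls, function(s) s$end_bp[s$chrom == ch]))
    if (length(ends) == 0) next
    bounds <- sort(unique(c(ends, genome$centromere[ci], genome$length[ci])))
    bounds <- bounds[bounds <= genome$length[ci]]
    start <- c(1, utils::head(bounds, -1) + 1)
    grid[[ch]] <- data.frame(chrom = ch, start = start, end = bounds,
                             stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, grid)
  rownames(grid) <- NULL
  grid$arm <- assign_arm(grid$chrom, grid$start, genome)
  if (!is.null(panel)) {
    grid$n_snps <- vapply(seq_len(nrow(grid)), function(i)
      sum(panel$chrom == grid$chrom[i] & panel$pos >= grid$start[i] &
            panel$pos <= grid$end[i]), 0L)
  } else grid$n_snps <- NA_integer_

  ncell <- nrow(grid)
  mk <- function(mode = "numeric")
    matrix(if (mode == "numeric") NA_real_ else NA_character_,
           length(ids), ncell, dimnames = list(ids, NULL))
  M <- list(r = mk(), lair = mk(), cn = mk(), p = mk(), q = mk(),
            balance = mk("char"), gainloss = mk("char"))
  for (s in ids) {
    cs <- calls[[s]]
    for (ch in unique(grid$chrom)) {
      gi <- which(grid$chrom == ch)
      seg <- cs[cs$chrom == ch, , drop = FALSE]
      if (nrow(seg) == 0) next
      k <- findInterval(grid$start[gi], seg$start_bp)
      k[k < 1] <- 1
      M$r[s, gi] <- seg$r[k]
      M$lair[s, gi] <- seg$lair_seg[k]
      M$cn[s, gi] <- seg$c[k]
      M$p[s, gi] <- seg$p[k]
      M$q[s, gi] <- seg$q[k]
      M$balance[s, gi] <- seg$balance_state[k]
      M$gainloss[s, gi] <- seg$gainloss[k]
    }
  }
  out <- c(list(grid = grid), M)
  class(out) <- "cohort_matrix"
  out
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("Cohort matrix: %d samples x %d unified grid cells (%d chromosomes, %d arms)\n",
              nrow(x$r), nrow(x$grid), length(unique(x$grid$chrom)),
              length(unique(paste0(x$grid$chrom, x$grid$arm)))))
  invisible(x)
}

#' Measure matrix for testing
#'
#' Extracts the samples x cells matrix of one measure from a
#' `cohort_matrix`, in the encoding used by the global test: continuous
#' and discrete CN and LAIR as numeric (NA cells mean-imputed per column),
#' balance state expanded to three indicator columns (balanced /
#' imbalance / LOH) per grid cell with unknowns mean-imputed.
#'
#' @param cohort a `cohort_matrix`.
#' @param measure one of "continuous_cn", "discrete_cn", "lair",
#'   "balance_state".
#' @param cells optional integer subset of grid cells (e.g. one arm).
#' @return numeric matrix, samples x columns.
#' @export
measure_matrix <- function(cohort,
                           measure = c("continuous_cn", "discrete_cn",
                                       "lair", "balance_state"),
                           cells = NULL) {
  measure <- match.arg(measure)
  if (is.null(cells)) cells <- seq_len(nrow(cohort$grid))
  impute <- function(X) {
    for (j in seq_len(ncol(X))) {
      na <- is.na(X[, j])
      if (any(na)) X[na, j] <- mean(X[, j], na.rm = TRUE)
      if (all(is.na(X[, j])) || any(!is.finite(X[, j]))) X[, j][!is.finite(X[, j])] <- 0
    }
    X
  }
  if (measure == "balance_state") {
    b <- cohort$balance[, cells, drop = FALSE]
    X <- do.call(cbind, lapply(c("balanced", "imbalance", "LOH"),
      function(st) {
        ind <- matrix(NA_real_, nrow(b), ncol(b))
        known <- !is.na(b) & b != "unknown"
        ind[known] <- as.numeric(b[known] == st)
        ind
      }))
    rownames(X) <- rownames(b)
    return(impute(X))
  }
  X <- switch(measure, continuous_cn = cohort$r, discrete_cn = cohort$cn,
              lair = cohort$lair)[, cells, drop = FALSE]
  impute(X)
}

#' Frequency profiles of genomic events
#'
#' Per unified grid cell, the fraction of samples showing LOH, allelic
#' imbalance, continuous-CN gain and loss, binned at the rendering
#' thresholds 10/20/30/40%, plus a per-arm maxima summary.
#'
#' @param cohort a `cohort_matrix`.
#' @return list of class `freq_profile`: `freq` (grid columns + frac_loh,
#'   frac_imbalance, frac_gain, frac_loss and their bins), `arm_summary`.
#' @export
frequency_profiles <- function(cohort) {
  frac <- function(M, what) colMeans(M == what, na.rm = TRUE)
  f <- cohort$grid
  f$frac_loh <- frac(cohort$balance, "LOH")
  f$frac_imbalance <- frac(cohort$balance, "imbalance")
  f$frac_gain <- frac(cohort$gainloss, "gain")
  f$frac_loss <- frac(cohort$gainloss, "loss")
  bin <- function(x) cut(x, c(-Inf, 0.1, 0.2, 0.3, 0.4, Inf),
                         labels = c("<=10%", ">10%", ">20%", ">30%", ">40%"))
  for (cname in c("frac_loh", "frac_imbalance", "frac_gain", "frac_loss"))
    f[[paste0(cname, "_bin")]] <- bin(f[[cname]])
  arm <- paste0(f$chrom, f$arm)
  arm_summary <- do.call(rbind, lapply(split(f, arm), function(g)
    data.frame(arm = paste0(g$chrom[1], g$arm[1]),
               max_loh = max(g$frac_loh), max_imbalance = max(g$frac_imbalance),
               max_gain = max(g$frac_gain), max_loss = max(g$frac_loss),
               stringsAsFactors = FALSE)))
  rownames(arm_summary) <- NULL
  out <- list(freq = f, arm_summary = arm_summary)
  class(out) <- "freq_profile"
  out
}

#' @export
print.freq_profile <- function(x, ...) {
  top <- x$arm_summary[order(-pmax(x$arm_summary$max_gain,
                                   x$arm_summary$max_loss)), ]
  cat("Frequency profile; most aberrant arms:\n")
  print(utils::head(top, 5), row.names = FALSE)
  invisible(x)
}

#' Plot frequency profiles
#'
#' Ideogram-style rendering: per chromosome, gain (or imbalance) frequency
#' above the axis and loss (or LOH) frequency below, colored by the
#' 10/20/30/40% bins.
#'
#' @param x a `freq_profile`.
#' @param measure "cn" (gain/loss) or "balance" (imbalance/LOH).
#' @param ... ignored.
#' @export
plot.freq_profile <- function(x, measure = c("cn", "balance"), ...) {
  measure <- match.arg(measure)
  f <- x$freq
  up <- if (measure == "cn") f$frac_gain else f$frac_imbalance
  dn <- if (measure == "cn") f$frac_loss else f$frac_loh
  chroms <- unique(f$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch) max(f$end[f$chrom == ch]),
                             0)))
  names(offs) <- c(chroms, "end")
  cols <- function(v) c("grey40", "black", "darkgreen", "blue",
                        "red")[findInterval(v, c(0, 0.1, 0.2, 0.3, 0.4),
                                            left.open = TRUE) + 1]
  x0 <- f$start + offs[f$chrom]; x1 <- f$end + offs[f$chrom]
  graphics::plot(NA, xlim = c(0, max(x1)), ylim = c(-1, 1), xlab = "",
                 ylab = if (measure == "cn") "loss | gain" else "LOH | imbalance",
                 xaxt = "n")
  graphics::rect(x0, 0, x1, up, col = cols(up), border = NA)
  graphics::rect(x0, -dn, x1, 0, col = cols(dn), border = NA)
  graphics::abline(v = offs, col = "grey80")
  graphics::abline(h = 0)
  mid <- (offs[seq_along(chroms)] + offs[-1]) / 2
  graphics::axis(1, at = mid, labels = chroms, tick = FALSE, cex.axis = 0.6)
  invisible(x)
}
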