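# Circular binary segmentation and LAIR sub-segmentation.

#' Segmentation parameters
#'
#' @param alpha significance level for accepting a split (default 0.01).
#' @param n_perm permutations for the split p-value (default 10000; a
#'   sequential early stop abandons the permutation loop as soon as the
#'   exceedance count guarantees p > alpha, without changing the decision).
#' @param min_width minimum probes per segment (default 2).
#' @param k_min minimum informative SNPs for a usable segment LAIR
#'   (default 5).
#' @param seed integer seed for the permutation null.
#' @return list of class `seg_params`.
#' @export
seg_params <- function(alpha = 0.01, n_perm = 10000, min_width = 2,
                       k_min = 5, seed = 1) {
  stopifnot(alpha > 0, alpha < 1, min_width >= 2, n_perm >= 1, k_min >= 1)
  structure(list(alpha = alpha, n_perm = n_perm, min_width = min_width,
                 k_min = k_min, seed = seed), class = "seg_params")
}

#' Circular binary segmentation of one track
#'
#' Recursively finds the arc maximizing the circular two-sample
#' t-statistic between the probes inside and outside the arc, accepts the
#' split when its permutation p-value is at most `alpha`, and recurses on
#' the resulting pieces. Constant input yields no breakpoints.
#'
#' @param x numeric vector (one chromosome's ordered probe values); NAs
#'   are not allowed.
#' @param params a [seg_params()].
#' @return sorted integer vector of breakpoint indices b, meaning a
#'   boundary between positions b and b+1 (empty when no change-points).
#' @examples
#' cbs_segment(c(rep(1, 20), rep(2, 20)), seg_params(n_perm = 500))
#' @export
cbs_segment <- function(x, params = seg_params()) {
  stopifnot(!anyNA(x))
  if (!is.null(params$seed)) set.seed(params$seed)
  breaks <- integer(0)
  rec <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 2 * params$min_width) return()
    seg <- x[lo:hi]
    m <- .cbs_max_arc(seg, params$min_width)
    if (m$stat <= 0) return()
    p <- .cbs_perm_p(seg, params$min_width, m$stat, params$n_perm,
                     params$alpha)
    if (p > params$alpha) return()
    b1 <- if (m$i > 0) lo + m$i - 1L else NA_integer_
    b2 <- if (m$j < n) lo + m$j - 1L else NA_integer_
    new_b <- c(b1, b2)
    new_b <- new_b[!is.na(new_b)]
    if (length(new_b) == 0) return()
    breaks <<- c(breaks, new_b)
    bounds <- c(lo - 1L, as.integer(new_b), hi)
    for (k in seq_len(length(bounds) - 1))
      rec(bounds[k] + 1L, bounds[k + 1])
  }
  rec(1L, length(x))
  sort(unique(as.integer(breaks)))
}

# Per-segment summaries given per-chromosome breakpoints.
# Breakpoints are indices into the chromosome's SNP vector.
.segments_from_breaks <- function(breaks, n) {
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  data.frame(start_snp = starts, end_snp = ends)
}

# bp boundaries: segment edges at midpoints between flanking SNPs,
# chromosome ends clipped to [1, chrom_length].
.bp_bounds <- function(pos, start_snp, end_snp, chrom_len) {
  n <- length(pos)
  start_bp <- ifelse(start_snp == 1, 1,
                     floor((pos[pmax(start_snp - 1, 1)] + pos[start_snp]) / 2) + 1)
  end_bp <- ifelse(end_snp == n, chrom_len,
                   floor((pos[end_snp] + pos[pmin(end_snp + 1, n)]) / 2))
  data.frame(start_bp = start_bp, end_bp = end_bp)
}

#' Segment one tumor sample
#'
#' Per chromosome, segments the normalized total intensity track with
#' circular binary segmentation, then sub-segments each intensity segment
#' on the LAIR values of its informative SNPs; the final segmentation is
#' the refinement of the two (every intensity breakpoint is kept). Per
#' final segment it reports `r`, the mean total intensity relative to the
#' sample mean (so the SNP-weighted genome mean of `r` is 1 regardless of
#' ploidy), and `lair_seg`, the median LAIR over informative SNPs (NA when
#' fewer than `k_min` informative SNPs fall in the segment). Segment bp
#' bounds are 1-based inclusive, cut at midpoints between flanking SNPs so
#' segments tile each chromosome.
#'
#' @param assay normalized tumor `snp_assay` (after step IV).
#' @param normal_genotype matched-normal genotypes (one per assay SNP).
#' @param panel the `snp_panel` restricted to the same SNPs.
#' @param genome a [genome_layout()].
#' @param params a [seg_params()].
#' @return data frame of class `segment_profile`: sample_id, chrom,
#'   start_snp, end_snp (per-chromosome SNP indices), start_bp, end_bp,
#'   n_snps, n_informative, r, lair_seg.
#' @export
segment_sample <- function(assay, normal_genotype, panel,
                           genome = genome_layout(),
                           params = seg_params()) {
  stopifnot(nrow(assay) == nrow(panel))
  tot <- assay$I_A + assay$I_B
  sample_mean <- mean(tot)
  informative <- select_informative(normal_genotype)
  lair <- compute_lair(assay$I_A, assay$I_B)

  out <- list()
  for (ci in seq_len(nrow(genome))) {
    ch <- genome$chrom[ci]
    idx <- which(panel$chrom == ch)
    if (length(idx) == 0) next
    tt <- tot[idx]
    br_int <- cbs_segment(tt, params)
    segs <- .segments_from_breaks(br_int, length(idx))

    # LAIR sub-segmentation within each intensity segment
    final_breaks <- br_int
    for (s in seq_len(nrow(segs))) {
      rng <- segs$start_snp[s]:segs$end_snp[s]
      inf_local <- which(informative[idx][rng] & !is.na(lair[idx][rng]))
      if (length(inf_local) < 2 * params$min_width) next
      lv <- lair[idx][rng][inf_local]
      br_l <- cbs_segment(lv, params)
      if (length(br_l) == 0) next
      # breakpoint after informative SNP k maps to the chromosome index of
      # that informative SNP
      final_breaks <- c(final_breaks,
                        segs$start_snp[s] - 1L + inf_local[br_l])
    }
    final_breaks <- sort(unique(final_breaks))
    fsegs <- .segments_from_breaks(final_breaks, length(idx))
    bp <- .bp_bounds(panel$pos[idx], fsegs$start_snp, fsegs$end_snp,
                     genome$length[ci])
    nseg <- nrow(fsegs)
    r <- numeric(nseg); ls <- numeric(nseg); ninf <- integer(nseg)
    for (s in seq_len(nseg)) {
      rng <- fsegs$start_snp[s]:fsegs$end_snp[s]
      r[s] <- mean(tt[rng]) / sample_mean
      ii <- informative[idx][rng] & !is.na(lair[idx][rng])
      ninf[s] <- sum(ii)
      ls[s] <- if (ninf[s] >= params$k_min)
        stats::median(lair[idx][rng][ii]) else NA_real_
    }
    out[[ch]] <- data.frame(
      sample_id = attr(assay, "sample_id") %||% "sample",
      chrom = ch, start_snp = fsegs$start_snp, end_snp = fsegs$end_snp,
      start_bp = bp$start_bp, end_bp = bp$end_bp,
      n_snps = fsegs$end_snp - fsegs$start_snp + 1L,
      n_informative = ninf, r = r, lair_seg = ls,
      stringsAsFactors = FALSE)
  }
  prof <- do.call(rbind, out)
  rownames(prof) <- NULL
  attr(prof, "params") <- params
  attr(prof, "sample_mean_intensity") <- sample_mean
  class(prof) <- c("segment_profile", "data.frame")
  prof
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.segment_profile <- function(x, ...) {
  cat(sprintf("Segment profile %s: %d segments on %d chromosomes; r in [%.2f, %.2f]\n",
              x$sample_id[1], nrow(x), length(unique(x$chrom)),
              min(x$r), max(x$r)))
  invisible(x)
}

#' Plot a segment profile
#'
#' Continuous copy number (top) and segment LAIR (bottom) along the
#' genome, chromosomes concatenated.
#'
#' @param x a `segment_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.segment_profile <- function(x, ...) {
  chroms <- unique(x$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch)
    max(x$end_bp[x$chrom == ch]), 0)))
  names(offs) <- c(chroms, "end")
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  x0 <- x$start_bp + offs[x$chrom]
  x1 <- x$end_bp + offs[x$chrom]
  graphics::plot(NA, xlim = c(0, max(x1)), ylim = c(0, max(2, x$r) * 1.05),
                 xlab = "", ylab = "continuous CN (r)", ...)
  graphics::segments(x0, x$r, x1, x$r, lwd = 2, col = "steelblue")
  graphics::abline(v = offs, col = "grey80")
  graphics::plot(NA, xlim = c(0, max(x1)), ylim = c(0, 1),
                 xlab = "", ylab = "LAIR")
  graphics::segments(x0, x$lair_seg, x1, x$lair_seg, lwd = 2, col = "tomato")
  graphics::abline(v = offs, col = "grey80")
  invisible(x)
}
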