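# Ground-truth allele-specific copy-number profiles for synthetic cohorts.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-cohort generator. Defaults emulate
#' the study conditions the pipeline is designed for: two histology-like
#' groups (40 vs 20 tumors), a strongly enriched 2q loss in the first group
#' (probability 0.45 vs 0.10), a background rate of arm events in both
#' groups, whole-genome duplication in half the tumors (giving a bimodal
#' DNA-index distribution with modes near 1 and 2), multiplicative
#' log-normal intensity noise, a dye bias on channel A, and four sub-array
#' scale factors.
#'
#' @param n_per_group named integer vector: samples per group.
#' @param base_priors named numeric: per-arm probabilities of
#'   loss/gain/loh/imbalance events applied to every arm in every group.
#' @param group_arm_priors data frame (`group`, `arm_name`, `event`,
#'   `prob`) overriding `base_priors` for specific arms; the default plants
#'   the 2q-loss enrichment.
#' @param wgd_prob probability of whole-genome duplication per tumor.
#' @param n_snps panel size.
#' @param fst population divergence of the panel.
#' @param pop_probs named probabilities of each ancestry group.
#' @param gain expected intensity per allele copy, in raw instrument units.
#' @param sd_m multiplicative log-normal noise sd (log scale).
#' @param sd_a additive Gaussian noise sd (raw units).
#' @param dye_bias multiplicative bias applied to channel A before
#'   normalization.
#' @param subarray_factors per-sub-array scale factors (length 4).
#' @param sd_di relative measurement noise of the flow-cytometric DNA
#'   index (0 = measured equals truth).
#' @param seed integer seed fixing all randomness.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = c(squamous = 40, adenosquamous = 20),
                       base_priors = c(loss = 0.04, gain = 0.04,
                                       loh = 0.04, imbalance = 0.04),
                       group_arm_priors = data.frame(
                         group = c("squamous", "adenosquamous"),
                         arm_name = "2q", event = "loss",
                         prob = c(0.45, 0.10), stringsAsFactors = FALSE),
                       wgd_prob = 0.5,
                       n_snps = 2000, fst = 0.15,
                       pop_probs = c(EUR = 0.556, AFR = 0.309, ASI = 0.135),
                       gain = 3000, sd_m = 0.1, sd_a = 0,
                       dye_bias = 1.2,
                       subarray_factors = c(1, 0.9, 1.1, 1.05),
                       sd_di = 0, seed = 1) {
  stopifnot(all(n_per_group >= 1), !is.null(names(n_per_group)))
  stopifnot(all(base_priors >= 0 & base_priors <= 1),
            all(c("loss", "gain", "loh", "imbalance") %in% names(base_priors)))
  if (!is.null(group_arm_priors) && nrow(group_arm_priors) > 0)
    stopifnot(all(group_arm_priors$prob >= 0 & group_arm_priors$prob <= 1))
  stopifnot(wgd_prob >= 0, wgd_prob <= 1, sd_m >= 0, sd_a >= 0, sd_di >= 0,
            gain > 0, n_snps >= 1)
  pop_probs <- pop_probs / sum(pop_probs)
  out <- list(n_per_group = n_per_group, base_priors = base_priors,
              group_arm_priors = group_arm_priors, wgd_prob = wgd_prob,
              n_snps = n_snps, fst = fst, pop_probs = pop_probs,
              gain = gain, sd_m = sd_m, sd_a = sd_a, dye_bias = dye_bias,
              subarray_factors = subarray_factors, sd_di = sd_di,
              seed = seed)
  class(out) <- "sim_config"
  out
}

# Overwrite (p,q) on [start, end] of one chromosome's segment set
# (plain list of start/end/p/q vectors), splitting overlapped segments and
# merging identical neighbours. Segments tile the chromosome throughout.
.overwrite_interval <- function(segs, start, end, p, q) {
  ss <- segs$start; se <- segs$end; sp <- segs$p; sq <- segs$q
  outside <- se < start | ss > end
  left <- ss < start & se >= start
  right <- se > end & ss <= end
  ns <- c(ss[outside], ss[left], rep(end + 1, sum(right)), start)
  ne <- c(se[outside], rep(start - 1, sum(left)), se[right], end)
  np <- c(sp[outside], sp[left], sp[right], p)
  nq <- c(sq[outside], sq[left], sq[right], q)
  o <- order(ns)
  ns <- ns[o]; ne <- ne[o]; np <- np[o]; nq <- nq[o]
  n <- length(ns)
  keep <- which(c(TRUE, !(np[-1] == np[-n] & nq[-1] == nq[-n])))
  ends <- c(keep[-1] - 1L, n)
  list(start = ns[keep], end = ne[ends], p = np[keep], q = nq[keep])
}

# (p,q) assigned to each event type; losses/gains move total copy number,
# copy-neutral LOH and imbalance change only the allelic split.
.EVENT_STATE <- list(loss = c(1L, 0L), gain = c(2L, 1L),
                     loh = c(2L, 0L), imbalance = c(3L, 1L))

#' Generate a ground-truth copy-number profile
#'
#' Starts from the diploid heterozygous state (1,1) on every chromosome,
#' then draws arm-level events (loss, gain, copy-neutral LOH, imbalance)
#' from group-specific priors. Each event overwrites the state on the whole
#' arm (probability 0.5) or on a random sub-interval of it. A whole-genome
#' duplication, drawn with probability `wgd_prob`, doubles every (p,q) and
#' pushes the DNA index towards 2.
#'
#' @param config a [sim_config()].
#' @param group group label (must match `config$n_per_group` names).
#' @param population ancestry label for the sample.
#' @param genome a [genome_layout()].
#' @param sample_id sample identifier.
#' @return list of class `truth_profile`: `sample_id`, `segments` (chrom,
#'   start, end, p, q; 1-based inclusive, tiling each chromosome),
#'   `true_di`, `group`, `population`, `wgd`.
#' @export
generate_truth_profile <- function(config, group, population,
                                   genome = genome_layout(),
                                   sample_id = "s1") {
  arms <- chrom_arms(genome)
  a_chrom <- arms$chrom; a_start <- arms$start; a_end <- arms$end
  a_name <- arms$arm_name
  per_chrom <- lapply(seq_len(nrow(genome)), function(i)
    list(start = 1, end = genome$length[i], p = 1L, q = 1L))
  names(per_chrom) <- genome$chrom

  ev_names <- names(.EVENT_STATE)
  gp <- config$group_arm_priors
  if (!is.null(gp) && nrow(gp) > 0) gp <- gp[gp$group == group, , drop = FALSE]
  for (a in seq_len(nrow(arms))) {
    for (ev in ev_names) {
      prob <- unname(config$base_priors[[ev]])
      if (!is.null(gp) && nrow(gp) > 0) {
        hit <- gp$arm_name == a_name[a] & gp$event == ev
        if (any(hit)) prob <- gp$prob[hit][1]
      }
      if (stats::runif(1) >= prob) next
      if (stats::runif(1) < 0.5) {
        lo <- a_start[a]; hi <- a_end[a]
      } else {
        w <- a_end[a] - a_start[a] + 1
        len <- max(round(w * stats::runif(1, 0.2, 0.8)), 1)
        lo <- a_start[a] + floor(stats::runif(1, 0, w - len + 1))
        hi <- min(lo + len - 1, a_end[a])
      }
      st <- .EVENT_STATE[[ev]]
      per_chrom[[a_chrom[a]]] <-
        .overwrite_interval(per_chrom[[a_chrom[a]]], lo, hi, st[1], st[2])
    }
  }

  wgd <- stats::runif(1) < config$wgd_prob
  nseg <- vapply(per_chrom, function(s) length(s$start), 0L)
  segments <- data.frame(
    chrom = rep(names(per_chrom), nseg),
    start = unlist(lapply(per_chrom, `[[`, "start"), use.names = FALSE),
    end = unlist(lapply(per_chrom, `[[`, "end"), use.names = FALSE),
    p = as.integer(unlist(lapply(per_chrom, `[[`, "p"), use.names = FALSE)),
    q = as.integer(unlist(lapply(per_chrom, `[[`, "q"), use.names = FALSE)),
    stringsAsFactors = FALSE)
  if (wgd) {
    segments$p <- segments$p * 2L
    segments$q <- segments$q * 2L
  }
  rownames(segments) <- NULL
  prof <- list(sample_id = sample_id, segments = segments,
               group = group, population = population, wgd = wgd)
  class(prof) <- "truth_profile"
  prof$true_di <- compute_true_di(prof, genome)
  prof
}

#' DNA index of a truth profile
#'
#' The DNA index is the length-weighted mean total copy number divided
#' by 2 (diploid = 1, tetraploid = 2). Errors if the segments do not tile
#' the genome.
#'
#' @param profile a `truth_profile`.
#' @param genome a [genome_layout()].
#' @return scalar DNA index.
#' @export
compute_true_di <- function(profile, genome = genome_layout()) {
  segs <- profile$segments
  for (i in seq_len(nrow(genome))) {
    s <- segs[segs$chrom == genome$chrom[i], , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) == 0 || s$start[1] != 1 ||
        s$end[nrow(s)] != genome$length[i] ||
        (nrow(s) > 1 && any(s$start[-1] != s$end[-nrow(s)] + 1)))
      stop("segments do not tile the genome (chromosome ", genome$chrom[i], ")")
  }
  len <- segs$end - segs$start + 1
  sum(len * (segs$p + segs$q)) / (2 * sum(len))
}

#' @export
print.truth_profile <- function(x, ...) {
  cat(sprintf("Truth profile %s (%s, %s): %d segments, DI = %.3f%s\n",
              x$sample_id, x$group, x$population, nrow(x$segments),
              x$true_di, if (x$wgd) ", WGD" else ""))
  invisible(x)
}
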