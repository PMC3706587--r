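# Discrete allele-specific copy-number calling anchored to the DNA index.

#' Caller parameters
#'
#' @param di sample DNA index (> 0); 1 = diploid, 2 = tetraploid.
#' @param c_max maximum total copy number considered (default 8, covering
#'   DNA indices above 2.5).
#' @param w_r,w_l weights of the intensity and LAIR terms in the fit cost.
#' @param di_tolerance allowed relative deviation between the
#'   length-weighted mean discrete CN / 2 and the DNA index (default 0.15).
#' @param k_min minimum informative SNPs for a segment LAIR to enter the
#'   cost.
#' @return list of class `caller_params`.
#' @export
caller_params <- function(di, c_max = 8, w_r = 1, w_l = 1,
                          di_tolerance = 0.15, k_min = 5) {
  stopifnot(di > 0, c_max >= 2, w_r >= 0, w_l >= 0, di_tolerance > 0)
  structure(list(di = di, c_max = c_max, w_r = w_r, w_l = w_l,
                 di_tolerance = di_tolerance, k_min = k_min),
            class = "caller_params")
}

#' Enumerate allelic states
#'
#' All states (p, q) with p >= q >= 0 and 1 <= p+q <= c_max, plus the
#' homozygous deletion (0,0). Each state carries its label (e.g. "AAB"),
#' total copy number c = p+q, and the noise-free expectations: continuous
#' CN c/(2*di) and LAIR q/p (undefined for p = 0).
#'
#' @param c_max maximum total copy number.
#' @return data frame: p, q, c, label, expected_lair.
#' @examples
#' enumerate_states(2)
#' @export
enumerate_states <- function(c_max = 8) {
  stopifnot(c_max >= 1)
  pq <- do.call(rbind, lapply(0:c_max, function(p)
    data.frame(p = p, q = 0:min(p, c_max - p))))
  pq <- pq[pq$p + pq$q >= 1 | (pq$p == 0 & pq$q == 0), ]
  pq$c <- pq$p + pq$q
  pq <- pq[pq$c <= c_max, ]
  pq$label <- ifelse(pq$c == 0, "-",
                     paste0(strrep("A", pq$p), strrep("B", pq$q)))
  pq$expected_lair <- ifelse(pq$p > 0, pq$q / pq$p, NA_real_)
  rownames(pq) <- NULL
  pq
}

.balance_state <- function(p, q) {
  ifelse(p + q == 0, "unknown",
         ifelse(q == 0, "LOH", ifelse(p == q, "balanced", "imbalance")))
}

#' Call the allelic state of one segment
#'
#' Finds the state (p, q) minimizing
#' `w_r * (r - c/(2*di))^2 + w_l * (lair_seg - q/p)^2`; the LAIR term is
#' dropped when the segment LAIR is missing or p = 0. Homozygous deletion
#' (0,0) is only eligible when `r < 0.25/di`, so noise is not labeled
#' nullisomy. Ties resolve to the smaller total copy number, then the
#' smaller allelic difference p-q (parsimony toward simpler states).
#'
#' @param r segment continuous CN (>= 0).
#' @param lair_seg segment LAIR in [0, 1] or NA.
#' @param params a [caller_params()].
#' @param states optional precomputed [enumerate_states()] table.
#' @return one-row data frame: p, q, c, state_label, balance_state, cost.
#' @examples
#' call_segment(0.5, 0.02, caller_params(di = 1))  # one copy, LOH: "A"
#' @export
call_segment <- function(r, lair_seg = NA, params, states = NULL) {
  stopifnot(r >= 0)
  if (is.null(states)) states <- enumerate_states(params$c_max)
  expected_r <- states$c / (2 * params$di)
  cost <- params$w_r * (r - expected_r)^2
  if (!is.na(lair_seg)) {
    dl <- (lair_seg - states$expected_lair)^2
    cost <- cost + ifelse(is.na(dl), 0, params$w_l * dl)
  }
  eligible <- states$c > 0 | r < 0.25 / params$di
  cost[!eligible] <- Inf
  ord <- order(round(cost, 12), states$c, states$p - states$q)
  k <- ord[1]
  data.frame(p = states$p[k], q = states$q[k], c = states$c[k],
             state_label = states$label[k],
             balance_state = .balance_state(states$p[k], states$q[k]),
             cost = cost[k], stringsAsFactors = FALSE)
}

#' Continuous gain/loss classification
#'
#' Gains and losses are deviations of more than 15% from the sample
#' average continuous CN.
#'
#' @param r segment continuous CN values.
#' @param sample_mean_r sample average (1 by construction).
#' @param threshold relative deviation (default 0.15).
#' @return character vector in {gain, neutral, loss}.
#' @export
classify_gain_loss <- function(r, sample_mean_r = 1, threshold = 0.15) {
  stopifnot(sample_mean_r > 0)
  ifelse(r > (1 + threshold) * sample_mean_r, "gain",
         ifelse(r < (1 - threshold) * sample_mean_r, "loss", "neutral"))
}

#' Call allelic states for a whole segment profile
#'
#' Applies [call_segment()] to every segment and [classify_gain_loss()] to
#' the continuous CN, then checks the ploidy contract with
#' [validate_ploidy()]: the length-weighted mean discrete CN over the
#' genome must reflect the sample DNA index.
#'
#' @param profile a `segment_profile`.
#' @param params a [caller_params()] carrying the sample's measured DNA
#'   index.
#' @return data frame of class `allelic_calls`: the profile columns plus
#'   p, q, c, state_label, balance_state, cost, gainloss; attributes
#'   `ploidy_report` and `params`.
#' @export
call_profile <- function(profile, params) {
  calls <- .call_all(profile, params, rescale = 1)
  rep0 <- .ploidy_check(calls, params)
  rescale <- 1
  if (!rep0$pass) {
    grid <- seq(0.8, 1.25, by = 0.05)
    devs <- vapply(grid, function(f) {
      .ploidy_check(.call_all(profile, params, rescale = f), params)$dev
    }, 0)
    rescale <- grid[which.min(devs)]
    calls <- .call_all(profile, params, rescale = rescale)
    rep0 <- .ploidy_check(calls, params)
    rep0$flagged <- TRUE
    rep0$rescale <- rescale
  } else {
    rep0$flagged <- FALSE
    rep0$rescale <- 1
  }
  attr(calls, "ploidy_report") <- rep0
  attr(calls, "params") <- params
  class(calls) <- c("allelic_calls", "data.frame")
  calls
}

.call_all <- function(profile, params, rescale = 1) {
  states <- enumerate_states(params$c_max)
  res <- do.call(rbind, lapply(seq_len(nrow(profile)), function(i)
    call_segment(profile$r[i] * rescale, profile$lair_seg[i], params,
                 states)))
  calls <- cbind(as.data.frame(profile), res)
  calls$gainloss <- classify_gain_loss(profile$r)
  calls
}

.ploidy_check <- function(calls, params) {
  len <- calls$end_bp - calls$start_bp + 1
  m <- sum(len * calls$c) / sum(len)
  dev <- abs(m / 2 - params$di)
  list(pass = dev <= params$di_tolerance * params$di, m = m,
       di = params$di, dev = dev)
}

#' Ploidy validation report
#'
#' Computes the length-weighted mean discrete CN m of a call set and
#' checks `|m/2 - di| <= di_tolerance * di`. [call_profile()] runs this
#' automatically and, on failure, retries calling over a global intensity
#' rescale grid (0.8 to 1.25 in 0.05 steps), keeping the rescale
#' minimizing the deviation and flagging the sample.
#'
#' @param calls an `allelic_calls` data frame.
#' @param params a [caller_params()].
#' @return list: pass, m (mean discrete CN), di, dev.
#' @export
validate_ploidy <- function(calls, params) {
  .ploidy_check(calls, params)
}

#' @export
print.allelic_calls <- function(x, ...) {
  rep <- attr(x, "ploidy_report")
  if (is.null(rep)) return(print.data.frame(x, ...))
  cat(sprintf("Allelic calls %s: %d segments; mean discrete CN %.2f (DI %.2f, %s%s)\n",
              x$sample_id[1], nrow(x), rep$m, rep$di,
              if (rep$pass) "consistent" else "INCONSISTENT",
              if (rep$flagged) sprintf(", rescaled x%.2f", rep$rescale) else ""))
  tab <- tapply(x$end_bp - x$start_bp + 1, x$balance_state, sum)
  tab <- 100 * tab / sum(x$end_bp - x$start_bp + 1)
  cat("Balance state (% genome):",
      paste(sprintf("%s %.1f", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
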