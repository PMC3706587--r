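# Permutation global test: a quadratic-form score statistic for association
# between a high-dimensional feature matrix (segmented genomic profiles)
# and a clinical outcome, tolerant of strongly correlated features, with
# optional confounders handled by a null model plus stratified permutation.

# Strata for permutation: cross of categorical confounders and tertile
# bins of continuous confounders. Strata with < 2 samples are merged into
# the largest stratum with a warning.
.perm_strata <- function(Z, n) {
  if (is.null(Z) || ncol(Z) == 0) return(factor(rep(1, n)))
  parts <- lapply(seq_len(ncol(Z)), function(j) {
    z <- Z[[j]]
    if (is.numeric(z)) {
      qs <- unique(stats::quantile(z, c(1 / 3, 2 / 3)))
      cut(z, breaks = unique(c(-Inf, qs, Inf)))
    } else factor(z)
  })
  s <- droplevels(interaction(parts, drop = TRUE))
  tab <- table(s)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    warning("merging ", length(small), " stratum(s) with < 2 samples")
    big <- names(tab)[which.max(tab)]
    levels(s)[levels(s) %in% small] <- big
    s <- droplevels(s)
  }
  s
}

# Outcome indicator matrix: one column for 2 levels, one-vs-rest set for
# more.
.y_indicators <- function(y) {
  y <- factor(y)
  lev <- levels(y)
  if (length(lev) < 2) stop("constant y")
  if (length(lev) == 2) {
    m <- matrix(as.numeric(y == lev[2]), ncol = 1,
                dimnames = list(NULL, lev[2]))
  } else {
    m <- vapply(lev, function(l) as.numeric(y == l), numeric(length(y)))
  }
  m
}

# Null-model fitted values for each indicator column given confounders.
# Categorical-only confounders reduce to stratum proportions; continuous
# confounders use a logistic fit (linear fit as fallback).
.null_mu <- function(Yind, Z, strata) {
  n <- nrow(Yind)
  if (is.null(Z) || ncol(Z) == 0)
    return(matrix(colMeans(Yind), n, ncol(Yind), byrow = TRUE))
  has_num <- any(vapply(Z, is.numeric, TRUE))
  if (!has_num) {
    mu <- Yind
    for (g in seq_len(ncol(Yind)))
      mu[, g] <- stats::ave(Yind[, g], strata)
    return(mu)
  }
  Zm <- stats::model.matrix(~., data = Z)
  mu <- Yind
  for (g in seq_len(ncol(Yind))) {
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(Zm, Yind[, g],
                                      family = stats::binomial())),
      error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      mu[, g] <- fit$fitted.values
    } else {
      mu[, g] <- stats::lm.fit(Zm, Yind[, g])$fitted.values
    }
  }
  mu
}

# All distinct assignments of the multiset y (used for the exhaustive
# oracle at small n). Returns a matrix with one assignment per column.
.enumerate_assignments <- function(y) {
  y <- as.character(y)
  n <- length(y)
  counts <- table(y)
  total <- factorial(n) / prod(factorial(counts))
  if (total > 1e5) stop("too many assignments to enumerate")
  lev <- names(counts)
  res <- vector("list", 0)
  rec <- function(prefix, cnt) {
    if (length(prefix) == n) {
      res[[length(res) + 1]] <<- prefix
      return()
    }
    for (l in lev) if (cnt[[l]] > 0) {
      cnt2 <- cnt
      cnt2[[l]] <- cnt2[[l]] - 1
      rec(c(prefix, l), cnt2)
    }
  }
  rec(character(0), as.list(counts))
  do.call(cbind, res)
}

#' Global test for association of a genomic profile with an outcome
#'
#' Tests whether a samples x features matrix `X` (e.g. continuous CN of
#' all unified segments) differs between outcome groups. Features are
#' centered; the null model of the outcome on the confounders `Z` is
#' fitted (logistic for two levels, one-vs-rest indicator set for more;
#' stratum proportions when all confounders are categorical); with
#' residuals r_g the statistic is `Q = sum_g r_g' X X' r_g / m`, m the
#' number of features. Inference is by permutation of the outcome within
#' confounder strata (categorical confounders define strata; continuous
#' confounders are binned into tertiles for stratification while staying
#' continuous in the null fit):
#' `p = (1 + #[Q_perm >= Q_obs]) / (1 + n_perm)`. With
#' `permutations = "exhaustive"` all distinct outcome assignments are
#' enumerated instead and `p = #[Q >= Q_obs] / N` (the observed assignment
#' is part of the enumeration), which is the exact oracle for small n.
#'
#' @param X samples x features numeric matrix.
#' @param y outcome (factor or coercible; 2+ levels); samples with missing
#'   y are dropped from X, y and Z.
#' @param Z data frame of confounders (categorical and/or numeric) or NULL.
#' @param n_perm number of sampled permutations.
#' @param seed integer seed for the permutation draw.
#' @param permutations "sample" or "exhaustive".
#' @param parameter,measure,scope labels carried into the result.
#' @return object of class `lair_global_test`: Q, p, n_perm, n, m,
#'   parameter, measure, scope, confounders.
#' @examples
#' X <- matrix(c(1, 1, 1, 2, 2, 2), ncol = 1)
#' y <- c(0, 0, 0, 1, 1, 1)
#' global_test(X, y, permutations = "exhaustive")$p  # 2/20
#' @export
global_test <- function(X, y, Z = NULL, n_perm = 10000, seed = NULL,
                        permutations = c("sample", "exhaustive"),
                        parameter = NA, measure = NA, scope = "genome") {
  permutations <- match.arg(permutations)
  X <- as.matrix(X)
  y <- factor(y)
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- droplevels(y[keep])
  if (!is.null(Z)) {
    Z <- as.data.frame(Z)[keep, , drop = FALSE]
    cc <- stats::complete.cases(Z)
    X <- X[cc, , drop = FALSE]; y <- droplevels(y[cc])
    Z <- Z[cc, , drop = FALSE]
  }
  n <- nrow(X)
  if (nlevels(y) < 2) stop("constant y")
  m <- ncol(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  K <- tcrossprod(Xc)
  strata <- .perm_strata(Z, n)
  Yind <- .y_indicators(y)
  qstat <- function(R) sum(R * (K %*% R)) / m
  mu <- .null_mu(Yind, Z, strata)
  Q_obs <- qstat(Yind - mu)

  has_num <- !is.null(Z) && any(vapply(Z, is.numeric, TRUE))
  if (!is.null(seed)) set.seed(seed)

  if (permutations == "exhaustive") {
    if (nlevels(strata) > 1)
      stop("exhaustive enumeration implemented for unstratified tests only")
    A <- .enumerate_assignments(y)
    Qs <- apply(A, 2, function(a) {
      Yp <- .y_indicators(factor(a, levels = levels(y)))
      mup <- .null_mu(Yp, Z, strata)
      qstat(Yp - mup)
    })
    p <- sum(Qs >= Q_obs - 1e-12) / length(Qs)
    n_used <- length(Qs)
  } else {
    perm_within <- function() {
      idx <- seq_len(n)
      for (s in levels(strata)) {
        i <- which(strata == s)
        idx[i] <- i[sample.int(length(i))]
      }
      idx
    }
    if (!has_num) {
      # stratum means are permutation-invariant under within-stratum
      # permutation, so residual rows can be permuted directly; the
      # permutation loop is blocked and vectorized through one matrix
      # product per residual column.
      R <- Yind - mu
      count <- 0L
      block <- max(1L, min(n_perm, as.integer(2e6 / n)))
      done <- 0L
      while (done < n_perm) {
        B <- min(block, n_perm - done)
        IDX <- vapply(seq_len(B), function(b) perm_within(), integer(n))
        Qb <- numeric(B)
        for (g in seq_len(ncol(R))) {
          P <- matrix(R[, g][IDX], n, B)
          Qb <- Qb + colSums(P * (K %*% P))
        }
        count <- count + sum(Qb / m >= Q_obs - 1e-12)
        done <- done + B
      }
    } else {
      count <- 0L
      for (b in seq_len(n_perm)) {
        idx <- perm_within()
        Yp <- Yind[idx, , drop = FALSE]
        mup <- .null_mu(Yp, Z, strata)
        if (qstat(Yp - mup) >= Q_obs - 1e-12) count <- count + 1L
      }
    }
    p <- (1 + count) / (1 + n_perm)
    n_used <- n_perm
  }

  out <- list(Q = Q_obs, p = p, n_perm = n_used,
              permutations = permutations, n = n, m = m,
              parameter = parameter, measure = measure, scope = scope,
              confounders = if (is.null(Z)) character(0) else names(Z))
  class(out) <- "lair_global_test"
  out
}

#' @export
print.lair_global_test <- function(x, ...) {
  cat(sprintf("Global test%s%s [%s]: Q = %.4g, p = %.4g (n = %d, m = %d, %s %d permutations%s)\n",
              if (is.na(x$parameter)) "" else paste0(" ", x$parameter),
              if (is.na(x$measure)) "" else paste0(" / ", x$measure),
              x$scope, x$Q, x$p, x$n, x$m,
              if (x$permutations == "exhaustive") "exhaustive" else "sampled",
              x$n_perm,
              if (length(x$confounders))
                paste0("; confounders: ", paste(x$confounders, collapse = ","))
              else ""))
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR
#'
#' Step-up adjusted p-values: `fdr_(i) = min_(j >= i) p_(j) * n / j`,
#' capped at 1, in the order of increasing p.
#'
#' @param p vector of p-values.
#' @return adjusted values in the input order; always elementwise >= p.
#' @export
bh_adjust <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  adj <- pmax(adj, p[o]) # guard the fdr >= p invariant against rounding
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Genome-wide parameter scan
#'
#' Runs the genome-wide global test for every clinical parameter x measure
#' combination. Ethnic cluster is a confounder in every test; the DNA
#' index is an extra confounder for continuous CN (and optionally for
#' discrete CN as a secondary analysis, since discrete CN already absorbs
#' the DNA index). Parameters with more than `skip_frac` of samples in one
#' level are skipped with a reason.
#'
#' @param cohort a `cohort_matrix`.
#' @param clinical clinical table with `sample_id`, the parameters,
#'   `ethnic_cluster` and `di`, rows matching the cohort's samples.
#' @param parameters clinical column names to test.
#' @param measures measures to test (see [measure_matrix()]).
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @param di_confounder_discrete also add DI as confounder for discrete CN.
#' @param skip_frac near-constancy threshold (default 0.95).
#' @return data frame: parameter, measure, scope, Q, p, n_perm,
#'   confounders, note; attribute `tests` holds the test objects.
#' @export
run_parameter_scan <- function(cohort, clinical,
                               parameters = c("growth_pattern", "histology",
                                              "infiltration_depth",
                                              "lymph_nodes", "parametria",
                                              "vaso_invasion"),
                               measures = c("lair", "balance_state",
                                            "continuous_cn", "discrete_cn"),
                               n_perm = 1000, seed = 1,
                               di_confounder_discrete = FALSE,
                               skip_frac = 0.95) {
  ids <- rownames(cohort$r)
  clinical <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
  rows <- list(); tests <- list()
  for (param in parameters) {
    y <- clinical[[param]]
    tab <- table(y[!is.na(y)])
    note <- ""
    skip <- FALSE
    if (length(tab) < 2) { skip <- TRUE; note <- "single level" }
    else if (max(tab) / sum(tab) > skip_frac) {
      skip <- TRUE; note <- sprintf("near-constant (%.0f%% one level)",
                                    100 * max(tab) / sum(tab))
    }
    for (meas in measures) {
      if (skip) {
        rows[[length(rows) + 1]] <- data.frame(
          parameter = param, measure = meas, scope = "genome",
          Q = NA_real_, p = NA_real_, n_perm = NA_integer_,
          confounders = "", note = note, stringsAsFactors = FALSE)
        next
      }
      Z <- data.frame(ethnic_cluster = clinical$ethnic_cluster)
      if (meas == "continuous_cn" ||
          (meas == "discrete_cn" && di_confounder_discrete))
        Z$di <- clinical$di
      X <- measure_matrix(cohort, meas)
      gt <- global_test(X, y, Z, n_perm = n_perm, seed = seed,
                        parameter = param, measure = meas)
      tests[[paste(param, meas, sep = ".")]] <- gt
      rows[[length(rows) + 1]] <- data.frame(
        parameter = param, measure = meas, scope = "genome",
        Q = gt$Q, p = gt$p, n_perm = gt$n_perm,
        confounders = paste(gt$confounders, collapse = "+"), note = "",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "tests") <- tests
  res
}

# Batched global tests of many feature sets against one outcome with
# categorical-only confounders: the stratified permutation index set is
# drawn once and shared across feature sets, so per-set work is one matrix
# product. Returns Q and p per feature set.
.global_test_batch <- function(Xs, y, Z, n_perm, seed) {
  y <- factor(y)
  keep <- !is.na(y)
  if (!is.null(Z)) {
    Z <- as.data.frame(Z)
    keep <- keep & stats::complete.cases(Z)
  }
  y <- droplevels(y[keep])
  if (nlevels(y) < 2) stop("constant y")
  if (!is.null(Z)) Z <- Z[keep, , drop = FALSE]
  n <- sum(keep)
  strata <- .perm_strata(Z, n)
  Yind <- .y_indicators(y)
  mu <- .null_mu(Yind, Z, strata)
  R <- Yind - mu
  if (!is.null(seed)) set.seed(seed)
  IDX <- vapply(seq_len(n_perm), function(b) {
    idx <- seq_len(n)
    for (s in levels(strata)) {
      i <- which(strata == s)
      idx[i] <- i[sample.int(length(i))]
    }
    idx
  }, integer(n))
  P <- lapply(seq_len(ncol(R)), function(g) matrix(R[, g][IDX], n, n_perm))
  Q <- numeric(length(Xs)); p <- numeric(length(Xs))
  for (k in seq_along(Xs)) {
    Xc <- scale(Xs[[k]][keep, , drop = FALSE], center = TRUE, scale = FALSE)
    m <- ncol(Xc)
    K <- tcrossprod(Xc)
    Q[k] <- sum(R * (K %*% R)) / m
    Qb <- numeric(n_perm)
    for (g in seq_along(P)) Qb <- Qb + colSums(P[[g]] * (K %*% P[[g]]))
    p[k] <- (1 + sum(Qb / m >= Q[k] - 1e-12)) / (1 + n_perm)
  }
  list(Q = Q, p = p)
}

#' Arm-level global tests with BH FDR
#'
#' Localizes a genome-wide difference by running the global test on each
#' chromosome arm individually and adjusting the per-arm p-values by
#' Benjamini-Hochberg step-up FDR; an arm is significant when its FDR is
#' below 0.05. Arms with fewer than `k_min_snps` panel SNPs are excluded
#' (acrocentric short arms carry none).
#'
#' @inheritParams run_parameter_scan
#' @param parameter one clinical column.
#' @param measure one measure.
#' @param Z data frame of confounders (default: ethnic cluster, plus DI
#'   for continuous CN).
#' @param k_min_snps minimum SNPs for an arm to be tested.
#' @return data frame of class `arm_test_table`: arm, Q, p, fdr,
#'   significant.
#' @export
arm_tests_with_fdr <- function(cohort, clinical, parameter, measure,
                               Z = NULL, n_perm = 1000, seed = 1,
                               k_min_snps = 5) {
  ids <- rownames(cohort$r)
  clinical <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
  y <- clinical[[parameter]]
  if (is.null(Z)) {
    Z <- data.frame(ethnic_cluster = clinical$ethnic_cluster)
    if (measure == "continuous_cn") Z$di <- clinical$di
  }
  arm <- paste0(cohort$grid$chrom, cohort$grid$arm)
  arms <- unique(arm)
  if (!all(is.na(cohort$grid$n_snps))) {
    snps_per_arm <- tapply(cohort$grid$n_snps, arm, sum)
    arms <- arms[!is.na(snps_per_arm[arms]) &
                   snps_per_arm[arms] >= k_min_snps]
  }
  Xs <- lapply(arms, function(a)
    measure_matrix(cohort, measure, which(arm == a)))
  has_num <- !is.null(Z) && any(vapply(as.data.frame(Z), is.numeric, TRUE))
  if (!has_num) {
    # one shared stratified permutation draw across arms
    b <- .global_test_batch(Xs, y, Z, n_perm = n_perm, seed = seed)
    res <- data.frame(arm = arms, Q = b$Q, p = b$p,
                      stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, lapply(seq_along(arms), function(k) {
      gt <- global_test(Xs[[k]], y, Z, n_perm = n_perm, seed = seed,
                        parameter = parameter, measure = measure,
                        scope = arms[k])
      data.frame(arm = arms[k], Q = gt$Q, p = gt$p, stringsAsFactors = FALSE)
    }))
  }
  res$fdr <- bh_adjust(res$p)
  res$significant <- res$fdr < 0.05
  class(res) <- c("arm_test_table", "data.frame")
  res
}
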