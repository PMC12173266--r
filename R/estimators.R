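# Causal-effect estimators on a harmonized instrument set. All estimators
# take the HarmonizedPair columns beta_exposure/se_exposure and
# beta_outcome/se_outcome, with outcome betas on the log-odds scale for a
# binary outcome, and weight by the inverse outcome variance 1/se_outcome^2.

new_mr_estimate <- function(method, beta, se, n_snps, pval = NULL,
                            intercept = NULL) {
  if (is.null(pval)) pval <- 2 * stats::pnorm(-abs(beta / se))
  est <- list(method = method, beta = beta, se = se, pval = pval,
              n_snps = n_snps,
              or_point = exp(beta),
              or_ci = exp(c(beta - stats::qnorm(0.975) * se,
                            beta + stats::qnorm(0.975) * se)),
              ci = c(beta - stats::qnorm(0.975) * se,
                     beta + stats::qnorm(0.975) * se))
  if (!is.null(intercept)) est$intercept <- intercept
  structure(est, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s], %d SNP(s)\n", x$method, x$n_snps))
  cat(sprintf("  beta = %.6g (se %.6g), p = %.4g\n", x$beta, x$se, x$pval))
  cat(sprintf("  OR = %.4f (95%% CI %.4f-%.4f)\n",
              x$or_point, x$or_ci[1], x$or_ci[2]))
  invisible(x)
}

check_pairs <- function(pairs, min_n, caller) {
  stopifnot(is.data.frame(pairs))
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  missing <- setdiff(need, names(pairs))
  if (length(missing) > 0L) {
    stop(caller, ": pairs lack column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(pairs) < min_n) {
    stop(caller, " needs at least ", min_n, " instrument(s), got ",
         nrow(pairs), call. = FALSE)
  }
  invisible(pairs)
}

#' Wald ratio for a single instrument
#'
#' `beta = beta_outcome / beta_exposure`, with the first-order standard
#' error `se_outcome / |beta_exposure|`.
#'
#' @param pair one harmonized pair (single-row data.frame or list with
#'   `beta_exposure`, `beta_outcome`, `se_outcome`).
#' @return An `mr_estimate`.
#' @export
mr_wald_ratio <- function(pair) {
  bx <- pair$beta_exposure[1]
  by <- pair$beta_outcome[1]
  sey <- pair$se_outcome[1]
  if (bx == 0) stop("Wald ratio undefined: beta_exposure is zero", call. = FALSE)
  new_mr_estimate("wald", beta = by / bx, se = sey / abs(bx), n_snps = 1L)
}

#' Inverse-variance-weighted estimator
#'
#' The primary estimator: the weighted least-squares slope of the outcome
#' betas on the exposure betas through the origin, with weights
#' `1/se_outcome^2`. `beta = sum(w bx by) / sum(w bx^2)`,
#' `se_fixed = sqrt(1 / sum(w bx^2))`. The multiplicative random-effects
#' variant (default for two or more instruments) inflates the standard error
#' by `sqrt(max(1, Q / (n - 1)))` where `Q` is Cochran's statistic at the
#' fixed-effect estimate, and is robust under balanced heterogeneity.
#'
#' @param pairs harmonized pairs.
#' @param method `"re"` (multiplicative random effects) or `"fe"` (fixed
#'   effect). With a single instrument both reduce to the Wald ratio.
#' @return An `mr_estimate` (`method` field `ivw_re` or `ivw_fixed`).
#' @export
mr_ivw <- function(pairs, method = c("re", "fe")) {
  method <- match.arg(method)
  check_pairs(pairs, 1L, "mr_ivw")
  bx <- pairs$beta_exposure
  by <- pairs$beta_outcome
  w <- 1 / pairs$se_outcome^2
  sxx <- sum(w * bx^2)
  if (sxx == 0) stop("degenerate design: all exposure betas are zero",
                     call. = FALSE)
  beta <- sum(w * bx * by) / sxx
  se <- sqrt(1 / sxx)
  n <- nrow(pairs)
  label <- "ivw_fixed"
  if (method == "re" && n >= 2L) {
    q <- sum(w * (by - beta * bx)^2)
    se <- se * sqrt(max(1, q / (n - 1)))
    label <- "ivw_re"
  }
  new_mr_estimate(label, beta = beta, se = se, n_snps = n)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome betas on the exposure betas with an
#' unconstrained intercept (weights `1/se_outcome^2`). Pairs are oriented so
#' every exposure beta is non-negative before fitting (the InSIDE
#' convention); this changes the sign of the intercept, not of the slope.
#' The slope is the pleiotropy-adjusted causal estimate; a non-zero
#' intercept indicates directional horizontal pleiotropy, with "no
#' horizontal pleiotropy" declared at intercept p >= 0.05. Standard errors
#' carry the multiplicative random-effects floor `max(1, sigma)` on the
#' residual standard deviation.
#'
#' @param pairs harmonized pairs (at least 3).
#' @param pval_dist `"normal"` (default) or `"t"` (df = n - 2) for the
#'   two-sided p-values.
#' @return list with `estimate` (an `mr_estimate`, slope) and `pleiotropy`
#'   (list `intercept`, `intercept_se`, `pval`).
#' @export
mr_egger <- function(pairs, pval_dist = c("normal", "t")) {
  pval_dist <- match.arg(pval_dist)
  check_pairs(pairs, 3L, "mr_egger")
  flip <- sign(pairs$beta_exposure)
  flip[flip == 0] <- 1
  bx <- abs(pairs$beta_exposure)
  by <- pairs$beta_outcome * flip
  w <- 1 / pairs$se_outcome^2
  n <- nrow(pairs)
  sw <- sum(w); sx <- sum(w * bx); sy <- sum(w * by)
  sxx <- sum(w * bx^2); sxy <- sum(w * bx * by)
  det <- sw * sxx - sx^2
  if (det <= 0 || stats::var(bx) == 0) {
    stop("degenerate design: no variance in exposure betas", call. = FALSE)
  }
  slope <- (sw * sxy - sx * sy) / det
  intercept <- (sxx * sy - sx * sxy) / det
  rss <- sum(w * (by - intercept - slope * bx)^2)
  sigma2 <- rss / (n - 2)
  infl <- max(1, sigma2)
  slope_se <- sqrt(sw / det * infl)
  int_se <- sqrt(sxx / det * infl)
  pfun <- if (pval_dist == "normal") {
    function(z) 2 * stats::pnorm(-abs(z))
  } else {
    function(z) 2 * stats::pt(-abs(z), df = n - 2)
  }
  est <- new_mr_estimate("egger", beta = slope, se = slope_se, n_snps = n,
                         pval = pfun(slope / slope_se), intercept = intercept)
  pleio <- list(intercept = intercept, intercept_se = int_se,
                pval = pfun(intercept / int_se))
  list(estimate = est, pleiotropy = pleio)
}

#' Weighted median estimator
#'
#' Orders the per-variant Wald ratios and takes the value at cumulative
#' weight 0.5, with linear interpolation between bracketing ratios; weights
#' are `beta_exposure^2 / se_outcome^2`, normalized. Consistent when at
#' least half of the total weight comes from valid instruments, hence robust
#' to a minority of outliers. The standard error is a seeded parametric
#' bootstrap: each replicate redraws every `beta_exposure` and
#' `beta_outcome` from its normal sampling distribution and recomputes the
#' weighted median.
#'
#' @param pairs harmonized pairs (at least 2).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap (required).
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000, seed) {
  check_pairs(pairs, 2L, "mr_weighted_median")
  if (missing(seed)) stop("mr_weighted_median requires a seed", call. = FALSE)
  beta <- weighted_median_point(pairs$beta_exposure, pairs$beta_outcome,
                                pairs$se_outcome)
  n <- nrow(pairs)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(n, pairs$beta_exposure, pairs$se_exposure)
      by <- stats::rnorm(n, pairs$beta_outcome, pairs$se_outcome)
      weighted_median_point(bx, by, pairs$se_outcome)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  new_mr_estimate("weighted_median", beta = beta, se = se, n_snps = n)
}

weighted_median_point <- function(bx, by, sey) {
  ratio <- by / bx
  w <- bx^2 / sey^2
  ord <- order(ratio)
  ratio <- ratio[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(ratio[1])
  if (cw[length(cw)] <= 0.5) return(ratio[length(cw)])
  k <- max(which(cw < 0.5))
  ratio[k] + (ratio[k + 1] - ratio[k]) * (0.5 - cw[k]) / (cw[k + 1] - cw[k])
}

#' Cochran Q heterogeneity test
#'
#' `Q = sum(w (by - f(bx))^2)` with `w = 1/se_outcome^2`, where `f` is the
#' fitted model of the supplied estimate: `beta * bx` for IVW/Wald, or
#' `intercept + beta * bx` (on orientation-flipped pairs) for MR-Egger.
#' Under homogeneity Q is chi-square with `n - 1` (IVW) or `n - 2` (Egger)
#' degrees of freedom; heterogeneity is declared at p < 0.05.
#'
#' @param pairs harmonized pairs (at least 2; at least 3 for Egger).
#' @param estimate an `mr_estimate` from [mr_ivw()], [mr_wald_ratio()] or
#'   [mr_egger()]`$estimate`.
#' @return list `q_stat`, `df`, `pval`.
#' @export
mr_cochran_q <- function(pairs, estimate) {
  stopifnot(inherits(estimate, "mr_estimate"))
  is_egger <- identical(estimate$method, "egger")
  check_pairs(pairs, if (is_egger) 3L else 2L, "mr_cochran_q")
  w <- 1 / pairs$se_outcome^2
  if (is_egger) {
    flip <- sign(pairs$beta_exposure)
    flip[flip == 0] <- 1
    bx <- abs(pairs$beta_exposure)
    by <- pairs$beta_outcome * flip
    resid <- by - estimate$intercept - estimate$beta * bx
    df <- nrow(pairs) - 2L
  } else {
    resid <- pairs$beta_outcome - estimate$beta * pairs$beta_exposure
    df <- nrow(pairs) - 1L
  }
  q <- sum(w * resid^2)
  list(q_stat = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW effect omitting each instrument in turn. An omission
#' is flagged influential when it changes the sign of the estimate or moves
#' it outside the full-set 95% confidence interval. The reference interval
#' uses the fixed-effect IVW by default: a dominant outlier inflates the
#' random-effects interval and would mask its own influence.
#'
#' @param pairs harmonized pairs (at least 3).
#' @param method IVW variant passed to [mr_ivw()].
#' @return data.frame with one row per omitted variant: `omitted`, `beta`,
#'   `se`, `pval`, `flagged`; attribute `full` holds the full-set estimate.
#' @export
mr_leave_one_out <- function(pairs, method = c("fe", "re")) {
  method <- match.arg(method)
  check_pairs(pairs, 3L, "mr_leave_one_out")
  full <- mr_ivw(pairs, method = method)
  n <- nrow(pairs)
  ids <- if (!is.null(pairs$variant_id)) pairs$variant_id else as.character(seq_len(n))
  rows <- lapply(seq_len(n), function(j) {
    est <- mr_ivw(pairs[-j, , drop = FALSE], method = method)
    data.frame(omitted = ids[j], beta = est$beta, se = est$se,
               pval = est$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flagged <- sign(out$beta) != sign(full$beta) |
    out$beta < full$ci[1] | out$beta > full$ci[2]
  attr(out, "full") <- full
  out
}

#' MR-PRESSO outlier test
#'
#' Pleiotropy residual sum and outlier test. The observed statistic is the
#' leave-one-out weighted residual sum of squares
#' `RSS = sum_j w_j (by_j - beta_(-j) * bx_j)^2` with `w = 1/se_outcome^2`
#' and `beta_(-j)` the fixed-effect IVW slope excluding variant j. Its null
#' distribution is simulated parametrically: each replicate redraws
#' `bx* ~ N(bx, se_exposure)` and `by* ~ N(beta_(-j) * bx_j, se_outcome)`.
#'
#' * global test: p = fraction of simulated RSS >= observed;
#' * outlier test: per-variant simulated tail p for the weighted squared
#'   residual, Bonferroni-adjusted (capped at 1); variants with adjusted
#'   p < `outlier_p_threshold` are removed. The default threshold 1 removes
#'   every flagged outlier;
#' * distortion test: p for the shift between the pre- and post-removal IVW
#'   estimates against removals of random subsets of the same size.
#'
#' Fully deterministic given `seed`.
#'
#' @param pairs harmonized pairs (at least 4).
#' @param n_simulations parametric replicates (default 1000).
#' @param outlier_p_threshold Bonferroni-adjusted p cutoff for removal
#'   (default 1).
#' @param seed integer seed (required).
#' @return list of class `mr_presso`: `global_rss`, `global_pval`,
#'   `outlier_pvals` (named, Bonferroni-adjusted), `outliers`,
#'   `distortion_pval`, `n_simulations`, `seed`, and `retained` (the pairs
#'   with outliers removed).
#' @export
mr_presso <- function(pairs, n_simulations = 1000, outlier_p_threshold = 1,
                      seed) {
  check_pairs(pairs, 4L, "mr_presso")
  if (missing(seed)) stop("mr_presso requires a seed", call. = FALSE)
  n <- nrow(pairs)
  ids <- if (!is.null(pairs$variant_id)) pairs$variant_id else as.character(seq_len(n))
  bx <- pairs$beta_exposure
  by <- pairs$beta_outcome
  sex <- pairs$se_exposure
  sey <- pairs$se_outcome
  w <- 1 / sey^2

  loo_slope <- function(bx, by, w) {
    sxy <- sum(w * bx * by)
    sxx <- sum(w * bx^2)
    (sxy - w * bx * by) / (sxx - w * bx^2)
  }
  b_loo <- loo_slope(bx, by, w)
  res2_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(res2_obs)

  sims <- with_seed(seed, {
    bx_star <- matrix(stats::rnorm(n * n_simulations, bx, sex), nrow = n)
    by_star <- matrix(stats::rnorm(n * n_simulations, b_loo * bx, sey), nrow = n)
    list(bx = bx_star, by = by_star,
         subset_seed = sample.int(.Machine$integer.max, 1L))
  })
  # vectorized leave-one-out slopes for every simulated dataset
  sxy_s <- colSums(w * sims$bx * sims$by)
  sxx_s <- colSums(w * sims$bx^2)
  b_loo_s <- (rep(sxy_s, each = n) - w * sims$bx * sims$by) /
    (rep(sxx_s, each = n) - w * sims$bx^2)
  res2_s <- w * (sims$by - b_loo_s * sims$bx)^2   # n x n_simulations
  rss_s <- colSums(res2_s)
  global_pval <- (1 + sum(rss_s >= rss_obs)) / (1 + n_simulations)

  p_raw <- (1 + rowSums(res2_s >= res2_obs)) / (1 + n_simulations)
  p_adj <- pmin(1, p_raw * n)
  names(p_adj) <- ids
  outliers <- ids[p_adj < outlier_p_threshold]

  distortion_pval <- NA_real_
  if (length(outliers) > 0L && length(outliers) < n) {
    keep <- !(ids %in% outliers)
    b_all <- sum(w * bx * by) / sum(w * bx^2)
    b_kept <- sum(w[keep] * bx[keep] * by[keep]) / sum(w[keep] * bx[keep]^2)
    d_obs <- b_kept - b_all
    k_out <- sum(!keep)
    d_sim <- with_seed(sims$subset_seed, {
      vapply(seq_len(n_simulations), function(i) {
        drop <- sample.int(n, k_out)
        b_sub <- sum(w[-drop] * bx[-drop] * by[-drop]) /
          sum(w[-drop] * bx[-drop]^2)
        b_sub - b_all
      }, numeric(1))
    })
    distortion_pval <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (1 + n_simulations)
  }

  retained <- pairs[!(ids %in% outliers), , drop = FALSE]
  structure(list(global_rss = rss_obs, global_pval = global_pval,
                 outlier_pvals = p_adj, outliers = outliers,
                 distortion_pval = distortion_pval,
                 n_simulations = n_simulations, seed = seed,
                 retained = retained),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS %.4g, global p = %.4g, %d outlier(s)\n",
              x$global_rss, x$global_pval, length(x$outliers)))
  if (length(x$outliers) > 0L) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
    cat(sprintf("  distortion p = %.4g\n", x$distortion_pval))
  }
  invisible(x)
}

#' Run the full estimator battery on one harmonized pair set
#'
#' IVW (primary), MR-Egger and weighted median (secondary), plus the
#' Egger-intercept pleiotropy test and Cochran Q heterogeneity at the IVW
#' fit. Estimators whose instrument-count preconditions are not met are
#' omitted.
#'
#' @param pairs harmonized pairs.
#' @param ivw_method `"re"` or `"fe"`.
#' @param n_boot weighted-median bootstrap replicates.
#' @param seed integer seed for stochastic components.
#' @return list with `estimates` (a data.frame of method rows: method,
#'   n_snps, beta, se, pval, or, ci_low, ci_high), `pleiotropy`,
#'   `heterogeneity`, and the individual `mr_estimate` objects.
#' @export
mr_all_methods <- function(pairs, ivw_method = c("re", "fe"), n_boot = 1000,
                           seed = 1L) {
  ivw_method <- match.arg(ivw_method)
  check_pairs(pairs, 1L, "mr_all_methods")
  n <- nrow(pairs)
  ests <- list()
  ests$ivw <- if (n == 1L) mr_wald_ratio(pairs) else mr_ivw(pairs, ivw_method)
  egger <- NULL
  if (n >= 3L) {
    egger <- mr_egger(pairs)
    ests$egger <- egger$estimate
  }
  if (n >= 2L) {
    ests$weighted_median <- mr_weighted_median(pairs, n_boot = n_boot,
                                               seed = seed)
  }
  het <- if (n >= 2L) mr_cochran_q(pairs, mr_ivw(pairs, "fe")) else NULL
  tab <- do.call(rbind, lapply(ests, function(e) {
    data.frame(method = e$method, n_snps = e$n_snps, beta = e$beta, se = e$se,
               pval = e$pval, or = e$or_point, ci_low = e$or_ci[1],
               ci_high = e$or_ci[2], stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(estimates = tab,
       pleiotropy = if (!is.null(egger)) egger$pleiotropy else NULL,
       heterogeneity = het,
       fits = ests)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
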