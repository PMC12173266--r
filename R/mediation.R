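# Two-phase causal screen and two-step mediation decomposition:
# total effect c (exposure -> outcome), reverse check d (outcome -> exposure),
# mediator paths a (exposure -> mediator) and b (mediator -> outcome),
# mediated effect a*b, mediated proportion (a*b)/c, direct effect c' = c - a*b.

#' Run one univariable two-sample MR analysis
#'
#' The full single-direction pipeline: instrument selection from the
#' exposure table ([select_instruments()]), harmonization against the
#' outcome ([harmonize()]), optional MR-PRESSO outlier exclusion, and the
#' estimator battery ([mr_all_methods()]).
#'
#' @param exposure,outcome [sumstats] tables.
#' @param ld LD lookup for clumping.
#' @param config a [selection_config] for the exposure's instruments.
#' @param eaf_window palindromic ambiguity window for [harmonize()].
#' @param drop_all_palindromic strict palindromic handling flag.
#' @param ivw_method `"re"` or `"fe"`.
#' @param presso run MR-PRESSO outlier exclusion before estimation when at
#'   least 4 instruments remain.
#' @param n_presso MR-PRESSO replicates.
#' @param n_boot weighted-median bootstrap replicates.
#' @param seed integer seed for stochastic components.
#' @param no_ld distance-only clumping (see [clump()]).
#' @return list of class `mr_analysis`: `ivw` (`mr_estimate`), `all`
#'   (output of [mr_all_methods()]), `pairs`, `n_snps`, `presso`,
#'   `selection` (report), `harmonization_exclusions`, `leave_one_out`,
#'   `exposure`, `outcome`.
#' @export
mr_analysis <- function(exposure, outcome, ld, config = selection_config(),
                        eaf_window = c(0.42, 0.58),
                        drop_all_palindromic = FALSE,
                        ivw_method = c("re", "fe"), presso = TRUE,
                        n_presso = 1000, n_boot = 1000, seed = 1L,
                        no_ld = FALSE) {
  ivw_method <- match.arg(ivw_method)
  instruments <- select_instruments(exposure, ld, config, no_ld = no_ld)
  if (nrow(instruments) == 0L) {
    stop("no instruments available for exposure '", trait_name(exposure), "'",
         call. = FALSE)
  }
  pairs <- harmonize(instruments, outcome, eaf_window = eaf_window,
                     drop_all_palindromic = drop_all_palindromic)
  if (nrow(pairs) == 0L) {
    stop("no harmonized instruments for '", trait_name(exposure), "' -> '",
         trait_name(outcome), "'", call. = FALSE)
  }
  presso_res <- NULL
  if (presso && nrow(pairs) >= 4L) {
    presso_res <- mr_presso(pairs, n_simulations = n_presso, seed = seed)
    pairs_used <- presso_res$retained
    if (nrow(pairs_used) >= 1L) pairs <- pairs_used
  }
  all <- mr_all_methods(pairs, ivw_method = ivw_method, n_boot = n_boot,
                        seed = seed)
  loo <- if (nrow(pairs) >= 3L) mr_leave_one_out(pairs) else NULL
  structure(list(ivw = all$fits$ivw, all = all, pairs = pairs,
                 n_snps = nrow(pairs), presso = presso_res,
                 selection = selection_report(instruments),
                 harmonization_exclusions = exclusions(pairs),
                 leave_one_out = loo,
                 exposure = trait_name(exposure),
                 outcome = trait_name(outcome)),
            class = "mr_analysis")
}

#' @export
print.mr_analysis <- function(x, ...) {
  cat(sprintf("MR analysis: %s -> %s (%d instruments)\n",
              x$exposure, x$outcome, x$n_snps))
  print(x$ivw)
  invisible(x)
}

#' Bidirectional causal screen
#'
#' Phase-1 check for a candidate exposure: forward MR (exposure -> outcome,
#' total effect c) and reverse MR (outcome -> exposure, effect d), each a
#' full selection/harmonization/estimation run. The screen passes when the
#' forward IVW is significant and the reverse IVW is not, i.e. the forward
#' association is unlikely to reflect reverse causation.
#'
#' @param exposure_stats,outcome_stats [sumstats] tables.
#' @param ld LD lookup.
#' @param config forward-direction [selection_config] (default p < 5e-5).
#' @param reverse_config reverse-direction config; the default applies the
#'   stricter genome-wide p < 5e-8 conventional for a disease trait used as
#'   exposure.
#' @param alpha significance gate (default 0.05).
#' @param ... passed to [mr_analysis()].
#' @return list of class `bidirectional_result`: `forward`, `reverse`
#'   (each an `mr_analysis` or a failure message), `passes_screen`,
#'   `reason`.
#' @export
bidirectional_screen <- function(exposure_stats, outcome_stats, ld,
                                 config = selection_config(p_threshold = 5e-5),
                                 reverse_config = selection_config(p_threshold = 5e-8),
                                 alpha = 0.05, ...) {
  fwd <- try(mr_analysis(exposure_stats, outcome_stats, ld, config, ...),
             silent = TRUE)
  rev <- try(mr_analysis(outcome_stats, exposure_stats, ld, reverse_config, ...),
             silent = TRUE)
  if (inherits(fwd, "try-error")) {
    return(structure(list(forward = NULL, reverse = NULL,
                          passes_screen = FALSE,
                          reason = paste("forward MR failed:",
                                         attr(fwd, "condition")$message)),
                     class = "bidirectional_result"))
  }
  fwd_sig <- fwd$ivw$pval < alpha
  if (inherits(rev, "try-error")) {
    # no valid reverse instruments: reverse causation cannot be assessed as
    # significant, treat as a pass provided the forward effect is there
    rev_sig <- FALSE
    rev <- NULL
  } else {
    rev_sig <- rev$ivw$pval < alpha
  }
  passes <- fwd_sig && !rev_sig
  reason <- if (!fwd_sig) {
    "forward effect not significant"
  } else if (rev_sig) {
    "significant reverse effect"
  } else NA_character_
  structure(list(forward = fwd, reverse = rev, passes_screen = passes,
                 reason = reason),
            class = "bidirectional_result")
}

#' @export
print.bidirectional_result <- function(x, ...) {
  cat("Bidirectional screen:",
      if (isTRUE(x$passes_screen)) "PASS" else paste0("FAIL (", x$reason, ")"),
      "\n")
  invisible(x)
}

#' Mediated effect with delta-method interval
#'
#' Product of coefficients: `effect = a * b` with the (unstandardized)
#' delta-method standard error `sqrt(a^2 se_b^2 + b^2 se_a^2)`, a 95% normal
#' interval, and a two-sided normal p-value. A seeded Monte Carlo
#' product-distribution interval is available as an alternative.
#'
#' @param a,b `mr_estimate` objects (or lists with `beta` and `se`).
#' @param method `"delta"` (default) or `"montecarlo"`.
#' @param n_mc Monte Carlo draws for `method = "montecarlo"`.
#' @param seed seed for the Monte Carlo method.
#' @return list `effect`, `se`, `ci` (length 2), `pval`.
#' @export
#' @examples
#' mediated_effect_ci(list(beta = 0.3, se = 0.05), list(beta = 0.4, se = 0.05))
mediated_effect_ci <- function(a, b, method = c("delta", "montecarlo"),
                               n_mc = 10000, seed = 1L) {
  method <- match.arg(method)
  effect <- a$beta * b$beta
  if (method == "delta") {
    se <- sqrt(a$beta^2 * b$se^2 + b$beta^2 * a$se^2)
    ci <- effect + c(-1, 1) * stats::qnorm(0.975) * se
    pval <- if (se == 0) 1 else 2 * stats::pnorm(-abs(effect / se))
  } else {
    draws <- with_seed(seed, {
      stats::rnorm(n_mc, a$beta, a$se) * stats::rnorm(n_mc, b$beta, b$se)
    })
    se <- stats::sd(draws)
    ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
    pval <- min(1, 2 * min(mean(draws <= 0) + 1 / n_mc,
                           mean(draws >= 0) + 1 / n_mc))
  }
  list(effect = effect, se = se, ci = ci, pval = pval)
}

#' Two-step mediation analysis for one exposure/mediator/outcome triple
#'
#' Phase-2 decomposition. Requires (unless `force = TRUE`):
#' the bidirectional screen passed for exposure -> outcome; a significant
#' exposure -> mediator effect (a); and a significant mediator -> outcome
#' effect (b). The total effect c is the forward IVW of the screen, the
#' mediated effect is `a * b` with a delta-method interval, the mediated
#' proportion is `(a * b) / c`, and the direct effect is `c' = c - a * b`.
#' The proportion is reported only when the mediated effect and c share a
#' sign; otherwise the result is flagged `inconsistent` and the proportion
#' withheld. All effects are on the log-odds scale for a binary outcome.
#'
#' @param exposure_stats,mediator_stats,outcome_stats [sumstats] tables.
#' @param ld LD lookup.
#' @param config [selection_config] for the molecular traits (p < 5e-5).
#' @param reverse_config config for the outcome used as exposure (p < 5e-8).
#' @param alpha significance gate.
#' @param force assemble the decomposition even when a gate fails.
#' @param ci_method passed to [mediated_effect_ci()].
#' @param ... passed to [mr_analysis()].
#' @return list of class `mediation_result`: `a`, `b`, `c` (`mr_estimate`s),
#'   `screen`, `mediated_effect`, `mediated_se`, `mediated_ci`,
#'   `mediated_pval`, `proportion`, `c_prime`, `consistent`, `passed`,
#'   `reject_stage` (`NA`, `"screen"`, `"a"`, or `"b"`).
#' @export
mediation_pipeline <- function(exposure_stats, mediator_stats, outcome_stats,
                               ld, config = selection_config(p_threshold = 5e-5),
                               reverse_config = selection_config(p_threshold = 5e-8),
                               alpha = 0.05, force = FALSE,
                               ci_method = "delta", ...) {
  screen <- bidirectional_screen(exposure_stats, outcome_stats, ld,
                                 config = config,
                                 reverse_config = reverse_config,
                                 alpha = alpha, ...)
  reject <- NA_character_
  if (!screen$passes_screen) reject <- "screen"
  if (!is.na(reject) && !force) {
    return(structure(list(screen = screen, passed = FALSE,
                          reject_stage = reject,
                          reason = screen$reason),
                     class = "mediation_result"))
  }
  a_run <- mr_analysis(exposure_stats, mediator_stats, ld, config, ...)
  if (is.na(reject) && a_run$ivw$pval >= alpha) reject <- "a"
  if (identical(reject, "a") && !force) {
    return(structure(list(screen = screen, a = a_run$ivw, passed = FALSE,
                          reject_stage = reject,
                          reason = "exposure -> mediator effect not significant"),
                     class = "mediation_result"))
  }
  b_run <- mr_analysis(mediator_stats, outcome_stats, ld, config, ...)
  if (is.na(reject) && b_run$ivw$pval >= alpha) reject <- "b"
  if (identical(reject, "b") && !force) {
    return(structure(list(screen = screen, a = a_run$ivw, b = b_run$ivw,
                          passed = FALSE, reject_stage = reject,
                          reason = "mediator -> outcome effect not significant"),
                     class = "mediation_result"))
  }
  a <- a_run$ivw
  b <- b_run$ivw
  c_est <- screen$forward$ivw
  med <- mediated_effect_ci(a, b, method = ci_method)
  consistent <- sign(med$effect) == sign(c_est$beta) || med$effect == 0
  proportion <- if (consistent && c_est$beta != 0) med$effect / c_est$beta else NA_real_
  structure(list(screen = screen, a = a, b = b, c = c_est,
                 a_run = a_run, b_run = b_run,
                 mediated_effect = med$effect, mediated_se = med$se,
                 mediated_ci = med$ci, mediated_pval = med$pval,
                 proportion = proportion,
                 c_prime = c_est$beta - med$effect,
                 consistent = consistent,
                 passed = is.na(reject), reject_stage = reject,
                 reason = NA_character_),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  if (!isTRUE(x$passed)) {
    cat("Mediation pathway rejected at stage:", x$reject_stage, "\n")
    if (!is.na(x$reason)) cat("  ", x$reason, "\n")
    if (is.null(x$mediated_effect)) return(invisible(x))
  }
  cat(sprintf("Mediation: a = %.4g, b = %.4g, c = %.4g\n",
              x$a$beta, x$b$beta, x$c$beta))
  cat(sprintf("  mediated effect a*b = %.4g (95%% CI %.4g to %.4g, p = %.3g)\n",
              x$mediated_effect, x$mediated_ci[1], x$mediated_ci[2],
              x$mediated_pval))
  if (!is.na(x$proportion)) {
    cat(sprintf("  mediated proportion = %.1f%%, direct effect c' = %.4g\n",
                100 * x$proportion, x$c_prime))
  } else {
    cat("  proportion withheld: mediated effect and total effect disagree in sign\n")
  }
  invisible(x)
}

#' Screen every exposure x mediator pathway
#'
#' Evaluates [mediation_pipeline()] for each combination, collecting the
#' passing decompositions and a per-pathway rejection log. Errors in one
#' pathway never abort the batch. No multiple-testing correction is applied
#' by default; `p_adjust` selects one ([stats::p.adjust()] method) applied
#' to the a- and b-path gates.
#'
#' @param exposures,mediators named lists of [sumstats] tables.
#' @param outcome_stats outcome [sumstats] table.
#' @param ld LD lookup.
#' @param p_adjust multiple-testing method (`"none"`, `"bonferroni"`,
#'   `"fdr"`, ...) for the pathway gates.
#' @param alpha significance gate.
#' @param ... passed to [mediation_pipeline()].
#' @return list of class `pathway_report`: `results` (passing
#'   `mediation_result`s, named `exposure|mediator`), `table` (one row per
#'   evaluated pathway with the report columns), `rejections`.
#' @export
batch_screen <- function(exposures, mediators, outcome_stats, ld,
                         p_adjust = "none", alpha = 0.05, ...) {
  if (is.null(names(exposures))) {
    names(exposures) <- vapply(exposures, trait_name, character(1))
  }
  if (length(mediators) > 0L && is.null(names(mediators))) {
    names(mediators) <- vapply(mediators, trait_name, character(1))
  }
  rows <- list()
  results <- list()
  rejections <- list()
  for (ex_name in names(exposures)) {
    for (md_name in names(mediators)) {
      key <- paste(ex_name, md_name, sep = "|")
      res <- try(mediation_pipeline(exposures[[ex_name]], mediators[[md_name]],
                                    outcome_stats, ld, alpha = alpha, ...),
                 silent = TRUE)
      if (inherits(res, "try-error")) {
        rejections[[key]] <- paste("error:", attr(res, "condition")$message)
        next
      }
      if (!isTRUE(res$passed)) {
        rejections[[key]] <- sprintf("rejected at stage '%s'", res$reject_stage)
        next
      }
      results[[key]] <- res
      rows[[key]] <- data.frame(
        exposure = ex_name, mediator = md_name,
        outcome = trait_name(outcome_stats),
        a_beta = res$a$beta, a_pval = res$a$pval,
        b_beta = res$b$beta, b_pval = res$b$pval,
        c_beta = res$c$beta, c_pval = res$c$pval,
        d_pval = if (!is.null(res$screen$reverse)) res$screen$reverse$ivw$pval else NA_real_,
        mediated_effect = res$mediated_effect,
        mediated_ci_low = res$mediated_ci[1],
        mediated_ci_high = res$mediated_ci[2],
        mediated_pval = res$mediated_pval,
        proportion = res$proportion,
        c_prime = res$c_prime,
        flags = if (res$consistent) "" else "inconsistent_sign",
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows) > 0L) do.call(rbind, rows) else empty_pathway_table()
  rownames(tab) <- NULL
  if (p_adjust != "none" && nrow(tab) > 0L) {
    a_adj <- stats::p.adjust(tab$a_pval, method = p_adjust)
    b_adj <- stats::p.adjust(tab$b_pval, method = p_adjust)
    drop <- a_adj >= alpha | b_adj >= alpha
    dropped_keys <- paste(tab$exposure[drop], tab$mediator[drop], sep = "|")
    for (key in dropped_keys) {
      rejections[[key]] <- "rejected after multiple-testing adjustment"
    }
    results[dropped_keys] <- NULL
    tab <- tab[!drop, , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(list(results = results, table = tab,
                 rejections = unlist(rejections)),
            class = "pathway_report")
}

empty_pathway_table <- function() {
  data.frame(exposure = character(0), mediator = character(0),
             outcome = character(0), a_beta = numeric(0), a_pval = numeric(0),
             b_beta = numeric(0), b_pval = numeric(0), c_beta = numeric(0),
             c_pval = numeric(0), d_pval = numeric(0),
             mediated_effect = numeric(0), mediated_ci_low = numeric(0),
             mediated_ci_high = numeric(0), mediated_pval = numeric(0),
             proportion = numeric(0), c_prime = numeric(0),
             flags = character(0), stringsAsFactors = FALSE)
}

#' @export
print.pathway_report <- function(x, ...) {
  cat(sprintf("Pathway report: %d passing, %d rejected\n",
              nrow(x$table), length(x$rejections)))
  if (nrow(x$table) > 0L) print(x$table)
  invisible(x)
}
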