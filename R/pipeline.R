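# End-to-end orchestration: configuration, the two analysis phases, result
# tables, and a reproducibility manifest. All tables are TSV; the manifest
# is JSON and suffices to rerun a phase byte-identically.

#' Assemble a run configuration
#'
#' @param exposures list of exposure specs, each a list with `path`,
#'   optional `column_map`, optional `trait_name`, optional `trait_type`
#'   (default continuous).
#' @param mediators list of mediator specs (same shape); may be empty for
#'   phase 1.
#' @param outcome outcome spec (same shape; `trait_type` default binary).
#' @param ld_path path to a 3-column LD TSV (`id_a`, `id_b`, `r2`)
#'   or `NULL` with `no_ld = TRUE`.
#' @param output_dir directory for result tables and the manifest.
#' @param selection forward-direction [selection_config].
#' @param reverse_selection config for the outcome used as exposure.
#' @param eaf_window palindromic ambiguity window.
#' @param drop_all_palindromic strict palindromic handling.
#' @param ivw_method `"re"` or `"fe"`.
#' @param n_boot,n_presso replicate counts for the stochastic components.
#' @param seed integer seed (mandatory; drives every stochastic component).
#' @param alpha significance gate.
#' @param p_adjust multiple-testing method for [batch_screen()].
#' @param no_ld distance-only clumping.
#' @return A `run_config` list.
#' @export
run_config <- function(exposures, mediators = list(), outcome, ld_path = NULL,
                       output_dir,
                       selection = selection_config(p_threshold = 5e-5),
                       reverse_selection = selection_config(p_threshold = 5e-8),
                       eaf_window = c(0.42, 0.58),
                       drop_all_palindromic = FALSE,
                       ivw_method = "re", n_boot = 1000, n_presso = 1000,
                       seed, alpha = 0.05, p_adjust = "none", no_ld = FALSE) {
  if (missing(seed)) stop("run_config requires an explicit seed", call. = FALSE)
  if (is.null(ld_path) && !no_ld) {
    stop("run_config needs ld_path unless no_ld = TRUE", call. = FALSE)
  }
  cfg <- list(exposures = exposures, mediators = mediators, outcome = outcome,
              ld_path = ld_path, output_dir = output_dir,
              selection = unclass(selection),
              reverse_selection = unclass(reverse_selection),
              eaf_window = eaf_window,
              drop_all_palindromic = drop_all_palindromic,
              ivw_method = ivw_method, n_boot = n_boot, n_presso = n_presso,
              seed = as.integer(seed), alpha = alpha, p_adjust = p_adjust,
              no_ld = no_ld)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The file holds the fields of [run_config()]; `selection` /
#' `reverse_selection` are nested maps of the [selection_config()] fields.
#' All referenced input paths are validated to exist.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON config file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  sel <- do.call(selection_config, as.list(raw$selection %||% list()))
  rsel_defaults <- list(p_threshold = 5e-8)
  rsel <- do.call(selection_config,
                  utils::modifyList(rsel_defaults,
                                    as.list(raw$reverse_selection %||% list())))
  args <- list(exposures = raw$exposures, mediators = raw$mediators %||% list(),
               outcome = raw$outcome, ld_path = raw$ld_path,
               output_dir = raw$output_dir, selection = sel,
               reverse_selection = rsel, seed = raw$seed)
  for (f in c("eaf_window", "drop_all_palindromic", "ivw_method", "n_boot",
              "n_presso", "alpha", "p_adjust", "no_ld")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  cfg <- do.call(run_config, args)
  validate_config_paths(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_config_paths <- function(cfg) {
  paths <- c(vapply(cfg$exposures, function(s) s$path, character(1)),
             if (length(cfg$mediators) > 0L)
               vapply(cfg$mediators, function(s) s$path, character(1)),
             cfg$outcome$path,
             if (!is.null(cfg$ld_path)) cfg$ld_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("configured input path(s) do not exist: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

load_spec <- function(spec, default_type = "continuous") {
  read_sumstats(spec$path, column_map = spec$column_map,
                trait_name = spec$trait_name %||%
                  sub("\\.[^.]*$", "", basename(spec$path)),
                trait_type = spec$trait_type %||% default_type)
}

load_config_inputs <- function(cfg) {
  exposures <- lapply(cfg$exposures, load_spec)
  names(exposures) <- vapply(exposures, trait_name, character(1))
  mediators <- lapply(cfg$mediators, load_spec)
  if (length(mediators) > 0L) {
    names(mediators) <- vapply(mediators, trait_name, character(1))
  }
  outcome <- load_spec(cfg$outcome, default_type = "binary")
  ld <- if (!is.null(cfg$ld_path)) ld_lookup(cfg$ld_path, default = 0) else NULL
  list(exposures = exposures, mediators = mediators, outcome = outcome,
       ld = ld)
}

write_manifest <- function(cfg, phase, dir, outputs) {
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(phase = phase,
                   config = unclass(cfg),
                   config_md5 = unname(tools::md5sum(tmp)),
                   seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("medmr")),
                   outputs = outputs)
  unlink(tmp)
  path <- file.path(dir, sprintf("%s_manifest.json", phase))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

stage_log <- function(dir, phase, lines) {
  path <- file.path(dir, sprintf("%s_log.txt", phase))
  writeLines(lines, path)
  invisible(path)
}

#' Phase 1: bidirectional screen of every exposure against the outcome
#'
#' Runs the full bidirectional MR (selection, harmonization, estimator
#' battery, diagnostics) for each configured exposure, and writes
#' `phase1_results.tsv`, a per-stage variant-count log, and a JSON manifest
#' to the configured output directory.
#'
#' @param cfg a [run_config] (or a path readable by [read_run_config()]).
#' @return invisibly, a list with `table` (the results data.frame) and
#'   `screens` (the `bidirectional_result` objects).
#' @export
run_phase1 <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_config_paths(cfg)
  inputs <- load_config_inputs(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  screens <- list()
  rows <- list()
  log_lines <- character(0)
  for (nm in names(inputs$exposures)) {
    scr <- bidirectional_screen(
      inputs$exposures[[nm]], inputs$outcome, inputs$ld,
      config = selection_config_from(cfg$selection),
      reverse_config = selection_config_from(cfg$reverse_selection),
      alpha = cfg$alpha, eaf_window = cfg$eaf_window,
      drop_all_palindromic = cfg$drop_all_palindromic,
      ivw_method = cfg$ivw_method, n_presso = cfg$n_presso,
      n_boot = cfg$n_boot, seed = cfg$seed, no_ld = cfg$no_ld)
    screens[[nm]] <- scr
    fwd <- scr$forward
    rev <- scr$reverse
    rows[[nm]] <- data.frame(
      exposure = nm, outcome = trait_name(inputs$outcome),
      n_snps_forward = if (!is.null(fwd)) fwd$n_snps else NA_integer_,
      c_beta = if (!is.null(fwd)) fwd$ivw$beta else NA_real_,
      c_se = if (!is.null(fwd)) fwd$ivw$se else NA_real_,
      c_pval = if (!is.null(fwd)) fwd$ivw$pval else NA_real_,
      c_or = if (!is.null(fwd)) fwd$ivw$or_point else NA_real_,
      d_beta = if (!is.null(rev)) rev$ivw$beta else NA_real_,
      d_pval = if (!is.null(rev)) rev$ivw$pval else NA_real_,
      passes_screen = scr$passes_screen,
      reason = if (is.na(scr$reason %||% NA)) "" else scr$reason,
      stringsAsFactors = FALSE)
    log_lines <- c(log_lines, funnel_lines(nm, fwd), funnel_lines(
      paste0(trait_name(inputs$outcome), " (reverse vs ", nm, ")"), rev))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  out_path <- file.path(cfg$output_dir, "phase1_results.tsv")
  write_tsv_exact(tab, out_path)
  stage_log(cfg$output_dir, "phase1", log_lines)
  write_manifest(cfg, "phase1", cfg$output_dir, outputs = "phase1_results.tsv")
  invisible(list(table = tab, screens = screens))
}

selection_config_from <- function(x) {
  if (inherits(x, "selection_config")) x else do.call(selection_config, x)
}

funnel_lines <- function(label, run) {
  if (is.null(run)) return(sprintf("%s: no valid MR run", label))
  rep <- run$selection
  n_in <- nrow(rep)
  n_p <- sum(rep$drop_reason %in% "pvalue")
  n_c <- sum(rep$drop_reason %in% "clump")
  n_f <- sum(rep$drop_reason %in% "f_filter")
  n_sel <- sum(rep$kept)
  excl <- run$harmonization_exclusions
  n_presso_out <- if (!is.null(run$presso)) length(run$presso$outliers) else 0L
  c(sprintf("%s: %d variants in", label, n_in),
    sprintf("  p-value screen dropped %d, clumping dropped %d, F-filter dropped %d -> %d instruments",
            n_p, n_c, n_f, n_sel),
    sprintf("  harmonization excluded %d (%s)", nrow(excl),
            if (nrow(excl) > 0L) {
              paste(names(table(excl$reason)), table(excl$reason),
                    sep = "=", collapse = ", ")
            } else "none"),
    sprintf("  MR-PRESSO removed %d outlier(s) -> %d analyzed", n_presso_out,
            run$n_snps))
}

#' Phase 2: mediation screen over every exposure x mediator pathway
#'
#' Runs [batch_screen()] with the configured gates, writing the pathway
#' report (`phase2_pathways.tsv`), per-pathway diagnostics
#' (`phase2_diagnostics.tsv`: Egger intercept and p, Cochran Q and p,
#' MR-PRESSO global p and outlier count, leave-one-out flags for each MR
#' run of each passing pathway), a rejection log, and a JSON manifest.
#'
#' @param cfg a [run_config] or config path.
#' @param force run even when no exposure passes phase 1 (a warning is
#'   logged; each pathway still applies its own gates).
#' @return invisibly, the `pathway_report`.
#' @export
run_phase2 <- function(cfg, force = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_config_paths(cfg)
  inputs <- load_config_inputs(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  phase1_path <- file.path(cfg$output_dir, "phase1_results.tsv")
  log_lines <- character(0)
  if (file.exists(phase1_path)) {
    p1 <- utils::read.delim(phase1_path, stringsAsFactors = FALSE)
    if (!any(p1$passes_screen) && !force) {
      stop("no exposure passed the phase-1 screen; rerun with force = TRUE ",
           "to evaluate pathways anyway", call. = FALSE)
    }
  } else if (!force) {
    stop("phase 1 results not found in ", cfg$output_dir,
         "; run run_phase1() first or use force = TRUE", call. = FALSE)
  } else {
    log_lines <- c(log_lines,
                   "WARNING: phase 2 forced without phase 1 results")
    warning("phase 2 forced without phase 1 results", call. = FALSE)
  }
  report <- batch_screen(inputs$exposures, inputs$mediators, inputs$outcome,
                         inputs$ld,
                         p_adjust = cfg$p_adjust, alpha = cfg$alpha,
                         config = selection_config_from(cfg$selection),
                         reverse_config = selection_config_from(cfg$reverse_selection),
                         eaf_window = cfg$eaf_window,
                         drop_all_palindromic = cfg$drop_all_palindromic,
                         ivw_method = cfg$ivw_method, n_presso = cfg$n_presso,
                         n_boot = cfg$n_boot, seed = cfg$seed,
                         no_ld = cfg$no_ld)
  write_tsv_exact(report$table, file.path(cfg$output_dir, "phase2_pathways.tsv"))
  diag <- pathway_diagnostics(report)
  write_tsv_exact(diag, file.path(cfg$output_dir, "phase2_diagnostics.tsv"))
  log_lines <- c(log_lines,
                 sprintf("%d pathway(s) passing, %d rejected",
                         nrow(report$table), length(report$rejections)),
                 if (length(report$rejections) > 0L) {
                   paste0("  ", names(report$rejections), ": ",
                          report$rejections)
                 })
  stage_log(cfg$output_dir, "phase2", log_lines)
  write_manifest(cfg, "phase2", cfg$output_dir,
                 outputs = c("phase2_pathways.tsv", "phase2_diagnostics.tsv"))
  invisible(report)
}

pathway_diagnostics <- function(report) {
  rows <- list()
  for (key in names(report$results)) {
    res <- report$results[[key]]
    runs <- list(c_path = res$screen$forward, a_path = res$a_run,
                 b_path = res$b_run)
    for (leg in names(runs)) {
      run <- runs[[leg]]
      if (is.null(run)) next
      pl <- run$all$pleiotropy
      het <- run$all$heterogeneity
      rows[[paste(key, leg)]] <- data.frame(
        pathway = key, leg = leg, n_snps = run$n_snps,
        egger_intercept = if (!is.null(pl)) pl$intercept else NA_real_,
        intercept_pval = if (!is.null(pl)) pl$pval else NA_real_,
        q_stat = if (!is.null(het)) het$q_stat else NA_real_,
        q_df = if (!is.null(het)) het$df else NA_integer_,
        q_pval = if (!is.null(het)) het$pval else NA_real_,
        presso_global_pval = if (!is.null(run$presso)) run$presso$global_pval else NA_real_,
        n_presso_outliers = if (!is.null(run$presso)) length(run$presso$outliers) else 0L,
        n_loo_flagged = if (!is.null(run$leave_one_out)) sum(run$leave_one_out$flagged) else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) {
    do.call(rbind, rows)
  } else {
    data.frame(pathway = character(0), leg = character(0),
               n_snps = integer(0), egger_intercept = numeric(0),
               intercept_pval = numeric(0), q_stat = numeric(0),
               q_df = integer(0), q_pval = numeric(0),
               presso_global_pval = numeric(0),
               n_presso_outliers = integer(0), n_loo_flagged = integer(0),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Quick self-test of the estimator battery
#'
#' Runs a handful of closed-form identities and a small null-calibration
#' simulation; intended as a smoke test of an installation.
#'
#' @param n_reps calibration replicates.
#' @param seed integer seed.
#' @return invisibly, a named logical vector of check results; all must be
#'   `TRUE` on a healthy installation.
#' @export
medmr_selftest <- function(n_reps = 200, seed = 42L) {
  checks <- c(
    f_spot = abs(f_statistic(0.5, 3, 1) - 1) < 1e-12,
    ivw_spot = {
      pairs <- harmonized_pairs(data.frame(
        variant_id = c("a", "b"), beta_exposure = c(1, 1),
        se_exposure = c(0.1, 0.1), beta_outcome = c(0.5, 0.5),
        se_outcome = c(0.1, 0.1)))
      est <- mr_ivw(pairs, "fe")
      abs(est$beta - 0.5) < 1e-12 && abs(est$se - sqrt(1 / 200)) < 1e-12
    },
    median_spot = {
      pairs <- harmonized_pairs(data.frame(
        variant_id = c("a", "b", "c"), beta_exposure = 1, se_exposure = 0.1,
        beta_outcome = c(0.1, 0.2, 0.3), se_outcome = 0.1))
      abs(weighted_median_point(pairs$beta_exposure, pairs$beta_outcome,
                                pairs$se_outcome) - 0.2) < 1e-12
    },
    null_calibration = {
      rej <- vapply(seq_len(n_reps), function(i) {
        pairs <- simulate_harmonized_pairs(30, beta = 0, seed = seed + i)
        mr_ivw(pairs)$pval < 0.05
      }, logical(1))
      mean(rej) < 0.12
    })
  if (!all(checks)) {
    warning("selftest failures: ",
            paste(names(checks)[!checks], collapse = ", "), call. = FALSE)
  } else {
    message("medmr selftest: all ", length(checks), " checks passed")
  }
  invisible(checks)
}
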