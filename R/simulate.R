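# Synthetic GWAS summary statistics under an explicit
# exposure -> mediator -> outcome structural model, generated for three
# non-overlapping cohorts that share one variant panel and allele coding.

#' Define a simulation scenario
#'
#' Parameterizes the synthetic causal world. Three disjoint cohorts (as
#' two-sample MR assumes) are genotyped on a shared panel; phenotypes follow
#' the structural equations
#' \deqn{X = \sum_j \gamma_j G_j + \epsilon_X}
#' \deqn{M = a X + \sum_j \alpha_j G_j + \epsilon_M}
#' \deqn{\mathrm{logit}\, P(Y=1) = \beta_0 + b M + c' X + \sum_j \delta_j G_j}
#' where the exposure instruments carry \eqn{\gamma}, a disjoint set of
#' mediator instruments carries \eqn{\alpha}, a third disjoint set of
#' outcome-specific instruments carries \eqn{\eta} (direct disease loci,
#' emulating a disease GWAS's own genetic architecture and giving the
#' reverse-direction analysis genuine instruments), and \eqn{\delta} is
#' horizontal pleiotropy on the exposure instruments (zero, balanced
#' zero-mean, or directional shifted-mean normal). The implied total effect
#' of X on Y is
#' `c = c_prime_true + a_true * b_true` and the mediated proportion is
#' `a_true * b_true / c`.
#'
#' Defaults mirror a desk-scale lipidome/metabolite/disease design:
#' continuous-trait cohorts of 7174 and 8299, a binary-outcome cohort of
#' 20000 at 5% prevalence, and 30 instruments per molecular trait with
#' per-variant F-statistics around 40-60.
#'
#' @param n_snps variant-panel size.
#' @param n_exposure,n_mediator,n_outcome cohort sizes.
#' @param maf_range range of minor-allele frequencies, within (0, 0.5].
#' @param n_instruments_x,n_instruments_m,n_instruments_y counts of true
#'   exposure, mediator, and outcome-specific instruments (disjoint sets).
#' @param gamma_sd,alpha_sd,eta_sd SD of the per-variant instrument effects.
#'   The default `eta_sd` is larger than the molecular traits': genome-wide
#'   significant disease loci are large-effect by construction, and an
#'   autoimmune outcome's top hits (e.g. HLA-region variants) dwarf
#'   trait-mediated SNP effects, which keeps the reverse-direction
#'   instrument set essentially free of exposure-mediated variants.
#' @param a_true,b_true,c_prime_true structural coefficients.
#' @param pleiotropy_mode `"none"`, `"balanced"`, or `"directional"`.
#' @param pleiotropy_sd scale of the pleiotropic outcome effects; the
#'   directional mode shifts their mean by the same amount.
#' @param outcome_prevalence baseline case fraction of the binary outcome.
#' @param outcome_mode `"logistic"` (binary outcome, per-variant logistic
#'   regression log-ORs) or `"linear"` (continuous outcome on the structural
#'   scale; collapsible, used for exact parameter-recovery checks).
#' @param ld_blocks optional `list(block_size =, r =)` giving non-overlapping
#'   LD blocks with fixed within-block genotype correlation `r` (so pairwise
#'   r-squared about `r^2`); `NULL` for an independent panel.
#' @param seed integer seed.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(n_snps = 120, n_exposure = 7174, n_mediator = 8299,
                         n_outcome = 20000, maf_range = c(0.05, 0.5),
                         n_instruments_x = 30, n_instruments_m = 30,
                         n_instruments_y = 30,
                         gamma_sd = 0.15, alpha_sd = 0.15, eta_sd = 0.4,
                         a_true = 0.3, b_true = 0.4, c_prime_true = 0.1,
                         pleiotropy_mode = c("none", "balanced", "directional"),
                         pleiotropy_sd = 0.05, outcome_prevalence = 0.05,
                         outcome_mode = c("logistic", "linear"),
                         ld_blocks = NULL, seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  outcome_mode <- match.arg(outcome_mode)
  stopifnot(n_snps >= 1, n_exposure > 2, n_mediator > 2, n_outcome > 2,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_instruments_x + n_instruments_m + n_instruments_y <= n_snps,
            outcome_prevalence > 0, outcome_prevalence < 1)
  if (!is.null(ld_blocks)) {
    stopifnot(is.list(ld_blocks), ld_blocks$block_size >= 1,
              ld_blocks$r >= 0, ld_blocks$r < 1)
  }
  structure(list(n_snps = n_snps, n_exposure = n_exposure,
                 n_mediator = n_mediator, n_outcome = n_outcome,
                 maf_range = maf_range, n_instruments_x = n_instruments_x,
                 n_instruments_m = n_instruments_m,
                 n_instruments_y = n_instruments_y, gamma_sd = gamma_sd,
                 alpha_sd = alpha_sd, eta_sd = eta_sd,
                 a_true = a_true, b_true = b_true,
                 c_prime_true = c_prime_true,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_sd = pleiotropy_sd,
                 outcome_prevalence = outcome_prevalence,
                 outcome_mode = outcome_mode, ld_blocks = ld_blocks,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate three-cohort GWAS summary statistics
#'
#' Draws genotypes per cohort under Hardy-Weinberg equilibrium (with
#' optional within-block correlation via a Gaussian copula), generates
#' phenotypes from the structural model of [sim_scenario()], and estimates
#' per-variant associations: ordinary least squares for continuous traits
#' and per-variant logistic regression (Newton scoring, vectorized across
#' variants) for the binary outcome, so outcome betas are genuine log odds
#' ratios. Fully reproducible from the scenario seed.
#'
#' @param scenario a [sim_scenario].
#' @return list of class `sim_output`: `exposure_stats`, `mediator_stats`,
#'   `outcome_stats` ([sumstats] tables), `truth` (per-variant gamma, alpha,
#'   delta, the structural coefficients, instrument ID sets, intercept and
#'   realized prevalence), and `ld` (an [ld_lookup] of realized pairwise
#'   r-squared for all same-chromosome pairs within the 10 Mb clump window,
#'   measured in the exposure cohort; `default = 0`).
#' @export
simulate_gwas <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    m <- sc$n_snps
    maf <- stats::runif(m, sc$maf_range[1], sc$maf_range[2])
    panel <- sim_panel(m, maf,
                       block_size = if (!is.null(sc$ld_blocks)) {
                         sc$ld_blocks$block_size
                       } else 1L)
    idx_x <- sort(sample.int(m, sc$n_instruments_x))
    idx_m <- sort(sample(setdiff(seq_len(m), idx_x), sc$n_instruments_m))
    idx_y <- sort(sample(setdiff(seq_len(m), c(idx_x, idx_m)),
                         sc$n_instruments_y))
    gamma <- numeric(m); gamma[idx_x] <- stats::rnorm(sc$n_instruments_x, 0, sc$gamma_sd)
    alpha <- numeric(m); alpha[idx_m] <- stats::rnorm(sc$n_instruments_m, 0, sc$alpha_sd)
    eta <- numeric(m); eta[idx_y] <- stats::rnorm(sc$n_instruments_y, 0, sc$eta_sd)
    delta <- numeric(m)
    if (sc$pleiotropy_mode == "balanced") {
      delta[idx_x] <- stats::rnorm(sc$n_instruments_x, 0, sc$pleiotropy_sd)
    } else if (sc$pleiotropy_mode == "directional") {
      delta[idx_x] <- stats::rnorm(sc$n_instruments_x, sc$pleiotropy_sd,
                                   sc$pleiotropy_sd)
    }

    # exposure cohort
    g_e <- sim_genotypes(sc$n_exposure, maf, sc$ld_blocks)
    x_e <- drop(g_e %*% gamma) + stats::rnorm(sc$n_exposure)
    exposure_stats <- assoc_table(g_e, x_e, panel, "exposure", "continuous")
    ld <- realized_ld(g_e, panel, window_bp = 1e7)

    # mediator cohort
    g_m <- sim_genotypes(sc$n_mediator, maf, sc$ld_blocks)
    x_m <- drop(g_m %*% gamma) + stats::rnorm(sc$n_mediator)
    med <- sc$a_true * x_m + drop(g_m %*% alpha) + stats::rnorm(sc$n_mediator)
    mediator_stats <- assoc_table(g_m, med, panel, "mediator", "continuous")

    # outcome cohort
    g_o <- sim_genotypes(sc$n_outcome, maf, sc$ld_blocks)
    x_o <- drop(g_o %*% gamma) + stats::rnorm(sc$n_outcome)
    m_o <- sc$a_true * x_o + drop(g_o %*% alpha) + stats::rnorm(sc$n_outcome)
    lp <- sc$b_true * m_o + sc$c_prime_true * x_o + drop(g_o %*% (delta + eta))
    if (sc$outcome_mode == "logistic") {
      beta0 <- solve_intercept(lp, sc$outcome_prevalence)
      y <- stats::rbinom(sc$n_outcome, 1L, stats::plogis(beta0 + lp))
      if (sum(y) == 0L || sum(y) == sc$n_outcome) {
        stop("outcome prevalence incompatible with requested effect sizes: ",
             "sampled ", sum(y), " cases of ", sc$n_outcome, call. = FALSE)
      }
      outcome_stats <- assoc_table(g_o, y, panel, "outcome", "binary",
                                   logistic = TRUE)
      prevalence_realized <- mean(y)
    } else {
      beta0 <- 0
      y <- lp + stats::rnorm(sc$n_outcome)
      outcome_stats <- assoc_table(g_o, y, panel, "outcome", "continuous")
      prevalence_realized <- NA_real_
    }

    truth <- list(gamma = gamma, alpha = alpha, delta = delta, eta = eta,
                  instruments_x = panel$variant_id[idx_x],
                  instruments_m = panel$variant_id[idx_m],
                  instruments_y = panel$variant_id[idx_y],
                  a_true = sc$a_true, b_true = sc$b_true,
                  c_prime_true = sc$c_prime_true,
                  c_total = sc$c_prime_true + sc$a_true * sc$b_true,
                  maf = maf, beta0 = beta0,
                  prevalence_realized = prevalence_realized,
                  scenario = unclass(sc))
    structure(list(exposure_stats = exposure_stats,
                   mediator_stats = mediator_stats,
                   outcome_stats = outcome_stats,
                   truth = truth, ld = ld),
              class = "sim_output")
  })
}

# Variant panel: IDs, chromosomes, positions, alleles. Blocks of adjacent
# variants sit within 10 kb steps; successive blocks are separated by 20 Mb
# so cross-block pairs never fall inside the default 10 Mb clump window.
sim_panel <- function(m, maf, block_size = 1L) {
  block <- (seq_len(m) - 1L) %/% block_size
  within <- (seq_len(m) - 1L) %% block_size
  chrom <- as.character((block %% 22L) + 1L)
  pos <- as.integer(1e6 + (block %/% 22L) * 2e7 + within * 1e4)
  alleles <- t(vapply(seq_len(m), function(i) sample(VALID_BASES, 2L),
                      character(2)))
  data.frame(variant_id = sprintf("rs%06d", seq_len(m)), chrom = chrom,
             pos = pos, effect_allele = alleles[, 1], other_allele = alleles[, 2],
             stringsAsFactors = FALSE)
}

# HWE genotype dosages, optionally with block-correlated latent Gaussians
# (Gaussian copula; dosage correlation is close to the latent correlation).
sim_genotypes <- function(n, maf, ld_blocks = NULL) {
  m <- length(maf)
  if (is.null(ld_blocks) || ld_blocks$block_size <= 1L || ld_blocks$r == 0) {
    return(matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), nrow = n))
  }
  bs <- ld_blocks$block_size
  r <- ld_blocks$r
  g <- matrix(0L, n, m)
  for (hap in 1:2) {
    block_id <- (seq_len(m) - 1L) %/% bs
    shared <- matrix(stats::rnorm(n * (max(block_id) + 1L)), nrow = n)
    z <- sqrt(r) * shared[, block_id + 1L, drop = FALSE] +
      sqrt(1 - r) * matrix(stats::rnorm(n * m), nrow = n)
    u <- stats::pnorm(z)
    g <- g + (u < rep(maf, each = n))
  }
  storage.mode(g) <- "integer"
  g
}

# Vectorized per-variant association estimates.
assoc_table <- function(g, y, panel, trait, type, logistic = FALSE) {
  n <- nrow(g)
  if (logistic) {
    fit <- logistic_scan(g, y)
    beta <- fit$beta; se <- fit$se
    pval <- 2 * stats::pnorm(-abs(beta / se))
  } else {
    gbar <- colMeans(g)
    ybar <- mean(y)
    sxx <- colSums(g^2) - n * gbar^2
    sxy <- drop(crossprod(g, y)) - n * gbar * ybar
    syy <- sum(y^2) - n * ybar^2
    beta <- sxy / sxx
    rss <- pmax(syy - beta * sxy, 0)
    se <- sqrt(rss / (n - 2) / sxx)
    pval <- 2 * stats::pt(-abs(beta / se), df = n - 2)
  }
  pval <- pmax(pval, .Machine$double.xmin)
  df <- panel
  df$eaf <- colMeans(g) / 2
  df$beta <- beta
  df$se <- se
  df$pval <- pval
  df$n <- n
  sumstats(df, trait_name = trait, trait_type = type)
}

# Per-variant two-parameter logistic regression (Newton scoring), compiled;
# solves logit P(y=1) = b0_j + b1_j g_j for every column j of g. Identical
# to glm(family = binomial) at convergence.
logistic_scan <- function(g, y, max_iter = 50L, tol = 1e-10) {
  storage.mode(g) <- "integer"
  fit <- .logistic_scan_cpp(g, as.integer(y), max_iter, tol)
  bad <- !is.finite(fit$beta) | !is.finite(fit$se) | fit$se <= 0
  if (any(bad)) {
    stop("per-variant logistic regression is not estimable for ", sum(bad),
         " variant(s) (separation or empty genotype class); increase the ",
         "outcome cohort size or prevalence", call. = FALSE)
  }
  fit
}

# Intercept such that the mean simulated case probability hits the target
# prevalence given the sampled linear predictors.
solve_intercept <- function(lp, prevalence) {
  stats::uniroot(function(b0) mean(stats::plogis(b0 + lp)) - prevalence,
                 interval = c(-30, 30), tol = 1e-10)$root
}

# Empirical pairwise genotype r^2 for all same-chromosome pairs within
# window_bp, as a long-format pair table wrapped in an ld_lookup.
realized_ld <- function(g, panel, window_bp = 1e7) {
  pairs <- list()
  for (ch in unique(panel$chrom)) {
    idx <- which(panel$chrom == ch)
    if (length(idx) < 2L) next
    idx <- idx[order(panel$pos[idx])]
    for (i in seq_along(idx)[-length(idx)]) {
      for (j in (i + 1L):length(idx)) {
        if (panel$pos[idx[j]] - panel$pos[idx[i]] > window_bp) break
        r <- suppressWarnings(stats::cor(g[, idx[i]], g[, idx[j]]))
        if (is.na(r)) r <- 0
        pairs[[length(pairs) + 1L]] <- data.frame(
          id_a = panel$variant_id[idx[i]], id_b = panel$variant_id[idx[j]],
          r2 = r^2, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(pairs) > 0L) {
    do.call(rbind, pairs)
  } else {
    data.frame(id_a = character(0), id_b = character(0), r2 = numeric(0))
  }
  ld <- ld_lookup(tab, default = 0)
  attr(ld, "pairs") <- tab
  ld
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf(paste0("Simulated GWAS: %d variants; cohorts n = %d / %d / %d; ",
                     "a = %.3g, b = %.3g, c' = %.3g\n"),
              nrow(x$exposure_stats), x$truth$scenario$n_exposure,
              x$truth$scenario$n_mediator, x$truth$scenario$n_outcome,
              x$truth$a_true, x$truth$b_true, x$truth$c_prime_true))
  invisible(x)
}

#' Write a simulated dataset as plain-text fixtures
#'
#' Emits the three summary-statistics TSVs, the realized LD pair TSV
#' (`id_a`, `id_b`, `r2`), and a `truth.json`, in the formats consumed by
#' [read_sumstats()] and [ld_lookup()]. Numeric values are written at full
#' precision, so [read_fixtures()] reproduces the in-memory tables exactly.
#'
#' @param sim a `sim_output` from [simulate_gwas()].
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_fixtures <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_output"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sumstats(sim$exposure_stats, file.path(dir, "exposure.tsv"))
  write_sumstats(sim$mediator_stats, file.path(dir, "mediator.tsv"))
  write_sumstats(sim$outcome_stats, file.path(dir, "outcome.tsv"))
  write_tsv_exact(attr(sim$ld, "pairs"), file.path(dir, "ld.tsv"))
  truth <- sim$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read back a fixture directory written by [write_fixtures()]
#'
#' @param dir fixture directory.
#' @return list with `exposure_stats`, `mediator_stats`, `outcome_stats`,
#'   `truth`, `ld`.
#' @export
read_fixtures <- function(dir) {
  exposure <- read_sumstats(file.path(dir, "exposure.tsv"),
                            trait_name = "exposure")
  mediator <- read_sumstats(file.path(dir, "mediator.tsv"),
                            trait_name = "mediator")
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  outcome_type <- if (identical(truth$scenario$outcome_mode, "logistic")) {
    "binary"
  } else "continuous"
  outcome <- read_sumstats(file.path(dir, "outcome.tsv"),
                           trait_name = "outcome", trait_type = outcome_type)
  pairs <- utils::read.delim(file.path(dir, "ld.tsv"),
                             stringsAsFactors = FALSE,
                             colClasses = c("character", "character", "numeric"))
  ld <- ld_lookup(pairs, default = 0)
  attr(ld, "pairs") <- pairs
  list(exposure_stats = exposure, mediator_stats = mediator,
       outcome_stats = outcome, truth = truth, ld = ld)
}

#' Simulate harmonized instrument pairs at the summary level
#'
#' A lightweight generator that draws per-instrument summary associations
#' directly from their asymptotic sampling distributions, bypassing
#' individual-level data: `bx_j ~ N(gamma_j, se_x)`, and
#' `by_j ~ N(beta * gamma_j + pleio_j, se_y)`. Useful for fast calibration
#' and robustness studies of the estimators themselves.
#'
#' @param n_snps number of instruments.
#' @param beta true causal effect.
#' @param gamma_mean,gamma_sd distribution of true instrument effects
#'   (effects are drawn once per call).
#' @param se_exposure,se_outcome sampling standard errors (recycled).
#' @param pleiotropy per-variant intercepts added to the outcome means
#'   (recycled; default 0).
#' @param seed integer seed.
#' @return a `harmonized` pair table.
#' @export
simulate_harmonized_pairs <- function(n_snps, beta = 0, gamma_mean = 0.15,
                                      gamma_sd = 0.05, se_exposure = 0.02,
                                      se_outcome = 0.05, pleiotropy = 0,
                                      seed = 1L) {
  with_seed(seed, {
    gamma <- stats::rnorm(n_snps, gamma_mean, gamma_sd)
    bx <- stats::rnorm(n_snps, gamma, se_exposure)
    by <- stats::rnorm(n_snps, beta * gamma + pleiotropy, se_outcome)
    harmonized_pairs(data.frame(
      variant_id = sprintf("rs%06d", seq_len(n_snps)),
      beta_exposure = bx, se_exposure = rep_len(se_exposure, n_snps),
      beta_outcome = by, se_outcome = rep_len(se_outcome, n_snps),
      stringsAsFactors = FALSE))
  })
}
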