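#' Selection configuration for genetic instruments
#'
#' Bundles the thresholds of the three-stage instrument funnel: genome-wide
#' p-value screen, greedy distance/r-squared clumping, and per-variant
#' F-statistic filter.
#'
#' @param p_threshold significance cutoff for the screen. The conventional
#'   choices are `5e-5` for molecular exposures/mediators and `5e-8` for a
#'   disease outcome used as exposure in the reverse direction.
#' @param clump_kb clumping window in kilobases (default 10000).
#' @param clump_r2 LD r-squared threshold; variants with r2 >= this value
#'   with a better index variant are pruned (default 0.001).
#' @param f_min minimum per-variant F-statistic; variants with F <= `f_min`
#'   are dropped (default 10).
#' @param r2_estimator `"t"` for the t-statistic identity
#'   `r2 = t^2 / (t^2 + n - 2)` (no allele frequency needed) or `"eaf"` for
#'   the standardized-trait approximation `2 * eaf * (1 - eaf) * beta^2`.
#' @return A `selection_config` list.
#' @export
selection_config <- function(p_threshold = 5e-5, clump_kb = 10000,
                             clump_r2 = 0.001, f_min = 10,
                             r2_estimator = c("t", "eaf")) {
  stopifnot(p_threshold > 0, clump_kb > 0, clump_r2 >= 0, clump_r2 <= 1,
            f_min >= 0)
  structure(list(p_threshold = p_threshold, clump_kb = clump_kb,
                 clump_r2 = clump_r2, f_min = f_min,
                 r2_estimator = match.arg(r2_estimator)),
            class = "selection_config")
}

#' P-value screen
#'
#' Keeps the records with `pval < p_threshold`, preserving input order.
#'
#' @param table a [sumstats] object.
#' @param p_threshold significance cutoff.
#' @return The filtered [sumstats] table.
#' @export
pvalue_screen <- function(table, p_threshold) {
  stopifnot(inherits(table, "sumstats"), p_threshold > 0)
  keep <- table$pval < p_threshold
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L && nrow(table) > 0L) {
    warning("no variants pass p < ", format(p_threshold), " for trait '",
            trait_name(table), "'", call. = FALSE)
  }
  out
}

#' Linkage-disequilibrium lookup
#'
#' Wraps pairwise r-squared values in a uniform lookup. Accepts a long-format
#' data.frame (`id_a`, `id_b`, `r2`), a dense symmetric matrix with variant
#' IDs as dimnames, or a file path to a 3-column TSV. Pairs absent from a
#' long-format table are taken as r2 = 0 only when `default` is supplied.
#'
#' @param x pair table, matrix, or path.
#' @param default value returned for pairs not present (default `NA`, which
#'   makes [clump()] raise an error for missing pairs).
#' @return An `ld_lookup` object.
#' @export
ld_lookup <- function(x, default = NA_real_) {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.delim(x, stringsAsFactors = FALSE)
  }
  env <- new.env(parent = emptyenv(), hash = TRUE)
  if (is.matrix(x)) {
    ids <- rownames(x)
    stopifnot(!is.null(ids), identical(ids, colnames(x)))
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i < j) assign(pair_key(ids[i], ids[j]), x[i, j], envir = env)
      }
    }
  } else {
    x <- as.data.frame(x)
    stopifnot(all(c("id_a", "id_b", "r2") %in% names(x)))
    for (i in seq_len(nrow(x))) {
      assign(pair_key(x$id_a[i], x$id_b[i]), x$r2[i], envir = env)
    }
  }
  structure(list(env = env, default = default), class = "ld_lookup")
}

pair_key <- function(a, b) {
  if (a < b) paste0(a, "\r", b) else paste0(b, "\r", a)
}

#' Query pairwise LD r-squared
#' @param ld an [ld_lookup], or a `function(id_a, id_b)`.
#' @param id_a,id_b variant identifiers.
#' @return scalar r-squared (or the lookup's default when the pair is absent).
#' @export
ld_r2 <- function(ld, id_a, id_b) {
  if (id_a == id_b) return(1)
  if (is.function(ld)) return(ld(id_a, id_b))
  stopifnot(inherits(ld, "ld_lookup"))
  key <- pair_key(id_a, id_b)
  if (exists(key, envir = ld$env, inherits = FALSE)) {
    get(key, envir = ld$env, inherits = FALSE)
  } else {
    ld$default
  }
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining variant with the smallest p-value as an
#' index variant, then discards every remaining variant on the same
#' chromosome within `clump_kb` kilobases whose r-squared with the index is
#' at least `clump_r2`. Ties in p-value are broken by (chrom, pos,
#' variant_id) so the result does not depend on input row order.
#'
#' @param table a [sumstats] object.
#' @param ld an [ld_lookup] object or `function(id_a, id_b) -> r2`. May be
#'   `NULL` only with `no_ld = TRUE`.
#' @param clump_kb window in kilobases.
#' @param clump_r2 r-squared threshold (prune when r2 >= threshold).
#' @param no_ld if `TRUE`, prune by distance alone: every variant within the
#'   window of a better index is dropped regardless of LD. This is an
#'   approximation for use when no LD source is available.
#' @return The clumped [sumstats] table (index variants, original row order).
#' @export
clump <- function(table, ld, clump_kb = 10000, clump_r2 = 0.001,
                  no_ld = FALSE) {
  stopifnot(inherits(table, "sumstats"))
  if (nrow(table) <= 1L) return(table)
  if (!no_ld && is.null(ld)) {
    stop("clump() needs an LD lookup unless no_ld = TRUE", call. = FALSE)
  }
  ord <- order(table$pval, table$chrom, table$pos, table$variant_id)
  active <- rep(TRUE, nrow(table))
  kept <- logical(nrow(table))
  window_bp <- clump_kb * 1000
  for (i in ord) {
    if (!active[i]) next
    kept[i] <- TRUE
    active[i] <- FALSE
    near <- which(active &
                    table$chrom == table$chrom[i] &
                    abs(table$pos - table$pos[i]) <= window_bp)
    for (j in near) {
      if (no_ld) {
        active[j] <- FALSE
      } else {
        r2 <- ld_r2(ld, table$variant_id[i], table$variant_id[j])
        if (is.na(r2)) {
          stop("LD lookup failed for pair (", table$variant_id[i], ", ",
               table$variant_id[j], ")", call. = FALSE)
        }
        if (r2 >= clump_r2) active[j] <- FALSE
      }
    }
  }
  out <- table[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instrument-strength F-statistic
#'
#' `F = (r2 / (1 - r2)) * ((n - k - 1) / k)` where `r2` is the variance in
#' the exposure explained by the instrument(s), `n` the sample size, and `k`
#' the number of instruments (per-variant filtering uses `k = 1`). F > 10 is
#' the conventional weak-instrument cutoff.
#'
#' @param r2 explained variance in `[0, 1)`.
#' @param n total sample size (`n > k + 1`).
#' @param k number of instruments (`k >= 1`).
#' @return F-statistic.
#' @export
#' @examples
#' f_statistic(0.5, 3, 1)        # 1
#' f_statistic(0.01, 7174, 1)    # 72.44...
f_statistic <- function(r2, n, k = 1) {
  if (any(r2 < 0 | r2 >= 1)) stop("r2 must be in [0, 1)", call. = FALSE)
  if (any(n <= k + 1)) stop("n must exceed k + 1", call. = FALSE)
  if (any(k < 1)) stop("k must be >= 1", call. = FALSE)
  (r2 / (1 - r2)) * ((n - k - 1) / k)
}

#' Per-variant explained variance
#'
#' Default estimator uses the t-statistic identity
#' `r2 = t^2 / (t^2 + n - 2)` with `t = beta / se`, which needs no allele
#' frequency. The `"eaf"` alternative `2 * eaf * (1 - eaf) * beta^2` assumes
#' a standardized (unit-variance) trait.
#'
#' @param beta,se,n per-variant effect, standard error, sample size.
#' @param eaf effect-allele frequency (only for `estimator = "eaf"`).
#' @param estimator `"t"` or `"eaf"`.
#' @return r-squared values.
#' @export
estimate_r2 <- function(beta, se, n, eaf = NULL, estimator = c("t", "eaf")) {
  estimator <- match.arg(estimator)
  if (estimator == "t") {
    if (any(n <= 2)) stop("n must be > 2 for the t-statistic r2", call. = FALSE)
    t2 <- (beta / se)^2
    t2 / (t2 + n - 2)
  } else {
    if (is.null(eaf) || anyNA(eaf)) {
      stop("eaf required for the frequency-based r2 estimator", call. = FALSE)
    }
    pmin(2 * eaf * (1 - eaf) * beta^2, 1 - 1e-12)
  }
}

#' Select genetic instruments
#'
#' Composition of [pvalue_screen()], [clump()], and the F-statistic filter
#' (drop variants with `F <= f_min`, per-variant `k = 1`). The attached
#' report accounts for every input variant's fate.
#'
#' @param table a [sumstats] object.
#' @param ld LD lookup passed to [clump()].
#' @param config a [selection_config].
#' @param no_ld prune by distance alone (see [clump()]).
#' @return The selected [sumstats] table with attribute `report`: a
#'   data.frame (`variant_id`, `pval`, `r2`, `f_stat`, `kept`, `drop_reason`)
#'   where `drop_reason` is one of `pvalue`, `clump`, `f_filter`, or `NA`.
#' @export
select_instruments <- function(table, ld, config = selection_config(),
                               no_ld = FALSE) {
  stopifnot(inherits(table, "sumstats"), inherits(config, "selection_config"))
  report <- data.frame(variant_id = table$variant_id, pval = table$pval,
                       r2 = NA_real_, f_stat = NA_real_, kept = FALSE,
                       drop_reason = NA_character_, stringsAsFactors = FALSE)
  s1 <- pvalue_screen(table, config$p_threshold)
  report$drop_reason[!(report$variant_id %in% s1$variant_id)] <- "pvalue"
  s2 <- if (nrow(s1) > 0L) {
    clump(s1, ld, clump_kb = config$clump_kb, clump_r2 = config$clump_r2,
          no_ld = no_ld)
  } else s1
  clumped_away <- setdiff(s1$variant_id, s2$variant_id)
  report$drop_reason[report$variant_id %in% clumped_away] <- "clump"
  if (nrow(s2) > 0L) {
    r2 <- if (config$r2_estimator == "t") {
      estimate_r2(s2$beta, s2$se, s2$n)
    } else {
      estimate_r2(s2$beta, s2$se, s2$n, eaf = s2$eaf, estimator = "eaf")
    }
    f <- f_statistic(r2, s2$n, k = 1)
    idx <- match(s2$variant_id, report$variant_id)
    report$r2[idx] <- r2
    report$f_stat[idx] <- f
    weak <- s2$variant_id[f <= config$f_min]
    report$drop_reason[report$variant_id %in% weak] <- "f_filter"
    keep <- setdiff(s2$variant_id, weak)
    out <- s2[s2$variant_id %in% keep, , drop = FALSE]
  } else {
    out <- s2
  }
  rownames(out) <- NULL
  report$kept <- is.na(report$drop_reason)
  if (nrow(out) == 0L && nrow(table) > 0L) {
    warning("no instruments survive selection for trait '",
            trait_name(table), "'", call. = FALSE)
  }
  attr(out, "report") <- report
  out
}

#' Selection report accessor
#' @param x result of [select_instruments()].
#' @return the per-variant selection report data.frame.
#' @export
selection_report <- function(x) attr(x, "report", exact = TRUE)
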