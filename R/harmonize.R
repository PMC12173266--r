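#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome associations onto the exposure's effect-allele frame so
#' both betas refer to the same allele. For each variant present in both
#' tables:
#'
#' * identical allele pairs are kept as-is;
#' * swapped allele pairs (outcome effect allele = exposure other allele) have
#'   the outcome beta negated and its frequency complemented (`flipped`);
#' * palindromic variants (A/T, C/G) with exposure effect-allele frequency
#'   inside `eaf_window` are excluded as `"ambiguous"` — near 0.5 the strand
#'   cannot be inferred from frequency;
#' * palindromic variants outside the window are aligned by frequency
#'   agreement: if the allele-matched outcome frequency falls on the opposite
#'   side of 0.5 from the exposure frequency, the record is interpreted as
#'   strand-flipped and corrected (beta negated, frequency complemented);
#' * palindromic variants lacking an exposure or outcome frequency are
#'   excluded (`"missing_eaf"`), and allele sets that match neither directly
#'   nor by swap are excluded (`"incompatible"`).
#'
#' @param exposure,outcome [sumstats] tables.
#' @param eaf_window numeric length-2, the ambiguity window on the exposure
#'   effect-allele frequency for palindromic variants. Default `c(0.42, 0.58)`.
#' @param drop_all_palindromic if `TRUE`, exclude every palindromic variant
#'   regardless of frequency (the strict reading).
#' @return A `harmonized` data.frame with columns `variant_id`,
#'   `beta_exposure`, `se_exposure`, `pval_exposure`, `eaf_exposure`,
#'   `beta_outcome`, `se_outcome`, `flipped`, `palindromic`, and attributes
#'   `exclusions` (data.frame `variant_id`, `reason`), `exposure_name`,
#'   `outcome_name`, `outcome_type`.
#' @export
harmonize <- function(exposure, outcome, eaf_window = c(0.42, 0.58),
                      drop_all_palindromic = FALSE) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"),
            length(eaf_window) == 2L, eaf_window[1] <= eaf_window[2])
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0L) {
    stop("no overlapping variants between '", trait_name(exposure), "' and '",
         trait_name(outcome), "'", call. = FALSE)
  }
  ex <- exposure[match(shared, exposure$variant_id), ]
  ou <- outcome[match(shared, outcome$variant_id), ]

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  same <- ou$effect_allele == ex$effect_allele & ou$other_allele == ex$other_allele
  swap <- ou$effect_allele == ex$other_allele & ou$other_allele == ex$effect_allele
  # NB: for palindromic variants `same` and `swap` cannot both hold (alleles
  # differ), but a swap there is indistinguishable from a strand flip; the
  # frequency rule below resolves orientation in either representation.

  beta_out <- ifelse(swap, -ou$beta, ou$beta)
  eaf_out <- ifelse(swap, 1 - ou$eaf, ou$eaf)
  flipped <- swap

  reason <- rep(NA_character_, length(shared))
  reason[!same & !swap] <- "incompatible"
  in_window <- !is.na(ex$eaf) & ex$eaf >= eaf_window[1] & ex$eaf <= eaf_window[2]
  if (drop_all_palindromic) {
    reason[pal & is.na(reason)] <- "palindromic"
  } else {
    reason[pal & is.na(reason) & in_window] <- "ambiguous"
    reason[pal & is.na(reason) & (is.na(ex$eaf) | is.na(eaf_out))] <- "missing_eaf"
    # frequency agreement for the remaining palindromic variants
    idx <- which(pal & is.na(reason))
    if (length(idx) > 0L) {
      disagree <- (ex$eaf[idx] < 0.5) != (eaf_out[idx] < 0.5)
      fix <- idx[disagree]
      beta_out[fix] <- -beta_out[fix]
      eaf_out[fix] <- 1 - eaf_out[fix]
      flipped[fix] <- !flipped[fix]
    }
  }

  keep <- is.na(reason)
  res <- data.frame(
    variant_id = shared[keep],
    chrom = ex$chrom[keep],
    pos = ex$pos[keep],
    effect_allele = ex$effect_allele[keep],
    other_allele = ex$other_allele[keep],
    beta_exposure = ex$beta[keep],
    se_exposure = ex$se[keep],
    pval_exposure = ex$pval[keep],
    eaf_exposure = ex$eaf[keep],
    beta_outcome = beta_out[keep],
    se_outcome = ou$se[keep],
    pval_outcome = ou$pval[keep],
    eaf_outcome = eaf_out[keep],
    flipped = flipped[keep],
    palindromic = pal[keep],
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  exclusions <- data.frame(variant_id = shared[!keep],
                           reason = reason[!keep],
                           stringsAsFactors = FALSE)
  structure(res,
            exclusions = exclusions,
            exposure_name = trait_name(exposure),
            outcome_name = trait_name(outcome),
            outcome_type = trait_type(outcome),
            class = c("harmonized", "data.frame"))
}

#' Exclusion log of a harmonization
#' @param x a `harmonized` object.
#' @return data.frame with `variant_id` and `reason`
#'   (`ambiguous`/`incompatible`/`missing_eaf`/`palindromic`).
#' @export
exclusions <- function(x) attr(x, "exclusions", exact = TRUE)

#' @export
`[.harmonized` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    for (a in c("exclusions", "exposure_name", "outcome_name", "outcome_type")) {
      attr(out, a) <- attr(x, a)
    }
    class(out) <- class(x)
  }
  out
}

#' @export
print.harmonized <- function(x, ...) {
  cat(sprintf("Harmonized pairs: %s -> %s, %d variants kept, %d excluded\n",
              attr(x, "exposure_name"), attr(x, "outcome_name"),
              nrow(x), nrow(exclusions(x))))
  NextMethod()
}

#' Write harmonized pairs and their exclusion log as TSV
#'
#' @param x a `harmonized` object.
#' @param path output TSV for the kept pairs.
#' @param exclusions_path optional output TSV for the exclusion log.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(x, path, exclusions_path = NULL) {
  write_tsv_exact(as.data.frame(x), path)
  if (!is.null(exclusions_path)) write_tsv_exact(exclusions(x), exclusions_path)
  invisible(path)
}

# Build a harmonized object directly from aligned columns (used by the
# summary-level simulator and by tests).
harmonized_pairs <- function(df, exposure_name = "exposure",
                             outcome_name = "outcome",
                             outcome_type = "continuous") {
  need <- c("variant_id", "beta_exposure", "se_exposure", "beta_outcome",
            "se_outcome")
  stopifnot(all(need %in% names(df)))
  if (is.null(df$pval_exposure)) {
    df$pval_exposure <- 2 * stats::pnorm(-abs(df$beta_exposure / df$se_exposure))
  }
  if (is.null(df$pval_outcome)) {
    df$pval_outcome <- 2 * stats::pnorm(-abs(df$beta_outcome / df$se_outcome))
  }
  if (is.null(df$flipped)) df$flipped <- FALSE
  if (is.null(df$palindromic)) df$palindromic <- FALSE
  structure(as.data.frame(df),
            exclusions = data.frame(variant_id = character(0),
                                    reason = character(0)),
            exposure_name = exposure_name,
            outcome_name = outcome_name,
            outcome_type = outcome_type,
            class = c("harmonized", "data.frame"))
}
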