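#' @keywords internal
#' @useDynLib medmr, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")

VALID_BASES <- c("A", "C", "G", "T")

#' Construct a GWAS summary-statistics table
#'
#' A `sumstats` object is a `data.frame` with one row per variant and the
#' columns `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pval`, `n`, plus the attributes `trait_name` and
#' `trait_type`. For binary traits `beta` is a log odds ratio per copy of the
#' effect allele.
#'
#' @param df data.frame containing the required columns. Alleles are
#'   normalized to upper case; `eaf` may be `NA`.
#' @param trait_name character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param validate validate every row and fail on any violation (default).
#' @return A `sumstats` data.frame.
#' @export
sumstats <- function(df, trait_name, trait_type = c("continuous", "binary"),
                     validate = TRUE) {
  trait_type <- match.arg(trait_type)
  missing_cols <- setdiff(SUMSTATS_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("sumstats is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[SUMSTATS_COLS]
  df$variant_id <- as.character(df$variant_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) df[[col]] <- as.numeric(df[[col]])
  df$n <- as.integer(df$n)
  rownames(df) <- NULL
  if (validate) {
    errs <- validate_sumstats_rows(df)
    if (length(errs) > 0L) {
      stop("invalid summary statistics for trait '", trait_name, "':\n  ",
           paste(errs, collapse = "\n  "), call. = FALSE)
    }
  }
  structure(df,
            trait_name = trait_name,
            trait_type = trait_type,
            class = c("sumstats", "data.frame"))
}

#' @export
`[.sumstats` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "trait_name") <- attr(x, "trait_name")
    attr(out, "trait_type") <- attr(x, "trait_type")
    class(out) <- class(x)
  }
  out
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d variants\n",
              trait_name(x), trait_type(x), nrow(x)))
  NextMethod()
}

#' Trait metadata accessors
#' @param x a `sumstats` object.
#' @return `trait_name()` the trait label; `trait_type()` `"continuous"` or
#'   `"binary"`.
#' @export
trait_name <- function(x) attr(x, "trait_name", exact = TRUE)

#' @rdname trait_name
#' @export
trait_type <- function(x) attr(x, "trait_type", exact = TRUE)

# Per-row invariant checks; returns a character vector of messages, one per
# violating row, each prefixed with the (1-based) data row number.
validate_sumstats_rows <- function(df) {
  errs <- character(0)
  row_err <- function(rows, msg) {
    if (any(rows, na.rm = TRUE)) {
      sprintf("row %d: %s", which(rows), msg)
    } else character(0)
  }
  bad_ea <- !(df$effect_allele %in% VALID_BASES)
  bad_oa <- !(df$other_allele %in% VALID_BASES)
  errs <- c(errs,
    row_err(bad_ea, "effect_allele must be a single base A/C/G/T"),
    row_err(bad_oa, "other_allele must be a single base A/C/G/T"),
    row_err(!bad_ea & !bad_oa & df$effect_allele == df$other_allele,
            "effect_allele equals other_allele"),
    row_err(is.na(df$se) | df$se <= 0, "se must be > 0"),
    row_err(is.na(df$beta), "beta is missing"),
    row_err(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "pval must be in (0, 1]"),
    row_err(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "eaf must be in [0, 1]"),
    row_err(is.na(df$pos) | df$pos < 1L, "pos must be >= 1"),
    row_err(is.na(df$n) | df$n < 1L, "n must be a positive integer"),
    row_err(is.na(df$variant_id) | df$variant_id == "", "variant_id is empty"))
  dup <- duplicated(df$variant_id)
  if (any(dup)) {
    errs <- c(errs, sprintf("row %d: duplicate variant_id '%s'",
                            which(dup), df$variant_id[dup]))
  }
  errs
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a header-labelled delimited file and maps its columns onto the
#' canonical `sumstats` schema. Every row is validated against the variant
#' invariants (valid single-base alleles, `se > 0`, `pval` in (0,1], ...);
#' all violations are collected and reported together with their file line
#' numbers.
#'
#' @param path file path.
#' @param column_map named character vector or list mapping canonical names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`) to the file's column names. Canonical names
#'   absent from the map are assumed to be used verbatim in the file.
#' @param trait_name trait label; defaults to the file name without extension.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param delim field delimiter, tab by default.
#' @return A [sumstats] object.
#' @export
#' @examples
#' path <- tempfile(fileext = ".tsv")
#' df <- data.frame(variant_id = c("rs1", "rs2"), chrom = "1",
#'                  pos = c(100L, 2000L), effect_allele = c("a", "C"),
#'                  other_allele = c("g", "T"), eaf = c(0.2, 0.4),
#'                  beta = c(0.1, -0.05), se = 0.02, pval = c(1e-6, 0.01),
#'                  n = 5000L)
#' write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
#' ss <- read_sumstats(path, trait_name = "lipid", trait_type = "continuous")
read_sumstats <- function(path, column_map = NULL,
                          trait_name = sub("\\.[^.]*$", "", basename(path)),
                          trait_type = c("continuous", "binary"),
                          delim = "\t") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("summary-statistics file not found: ", path,
                               call. = FALSE)
  raw <- utils::read.delim(path, sep = delim, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  cmap <- stats::setNames(SUMSTATS_COLS, SUMSTATS_COLS)
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    unknown <- setdiff(names(column_map), SUMSTATS_COLS)
    if (length(unknown) > 0L) {
      stop("column_map refers to unknown canonical field(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    cmap[names(column_map)] <- column_map
  }
  missing_src <- setdiff(unname(cmap), names(raw))
  if (length(missing_src) > 0L) {
    stop("mapped column(s) not present in ", path, ": ",
         paste(missing_src, collapse = ", "), call. = FALSE)
  }
  df <- stats::setNames(raw[unname(cmap)], names(cmap))
  suppressWarnings({
    df$pos <- as.integer(df$pos)
    for (col in c("eaf", "beta", "se", "pval")) df[[col]] <- as.numeric(df[[col]])
    df$n <- as.integer(round(as.numeric(df$n)))
  })
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  errs <- validate_sumstats_rows(df)
  if (length(errs) > 0L) {
    # header occupies line 1, so data row i is file line i + 1
    errs <- sub("^row (\\d+):", "line \\1:", errs)
    errs <- vapply(errs, function(e) {
      m <- regmatches(e, regexec("^line (\\d+):", e))[[1]]
      sub("^line \\d+:", sprintf("line %d:", as.integer(m[2]) + 1L), e)
    }, character(1), USE.NAMES = FALSE)
    stop("invalid rows in ", path, ":\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  sumstats(df, trait_name = trait_name, trait_type = trait_type,
           validate = FALSE)
}

#' Write a summary-statistics table as TSV
#'
#' Numeric columns are written with 17 significant digits so a read/write
#' round trip reproduces the doubles exactly.
#'
#' @param x a [sumstats] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  write_tsv_exact(as.data.frame(x), path)
  invisible(path)
}

# Full-precision TSV writer shared by all table outputs (deterministic bytes).
write_tsv_exact <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- "NA"
      out[[col]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Is an allele pair palindromic?
#'
#' A variant is palindromic when its two alleles are reverse complements of
#' each other (A/T, T/A, C/G, G/C), so the effect allele cannot be told apart
#' from its opposite-strand complement.
#'
#' @param effect_allele,other_allele single bases (vectorized).
#' @return logical vector.
#' @export
#' @examples
#' is_palindromic("A", "T")  # TRUE
#' is_palindromic("A", "G")  # FALSE
is_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele)
  oa <- toupper(other_allele)
  ok <- ea %in% VALID_BASES & oa %in% VALID_BASES
  if (!all(ok)) stop("alleles must be single bases A/C/G/T", call. = FALSE)
  complement_base(ea) == oa
}

complement_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[x])
}
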