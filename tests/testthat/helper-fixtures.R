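# Shared fixture builders and independent oracles.

# Minimal sumstats builder: any column can be overridden; defaults give a
# valid n-variant table on one chromosome with non-palindromic alleles.
make_table <- function(m = 3, trait = "trait", type = "continuous", ...) {
  df <- data.frame(
    variant_id = sprintf("rs%d", seq_len(m)),
    chrom = rep("1", m),
    pos = seq_len(m) * 1000000L,
    effect_allele = rep("A", m),
    other_allele = rep("G", m),
    eaf = rep(0.3, m),
    beta = rep(0.1, m),
    se = rep(0.02, m),
    pval = rep(1e-6, m),
    n = rep(5000L, m),
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  sumstats(df, trait_name = trait, trait_type = type)
}

# Harmonized pairs straight from beta/se vectors.
make_pairs <- function(bx, by, sey, sex = rep(0.01, length(bx)),
                       ids = sprintf("rs%d", seq_along(bx))) {
  medmr:::harmonized_pairs(data.frame(
    variant_id = ids, beta_exposure = bx, se_exposure = sex,
    beta_outcome = by, se_outcome = sey, stringsAsFactors = FALSE))
}

# Independent IVW oracle: brute-force minimizer of the weighted residual sum
# of squares over a dense grid, refined by the parabola through the three
# bracketing grid points (exact, since the objective is quadratic in b).
ivw_oracle <- function(bx, by, sey) {
  w <- 1 / sey^2
  f <- function(b) sum(w * (by - b * bx)^2)
  grid <- seq(-5, 5, length.out = 4001)
  vals <- vapply(grid, f, numeric(1))
  k <- max(2L, min(length(grid) - 1L, which.min(vals)))
  x <- grid[(k - 1L):(k + 1L)]
  y <- vals[(k - 1L):(k + 1L)]
  denom <- (x[2] - x[1]) * (y[2] - y[3]) - (x[2] - x[3]) * (y[2] - y[1])
  x[2] - 0.5 * ((x[2] - x[1])^2 * (y[2] - y[3]) -
                  (x[2] - x[3])^2 * (y[2] - y[1])) / denom
}

# Independent Egger oracle: weighted least squares via stats::lm on pairs
# oriented to non-negative exposure betas.
egger_oracle <- function(bx, by, sey) {
  flip <- sign(bx); flip[flip == 0] <- 1
  fit <- stats::lm(I(by * flip) ~ I(abs(bx)), weights = 1 / sey^2)
  stats::coef(fit)
}

# Two summary-level tables over a shared variant panel, for screen tests.
# betas/pvals are supplied per trait; alleles are fixed non-palindromic.
make_panel_tables <- function(betas, ses, traits, types = NULL, n = 10000L) {
  m <- length(betas[[1]])
  if (is.null(types)) types <- rep("continuous", length(betas))
  lapply(seq_along(betas), function(k) {
    make_table(m, trait = traits[k], type = types[k],
               beta = betas[[k]], se = ses[[k]],
               pval = pmax(2 * stats::pnorm(-abs(betas[[k]] / ses[[k]])),
                           1e-300),
               pos = seq_len(m) * 20000000L,
               chrom = as.character(rep_len(1:22, m)),
               n = n)
  })
}

# LD lookup declaring every pair independent.
ld_zero <- function() medmr:::ld_lookup(
  data.frame(id_a = character(0), id_b = character(0), r2 = numeric(0)),
  default = 0)

# The 10-variant selection fixture with a known fate for every variant.
# Expected: kept {rs2, rs6, rs7}; pvalue-dropped {rs1, rs8, rs10};
# clump-dropped {rs3 (by rs2), rs5 (by rs4)}; F-filter-dropped {rs4, rs9}.
funnel_fixture <- function() {
  tab <- make_table(
    10,
    chrom = c("1", "1", "1", "1", "1", "2", "2", "2", "3", "3"),
    pos = c(5000000L, 1000000L, 1500000L, 30000000L, 31000000L,
            1000000L, 2000000L, 90000000L, 1000000L, 2000000L),
    pval = c(0.5, 1e-6, 1e-5, 2e-6, 3e-6, 4e-6, 5e-6, 0.9, 4.9e-5, 1e-3),
    beta = c(0.1, 0.12, 0.11, 0.03, 0.10, 0.13, 0.12, 0.1, 0.028, 0.1),
    se = c(0.02, 0.012, 0.012, 0.01, 0.012, 0.013, 0.012, 0.02, 0.014, 0.02),
    n = c(5000L, 5000L, 5000L, 1000L, 5000L, 5000L, 5000L, 5000L, 102L, 5000L))
  ld <- medmr:::ld_lookup(data.frame(
    id_a = c("rs2", "rs4", "rs6"),
    id_b = c("rs3", "rs5", "rs7"),
    r2 = c(0.5, 0.9, 0.0005)), default = 0)
  list(table = tab, ld = ld,
       expect_kept = c("rs2", "rs6", "rs7"),
       expect_pvalue = c("rs1", "rs8", "rs10"),
       expect_clump = c("rs3", "rs5"),
       expect_f = c("rs4", "rs9"))
}
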