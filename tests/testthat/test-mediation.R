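test_that("the delta-method product interval is exact on closed-form cases", {
  res <- mediated_effect_ci(list(beta = 0.3, se = 0.05),
                            list(beta = 0.4, se = 0.05))
  expect_equal(res$effect, 0.12, tolerance = 1e-12)
  expect_equal(res$se, sqrt(0.09 * 0.0025 + 0.16 * 0.0025), tolerance = 1e-12)
  expect_equal(res$ci, c(0.071, 0.169), tolerance = 1e-3)
  # null first path: se collapses to |b| * se_a
  res0 <- mediated_effect_ci(list(beta = 0, se = 0.05),
                             list(beta = 0.4, se = 0.05))
  expect_equal(res0$effect, 0)
  expect_equal(res0$se, 0.4 * 0.05, tolerance = 1e-12)
  # Monte Carlo alternative agrees to sampling error and is seeded
  mc1 <- mediated_effect_ci(list(beta = 0.3, se = 0.05),
                            list(beta = 0.4, se = 0.05),
                            method = "montecarlo", seed = 4)
  mc2 <- mediated_effect_ci(list(beta = 0.3, se = 0.05),
                            list(beta = 0.4, se = 0.05),
                            method = "montecarlo", seed = 4)
  expect_identical(mc1, mc2)
  expect_equal(mc1$se, res$se, tolerance = 0.05)
})

test_that("delta-method intervals cover the true product at close to 95%", {
  set.seed(42)
  n <- 2000
  a_hat <- rnorm(n, 0.3, 0.05)
  b_hat <- rnorm(n, 0.4, 0.05)
  covered <- vapply(seq_len(n), function(i) {
    ci <- mediated_effect_ci(list(beta = a_hat[i], se = 0.05),
                             list(beta = b_hat[i], se = 0.05))$ci
    ci[1] <= 0.12 && 0.12 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.97)
})

test_that("the bidirectional screen passes a forward-only causal structure", {
  sim <- simulate_gwas(sim_scenario(n_snps = 70, n_instruments_y = 10,
                                    outcome_mode = "linear",
                                    seed = 501))
  scr <- suppressWarnings(bidirectional_screen(
    sim$exposure_stats, sim$outcome_stats, sim$ld, seed = 1))
  expect_true(scr$passes_screen)
  expect_lt(scr$forward$ivw$pval, 0.05)
})

test_that("a purely reverse-causal world fails the screen", {
  # outcome drives the exposure: the exposure's 'instruments' are really the
  # outcome's, so the reverse arm is significant and the screen must fail
  set.seed(502)
  m <- 30
  gamma_y <- rnorm(m, 0.2, 0.03)
  d <- 0.5
  tabs <- make_panel_tables(
    betas = list(d * gamma_y + rnorm(m, 0, 0.01), gamma_y),
    ses = list(rep(0.01, m), rep(0.01, m)),
    traits = c("exposure", "outcome"))
  scr <- suppressWarnings(bidirectional_screen(tabs[[1]], tabs[[2]],
                                               ld_zero(), seed = 1))
  expect_false(scr$passes_screen)
  expect_identical(scr$reason, "significant reverse effect")
  expect_lt(scr$reverse$ivw$pval, 0.05)
})

test_that("a global null fails the screen on the forward arm", {
  sim <- simulate_gwas(sim_scenario(n_snps = 40, n_instruments_m = 10,
                                    n_instruments_y = 0,
                                    a_true = 0, b_true = 0, c_prime_true = 0,
                                    outcome_mode = "linear", seed = 503))
  scr <- suppressWarnings(bidirectional_screen(
    sim$exposure_stats, sim$outcome_stats, sim$ld, seed = 1))
  expect_false(scr$passes_screen)
  expect_identical(scr$reason, "forward effect not significant")
})

test_that("the mediation decomposition is exact in its algebra", {
  sim <- simulate_gwas(sim_scenario(n_snps = 70, n_instruments_y = 10,
                                    outcome_mode = "linear",
                                    seed = 504))
  res <- suppressWarnings(mediation_pipeline(
    sim$exposure_stats, sim$mediator_stats, sim$outcome_stats, sim$ld,
    seed = 1))
  expect_true(res$passed)
  expect_identical(res$mediated_effect, res$a$beta * res$b$beta)
  expect_equal(res$c_prime + res$mediated_effect, res$c$beta,
               tolerance = 1e-15)
  expect_equal(res$proportion * res$c$beta, res$mediated_effect,
               tolerance = 1e-15)
  # estimates should sit near the generating coefficients (single-replicate
  # windows are wide: one draw of the pipeline carries real sampling noise)
  expect_lt(abs(res$a$beta - 0.3), 0.1)
  expect_lt(abs(res$b$beta - 0.4), 0.1)
  expect_lt(abs(res$proportion - 6 / 11), 0.2)
})

test_that("an opposite-sign mediated path withholds the proportion", {
  sim <- simulate_gwas(sim_scenario(n_snps = 70, n_instruments_y = 10,
                                    c_prime_true = -0.25,
                                    outcome_mode = "linear", seed = 505))
  res <- suppressWarnings(mediation_pipeline(
    sim$exposure_stats, sim$mediator_stats, sim$outcome_stats, sim$ld,
    seed = 1))
  expect_true(res$passed)
  expect_false(res$consistent)
  expect_true(is.na(res$proportion))
  expect_lt(res$c$beta, 0)
  expect_gt(res$mediated_effect, 0)
})

test_that("a null mediator is rejected at the b gate", {
  rejected <- vapply(1:8, function(i) {
    sim <- simulate_gwas(sim_scenario(n_snps = 70, n_instruments_y = 10,
                                      b_true = 0, c_prime_true = 0.22,
                                      outcome_mode = "linear",
                                      seed = 600 + i))
    res <- suppressWarnings(mediation_pipeline(
      sim$exposure_stats, sim$mediator_stats, sim$outcome_stats, sim$ld,
      seed = 1))
    identical(res$reject_stage, "b")
  }, logical(1))
  expect_gte(mean(rejected), 0.75)
})

test_that("the batch screen reports exactly the implanted pathway", {
  set.seed(510)
  m <- 90
  idx_a <- 1:30; idx_b <- 31:60; idx_c <- 61:90
  gamma <- alpha_b <- alpha_c <- numeric(m)
  gamma[idx_a] <- rnorm(30, 0.25, 0.05)
  alpha_b[idx_b] <- rnorm(30, 0.25, 0.05)
  alpha_c[idx_c] <- rnorm(30, 0.25, 0.05)
  a <- 0.3; b <- 0.4; cp <- 0.1
  noise <- function(sd) rnorm(m, 0, sd)
  tabs <- make_panel_tables(
    betas = list(gamma + noise(0.005),
                 noise(0.02),
                 a * gamma + alpha_b + noise(0.02),
                 alpha_c + noise(0.02),
                 (a * b + cp) * gamma + b * alpha_b + noise(0.02)),
    ses = list(rep(0.005, m), rep(0.02, m), rep(0.02, m), rep(0.02, m),
               rep(0.02, m)),
    traits = c("lipid1", "lipid2", "metab1", "metab2", "disease"),
    types = c(rep("continuous", 4), "binary"))
  report <- suppressWarnings(batch_screen(
    exposures = tabs[1:2], mediators = tabs[3:4], outcome_stats = tabs[[5]],
    ld = ld_zero(), seed = 1))
  expect_equal(nrow(report$table), 1)
  expect_identical(report$table$exposure, "lipid1")
  expect_identical(report$table$mediator, "metab1")
  expect_equal(report$table$proportion, a * b / (a * b + cp), tolerance = 0.15)
  expect_gte(length(report$rejections), 3)
  # empty mediator list gives an empty report
  empty <- suppressWarnings(batch_screen(tabs[1:2], list(), tabs[[5]],
                                         ld_zero(), seed = 1))
  expect_equal(nrow(empty$table), 0)
  # determinism: identical rerun
  report2 <- suppressWarnings(batch_screen(
    exposures = tabs[1:2], mediators = tabs[3:4], outcome_stats = tabs[[5]],
    ld = ld_zero(), seed = 1))
  expect_identical(report$table, report2$table)
})

test_that("under the complete null almost no pathway is emitted", {
  emitted <- vapply(1:400, function(i) {
    with_seed <- medmr:::with_seed
    tabs <- with_seed(20000 + i, {
      m <- 40
      gamma <- c(rnorm(20, 0.25, 0.05), numeric(20))
      alpha <- c(numeric(20), rnorm(20, 0.25, 0.05))
      make_panel_tables(
        betas = list(gamma + rnorm(m, 0, 0.005),
                     alpha + rnorm(m, 0, 0.02),
                     rnorm(m, 0, 0.005)),
        ses = list(rep(0.005, m), rep(0.02, m), rep(0.005, m)),
        traits = c("exposure", "mediator", "outcome"))
    })
    rep <- suppressWarnings(batch_screen(tabs[1], tabs[2], tabs[[3]],
                                         ld_zero(), presso = FALSE,
                                         n_boot = 50, seed = 1))
    nrow(rep$table) > 0
  }, logical(1))
  expect_lte(mean(emitted), 0.05)
})
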