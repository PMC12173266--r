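test_that("the Wald ratio and its first-order standard error are exact", {
  expect_equal(mr_wald_ratio(list(beta_exposure = 1, beta_outcome = 0.5,
                                  se_outcome = 0.1))$beta, 0.5)
  est <- mr_wald_ratio(list(beta_exposure = -2, beta_outcome = 1,
                            se_outcome = 0.2))
  expect_equal(est$beta, -0.5)
  expect_equal(est$se, 0.1)
  expect_equal(mr_wald_ratio(list(beta_exposure = 2, beta_outcome = 0,
                                  se_outcome = 0.1))$beta, 0)
  expect_error(mr_wald_ratio(list(beta_exposure = 0, beta_outcome = 1,
                                  se_outcome = 0.1)), "zero")
})

test_that("IVW matches its closed form on hand-computable cases", {
  pairs <- make_pairs(c(1, 1), c(0.5, 0.5), c(0.1, 0.1))
  est <- mr_ivw(pairs, "fe")
  expect_equal(est$beta, 0.5, tolerance = 1e-12)
  expect_equal(est$se, sqrt(1 / 200), tolerance = 1e-12)
  # single instrument reduces to the Wald ratio
  one <- make_pairs(2, 0.6, 0.05)
  expect_equal(mr_ivw(one)$beta, mr_wald_ratio(one)$beta)
  expect_equal(mr_ivw(one)$se, mr_wald_ratio(one)$se)
  # null outcome
  expect_equal(mr_ivw(make_pairs(c(1, 2), c(0, 0), c(0.1, 0.1)))$beta, 0)
  expect_error(mr_ivw(make_pairs(c(0, 0), c(1, 1), c(0.1, 0.1))), "degenerate")
})

test_that("IVW equals the brute-force weighted least-squares minimizer", {
  set.seed(201)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    bx <- rnorm(n, 0.2, 0.3)
    by <- rnorm(n, 0.3 * bx, 0.05)
    sey <- runif(n, 0.01, 0.2)
    expect_equal(mr_ivw(make_pairs(bx, by, sey), "fe")$beta,
                 ivw_oracle(bx, by, sey), tolerance = 1e-8)
  }
})

test_that("Egger recovers an exact line and matches the lm oracle", {
  pairs <- make_pairs(c(1, 2, 3), c(0.3, 0.5, 0.7), c(0.1, 0.1, 0.1))
  fit <- mr_egger(pairs)
  expect_equal(fit$estimate$beta, 0.2, tolerance = 1e-12)
  expect_equal(fit$pleiotropy$intercept, 0.1, tolerance = 1e-12)
  set.seed(202)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    bx <- rnorm(n, 0.2, 0.3)
    by <- rnorm(n, 0.05 + 0.3 * bx, 0.05)
    sey <- runif(n, 0.01, 0.2)
    fit <- mr_egger(make_pairs(bx, by, sey))
    ref <- egger_oracle(bx, by, sey)
    expect_equal(fit$pleiotropy$intercept, unname(ref[1]), tolerance = 1e-10)
    expect_equal(fit$estimate$beta, unname(ref[2]), tolerance = 1e-10)
  }
  expect_error(mr_egger(make_pairs(c(1, 2), c(1, 2), c(0.1, 0.1))),
               "at least 3")
  expect_error(mr_egger(make_pairs(c(1, 1, 1), c(1, 2, 3), rep(0.1, 3))),
               "degenerate")
})

test_that("constraining the Egger intercept to zero recovers the IVW slope", {
  set.seed(203)
  bx <- rnorm(10, 0.3, 0.1)
  by <- rnorm(10, 0.2 * bx, 0.05)
  sey <- runif(10, 0.02, 0.1)
  constrained <- stats::coef(stats::lm(by ~ bx - 1, weights = 1 / sey^2))
  expect_equal(mr_ivw(make_pairs(bx, by, sey), "fe")$beta,
               unname(constrained), tolerance = 1e-12)
})

test_that("the Egger intercept test holds its size under the no-pleiotropy null", {
  hits <- vapply(1:1000, function(i) {
    pairs <- simulate_harmonized_pairs(50, beta = 0.2, seed = 7000 + i)
    mr_egger(pairs)$pleiotropy$pval < 0.05
  }, logical(1))
  expect_gte(mean(!hits), 0.94)
})

test_that("the weighted median interpolates at cumulative weight one half", {
  pairs <- make_pairs(c(1, 1, 1), c(0.1, 0.2, 0.3), c(0.1, 0.1, 0.1))
  est <- mr_weighted_median(pairs, n_boot = 200, seed = 1)
  expect_equal(est$beta, 0.2, tolerance = 1e-12)
  # degenerate distribution: estimate exact, bootstrap se small
  pairs2 <- make_pairs(rep(1, 10), rep(0.4, 10), rep(0.01, 10),
                       sex = rep(0.001, 10))
  est2 <- mr_weighted_median(pairs2, n_boot = 200, seed = 1)
  expect_equal(est2$beta, 0.4, tolerance = 1e-12)
  expect_lt(est2$se, 0.02)
  # one heavy outlier with negligible weight cannot move the median
  bx <- c(rep(1, 49), 0.01)
  by <- c(rep(0.5, 49), 5 * 0.01)
  est3 <- mr_weighted_median(make_pairs(bx, by, rep(0.1, 50)),
                             n_boot = 200, seed = 1)
  expect_equal(est3$beta, 0.5, tolerance = 0.02)
  expect_error(mr_weighted_median(make_pairs(1, 1, 0.1), seed = 1),
               "at least 2")
  expect_error(mr_weighted_median(pairs, n_boot = 10), "seed")
})

test_that("the weighted median resists corruption of under half the weight", {
  set.seed(204)
  pairs <- simulate_harmonized_pairs(40, beta = 0.3, seed = 30)
  clean <- mr_weighted_median(pairs, n_boot = 300, seed = 2)
  corrupt <- pairs
  # displace 15 of 40 ratios (~37% of weight) far upward
  corrupt$beta_outcome[1:15] <- corrupt$beta_outcome[1:15] + 2
  shifted <- mr_weighted_median(corrupt, n_boot = 300, seed = 2)
  expect_lt(abs(shifted$beta - clean$beta), 4 * clean$se)
})

test_that("Cochran Q vanishes under proportionality and is minimized at IVW", {
  bx <- c(1, 2, 3, 4)
  pairs <- make_pairs(bx, 0.3 * bx, rep(0.1, 4))
  est <- mr_ivw(pairs, "fe")
  q <- mr_cochran_q(pairs, est)
  expect_equal(q$q_stat, 0, tolerance = 1e-20)
  expect_equal(q$pval, 1)
  expect_equal(q$df, 3)
  set.seed(205)
  pairs2 <- simulate_harmonized_pairs(15, beta = 0.2, seed = 55)
  q_ivw <- mr_cochran_q(pairs2, mr_ivw(pairs2, "fe"))$q_stat
  w <- 1 / pairs2$se_outcome^2
  grid <- seq(-1, 1.5, length.out = 2001)
  q_grid <- vapply(grid, function(b) {
    sum(w * (pairs2$beta_outcome - b * pairs2$beta_exposure)^2)
  }, numeric(1))
  expect_lte(q_ivw, min(q_grid) + 1e-10)
})

test_that("Cochran Q holds its nominal size under homogeneity", {
  hits <- vapply(1:1000, function(i) {
    pairs <- simulate_harmonized_pairs(20, beta = 0.2, seed = 9000 + i)
    mr_cochran_q(pairs, mr_ivw(pairs, "fe"))$pval < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.03)
  expect_lte(mean(hits), 0.07)
})

test_that("leave-one-out flags exactly a dominant implanted outlier", {
  pairs <- simulate_harmonized_pairs(20, beta = 0.3, seed = 77)
  loo <- mr_leave_one_out(pairs)
  expect_equal(nrow(loo), 20)
  expect_false(any(loo$flagged))
  # noise-free fixture: a +12 * SE displacement on one of 20 equal-strength
  # instruments shifts the pooled estimate by 12/sqrt(20) = 2.7 sigma
  spiked <- make_pairs(rep(0.2, 20), c(rep(0.06, 19), 0.06 + 12 * 0.05),
                       rep(0.05, 20))
  loo2 <- mr_leave_one_out(spiked)
  expect_true(loo2$flagged[loo2$omitted == "rs20"])
  expect_equal(sum(loo2$flagged), 1)
  three <- make_pairs(c(1, 2, 3), c(0.3, 0.6, 0.9), rep(0.1, 3))
  expect_equal(nrow(mr_leave_one_out(three)), 3)
})

test_that("MR-PRESSO detects an implanted outlier and is seed-deterministic", {
  pairs <- simulate_harmonized_pairs(30, beta = 0.3, seed = 99)
  spiked <- pairs
  spiked$beta_outcome[4] <- spiked$beta_outcome[4] + 10 * spiked$se_outcome[4]
  res <- mr_presso(spiked, n_simulations = 1000, seed = 5)
  expect_true("rs000004" %in% res$outliers)
  expect_lt(res$global_pval, 0.05)
  expect_false("rs000004" %in% res$retained$variant_id)
  res2 <- mr_presso(spiked, n_simulations = 1000, seed = 5)
  expect_identical(res[c("global_rss", "global_pval", "outlier_pvals",
                         "outliers", "distortion_pval")],
                   res2[c("global_rss", "global_pval", "outlier_pvals",
                          "outliers", "distortion_pval")])
  expect_error(mr_presso(make_pairs(c(1, 2, 3), c(1, 2, 3), rep(0.1, 3)),
                         seed = 1), "at least 4")
  expect_error(mr_presso(pairs), "seed")
})

test_that("clean data leave the MR-PRESSO global test calm", {
  res <- mr_presso(simulate_harmonized_pairs(30, beta = 0.3, seed = 123),
                   n_simulations = 1000, seed = 6)
  expect_gt(res$global_pval, 0.05)
})

test_that("estimates are equivariant under exposure rescaling and outcome negation", {
  pairs <- simulate_harmonized_pairs(25, beta = 0.25, seed = 321)
  for (s in c(0.5, 2)) {
    scaled <- pairs
    scaled$beta_exposure <- pairs$beta_exposure * s
    scaled$se_exposure <- pairs$se_exposure * s
    expect_equal(mr_ivw(scaled, "fe")$beta, mr_ivw(pairs, "fe")$beta / s,
                 tolerance = 1e-12)
    expect_equal(mr_egger(scaled)$estimate$beta,
                 mr_egger(pairs)$estimate$beta / s, tolerance = 1e-12)
    expect_equal(medmr:::weighted_median_point(scaled$beta_exposure,
                                               scaled$beta_outcome,
                                               scaled$se_outcome),
                 medmr:::weighted_median_point(pairs$beta_exposure,
                                               pairs$beta_outcome,
                                               pairs$se_outcome) / s,
                 tolerance = 1e-7)
  }
  negated <- pairs
  negated$beta_outcome <- -pairs$beta_outcome
  expect_equal(mr_ivw(negated, "fe")$beta, -mr_ivw(pairs, "fe")$beta,
               tolerance = 1e-12)
  expect_equal(mr_egger(negated)$estimate$beta, -mr_egger(pairs)$estimate$beta,
               tolerance = 1e-12)
})

test_that("IVW confidence intervals attain close to nominal coverage", {
  covered <- vapply(1:1000, function(i) {
    pairs <- simulate_harmonized_pairs(30, beta = 0.2, seed = 40000 + i)
    est <- mr_ivw(pairs)
    est$ci[1] <= 0.2 && 0.2 <= est$ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("the battery runner assembles the reporting schema", {
  pairs <- simulate_harmonized_pairs(12, beta = 0.3, seed = 11)
  res <- mr_all_methods(pairs, seed = 3)
  expect_setequal(res$estimates$method, c("ivw_re", "egger", "weighted_median"))
  expect_true(all(c("beta", "se", "pval", "or", "ci_low", "ci_high") %in%
                    names(res$estimates)))
  expect_true(all(res$estimates$ci_low < res$estimates$or))
  expect_true(all(res$estimates$or < res$estimates$ci_high))
  expect_equal(res$heterogeneity$df, 11)
  one <- mr_all_methods(pairs[1, ], seed = 3)
  expect_identical(one$estimates$method, "wald")
})
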