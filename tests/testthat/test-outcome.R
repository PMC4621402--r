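test_that("change score and improvement flag follow the sign conventions", {
  expect_equal(change_score(300, 300), 0)
  expect_equal(change_score(339, 236), 103)
  expect_equal(change_score(200, 260), -60)
  expect_error(change_score(700, 100), "invalid-argument")
  expect_error(change_score(100, -5), "invalid-argument")
  expect_true(improvement_flag(57))
  expect_false(improvement_flag(56.6))   # strict inequality at the threshold
  expect_false(improvement_flag(-100))
  expect_error(improvement_flag(10, threshold = -1), "invalid-argument")
})

test_that("G-test reproduces printed likelihood-ratio statistics", {
  expect_equal(g_test_2x2(20, 19, 9, 37)$statistic, 9.59, tolerance = 0.005)
  # zero observed cell contributes 0 by convention
  expect_equal(g_test_2x2(0, 39, 15, 31)$statistic, 21.13, tolerance = 0.005)
  # exact independence
  g0 <- g_test_2x2(10, 10, 10, 10)
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p, 1)
})

test_that("G-test agrees with the algebraic form and is symmetric", {
  set.seed(12)
  for (i in 1:100) {
    cells <- rmultinom(1, size = sample(20:200, 1), prob = runif(4, 0.05, 1))
    a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
    if (any(c(a + b, cc + d, a + cc, b + d) == 0)) next
    g <- g_test_2x2(a, b, cc, d)$statistic
    expect_equal(g, oracle_g_algebraic(a, b, cc, d), tolerance = 1e-9)
    # transposition and row/column swaps leave G unchanged
    expect_equal(g_test_2x2(a, cc, b, d)$statistic, g, tolerance = 1e-12)
    expect_equal(g_test_2x2(cc, d, a, b)$statistic, g, tolerance = 1e-12)
    expect_equal(g_test_2x2(b, a, d, cc)$statistic, g, tolerance = 1e-12)
  }
  expect_error(g_test_2x2(0, 0, 5, 5), "invalid-table")
  expect_error(g_test_2x2(3, 0, 5, 0), "invalid-table")
  expect_error(g_test_2x2(1.5, 2, 3, 4), "invalid-table")
})

test_that("the G-test battery reproduces the study's frequency analysis", {
  subj <- table5_subjects()
  res <- shape_frequency_tests(subj$shape, subj$disposition, subj$improved)
  expect_equal(nrow(res), 25)
  get <- function(st, sh) res$statistic[res$stratum == st & res$shape == sh]
  expect_equal(get("whole_sample", "v_shape"), 9.59, tolerance = 0.005)
  expect_equal(get("whole_sample", "monotonic_increase"), 3.19, tolerance = 0.005)
  expect_equal(get("whole_sample", "monotonic_decrease"), 21.13, tolerance = 0.005)
  expect_equal(get("integrated_functional", "monotonic_increase"), 4.63,
               tolerance = 0.005)
  expect_equal(get("integrated_dysfunctional", "v_shape"), 5.64,
               tolerance = 0.005)
  expect_equal(get("disintegrated_dysfunctional", "monotonic_increase"), 4.20,
               tolerance = 0.005)
  expect_equal(get("disintegrated_dysfunctional", "v_shape"), 8.89,
               tolerance = 0.005)
  expect_equal(get("disintegrated_dysfunctional", "discontinuous_other"),
               4.98, tolerance = 0.005)
  expect_equal(get("disintegrated_dysfunctional", "monotonic_decrease"), 8.64,
               tolerance = 0.005)
  # counts are conserved per stratum
  totals <- res$a + res$b + res$c + res$d
  sizes <- c(whole_sample = 85, integrated_functional = 22,
             integrated_dysfunctional = 21, disintegrated_functional = 10,
             disintegrated_dysfunctional = 32)
  expect_equal(unname(totals), unname(sizes[res$stratum]))
})

test_that("a stratum with an empty shape column is skipped, not mistested", {
  shape <- rep(c("v_shape", "plateau"), c(6, 6))
  disp <- rep("integrated_functional", 12)
  improved <- rep(c(TRUE, FALSE), 6)
  expect_message(
    res <- shape_frequency_tests(shape, disp, improved),
    "zero margin"
  )
  expect_true(all(res$skipped[res$shape == "monotonic_increase" &
                                res$stratum == "integrated_functional"]))
  expect_false(any(res$skipped[res$shape == "v_shape" &
                                 res$stratum == "whole_sample"]))
})

test_that("subgroup correlation matches hand arithmetic", {
  expect_equal(subgroup_correlation(1:10, 2 * (1:10) + 3)$r, 1)
  x <- c(1, 2, 3); y <- c(2, 1, 3)
  o <- sum((x - 2) * (y - 2)) / sqrt(sum((x - 2)^2) * sum((y - 2)^2))
  res <- subgroup_correlation(x, y)
  expect_equal(res$r, o, tolerance = 1e-12)
  expect_equal(res$n, 3)
  set.seed(5)
  res2 <- subgroup_correlation(rnorm(1000), rnorm(1000))
  expect_lt(abs(res2$r), 0.1)
  expect_error(subgroup_correlation(c(1, 1, 1), c(1, 2, 3)),
               "undefined-correlation")
  expect_error(subgroup_correlation(1:2, 2:3), "invalid-argument")
})

test_that("interaction model recovers a constructed interaction exactly", {
  rmse <- rep(c(0.5, 1.5, 2.5, 4), 10)
  is_if <- rep(c(0, 1), each = 20)
  change <- ifelse(is_if == 1, 40 - 18 * rmse, 10 + 30 * rmse)
  # a perfect fit makes lm's own summary complain; only coefficients matter
  fit <- suppressWarnings(fit_interaction_model(change, rmse, is_if))
  est <- coef(fit)
  expect_equal(unname(est["rmse"]), 30, tolerance = 1e-9)
  expect_equal(unname(est["rmse:is_if"]), -48, tolerance = 1e-9)
  expect_equal(unname(est["(Intercept)"]), 10, tolerance = 1e-9)
  expect_equal(unname(est["is_if"]), 30, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("interaction model matches a normal-equations oracle", {
  rmse <- c(1, 2, 3, 1.5, 2.5, 4)
  is_if <- c(0, 0, 0, 1, 1, 1)
  change <- c(35, 70, 88, 20, 15, 4)
  X <- cbind(1, rmse, is_if, rmse * is_if)
  beta <- solve(t(X) %*% X, t(X) %*% change)
  fit <- fit_interaction_model(change, rmse, is_if)
  expect_equal(unname(coef(fit)), as.numeric(beta), tolerance = 1e-9)
  # sequential R2 shares sum to the total R2
  expect_equal(sum(fit$explained), fit$r_squared, tolerance = 1e-9)
  expect_error(fit_interaction_model(change, rmse, rep(1, 6)),
               "invalid-argument")
})

test_that("two-way ANOVA matches a hand sums-of-squares oracle on a balanced design", {
  # balanced 2 shapes x 2 dispositions, n = 2 per cell; on a balanced design
  # Type III equals the classical factorial decomposition
  change <- c(10, 14, 30, 34, 20, 24, 16, 20)
  shape <- rep(c("v_shape", "plateau"), each = 4)
  is_if <- rep(c(0, 0, 1, 1), 2)
  # cell-means oracle
  gm <- mean(change)
  m_sh <- tapply(change, shape, mean)
  m_if <- tapply(change, is_if, mean)
  m_cell <- tapply(change, interaction(shape, is_if), mean)
  ss_sh <- 4 * sum((m_sh - gm)^2)
  ss_if <- 4 * sum((m_if - gm)^2)
  ss_cells <- 2 * sum((m_cell - gm)^2)
  ss_int <- ss_cells - ss_sh - ss_if
  ss_err <- sum((change - ave(change, interaction(shape, is_if)))^2)
  res <- suppressMessages(two_way_anova(change, shape, is_if))
  tab <- res$table
  f_of <- function(term) tab$F[tab$term == term]
  eta_of <- function(term) tab$partial_eta2[tab$term == term]
  df_err <- tab$df_error[1]
  expect_equal(f_of("shape"), (ss_sh / 1) / (ss_err / df_err),
               tolerance = 1e-9)
  expect_equal(f_of("disp2"), (ss_if / 1) / (ss_err / df_err),
               tolerance = 1e-9)
  expect_equal(f_of("shape:disp2"), (ss_int / 1) / (ss_err / df_err),
               tolerance = 1e-9)
  expect_equal(eta_of("shape"), ss_sh / (ss_sh + ss_err), tolerance = 1e-9)
  expect_equal(eta_of("shape:disp2"), ss_int / (ss_int + ss_err),
               tolerance = 1e-9)
})

test_that("two-way ANOVA behaves on null and unbalanced designs", {
  set.seed(21)
  # null design: all cell means equal, noise only
  n <- 300
  shape <- sample(shape_levels(), n, replace = TRUE)
  is_if <- sample(c(0, 1), n, replace = TRUE)
  change <- rnorm(n, 50, 10)
  res <- two_way_anova(change, shape, is_if)
  expect_true(all(res$table$partial_eta2 < 0.06))
  expect_true(all(res$table$partial_eta2 >= 0 & res$table$partial_eta2 <= 1))
  # cell summaries carry n, mean, sd
  expect_true(all(c("n", "mean", "sd") %in% names(res$cells)))
  expect_equal(sum(res$cells$n), n)
})
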