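test_that("exact linear data give the exact slope and zero heterogeneity", {
  bx <- c(0.1, 0.2, 0.3, 0.15, 0.25)
  instr <- make_instr(bx, by = 2 * bx, sy = rep(0.05, 5))
  fit <- fit_gls(instr)
  expect_equal(fit$slope, 2, tolerance = 1e-8)
  expect_equal(fit$q_statistic, 0, tolerance = 1e-6)
  expect_equal(fit$df, 4)
  # affine data with the Egger intercept
  instr2 <- make_instr(bx, by = 0.1 + 2 * bx, sy = rep(0.05, 5))
  fit2 <- fit_gls(instr2, with_intercept = TRUE)
  expect_equal(fit2$intercept, 0.1, tolerance = 1e-8)
  expect_equal(fit2$slope, 2, tolerance = 1e-8)
  expect_equal(fit2$q_statistic, 0, tolerance = 1e-6)
  expect_equal(fit2$df, 3)
})

test_that("GLS fits match a brute-force normal-equations oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 8
    R <- simulate_ld_matrix(n, 4, runif(1, 0.2, 0.8))
    bx <- runif(n, 0.05, 0.4)
    sy <- runif(n, 0.02, 0.1)
    by <- 0.4 * bx + drop(crossprod(chol(R), rnorm(n))) * sy
    instr <- make_instr(bx, by, sy, R)
    for (ic in c(FALSE, TRUE)) {
      fit <- fit_gls(instr, with_intercept = ic, ridge = 0)
      orc <- oracle_gls(bx, by, sy, R, intercept = ic)
      expect_equal(fit$slope, orc$slope, tolerance = 1e-10)
      expect_equal(fit$slope_se, orc$slope_se, tolerance = 1e-10)
      expect_equal(fit$q_statistic, orc$q, tolerance = 1e-10)
      if (ic) expect_equal(fit$intercept, orc$intercept, tolerance = 1e-10)
    }
  }
})

test_that("identity-LD GLS equals the textbook inverse-variance weighting", {
  set.seed(99)
  n <- 12
  bx <- runif(n, 0.05, 0.4)
  sy <- runif(n, 0.02, 0.1)
  by <- 0.25 * bx + rnorm(n, 0, sy)
  fit <- fit_gls(make_instr(bx, by, sy), ridge = 0)
  tb <- oracle_ivw_textbook(bx, by, sy)
  expect_equal(fit$slope, tb$slope, tolerance = 1e-10)
  expect_equal(fit$slope_se, tb$slope_se, tolerance = 1e-10)
})

test_that("leverage lies in [0,1], sums to the parameter count, and Q decomposes", {
  set.seed(7)
  n <- 15
  R <- simulate_ld_matrix(n, 5, 0.6)
  bx <- runif(n, 0.05, 0.4)
  sy <- runif(n, 0.02, 0.1)
  by <- 0.2 * bx + drop(crossprod(chol(R), rnorm(n))) * sy
  instr <- make_instr(bx, by, sy, R)
  for (ic in c(FALSE, TRUE)) {
    fit <- fit_gls(instr, with_intercept = ic)
    p <- if (ic) 2 else 1
    expect_true(all(fit$leverage >= 0 & fit$leverage <= 1))
    expect_equal(sum(fit$leverage), p, tolerance = 1e-6)
    expect_equal(sum(fit$outlier_stats), fit$q_statistic, tolerance = 1e-8)
  }
})

test_that("pruning removes planted outliers and leverage points, and only those", {
  bx <- rep(c(0.1, 0.2, 0.3), 5)
  sy <- rep(0.05, 15)
  instr <- make_instr(bx, by = 2 * bx, sy = sy)
  fit <- fit_gls(instr)
  clean <- prune_variants(instr, fit)
  expect_equal(nrow(clean$variants), 15)  # zero residuals, balanced design

  # one perturbed outcome beta with standardised squared residual near 25
  by2 <- 2 * bx
  by2[7] <- by2[7] + 5 * sy[7]
  instr2 <- make_instr(bx, by2, sy)
  fit2 <- fit_gls(instr2)
  expect_gt(fit2$outlier_stats[[7]], 10.83)
  pr2 <- prune_variants(instr2, fit2)
  expect_equal(attr(pr2, "excluded_outlier"), "v007")
  expect_false("v007" %in% pr2$variants$variant_id)

  # one exposure beta ten times the rest dominates the hat diagonal
  bx3 <- c(rep(0.1, 9), 1.0)
  instr3 <- make_instr(bx3, by = 2 * bx3, sy = rep(0.05, 10))
  fit3 <- fit_gls(instr3)
  expect_gt(fit3$leverage[[10]], 3 * mean(fit3$leverage))
  pr3 <- prune_variants(instr3, fit3)
  expect_equal(attr(pr3, "excluded_leverage"), "v010")
})

test_that("model selection follows the chi-square(1) cut on the Q difference", {
  f <- function(q) list(q_statistic = q)
  expect_equal(rucker_select(f(10), f(10)), "IVW")
  expect_equal(rucker_select(f(13), f(3)), "Egger")   # diff 10 > 3.841
  expect_equal(rucker_select(f(6), f(3)), "IVW")      # diff 3 < 3.841
  expect_error(rucker_select(f(3), f(6)), "inconsistency")
})

test_that("Q_IVW is never below Q_Egger on a shared instrument set", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(4:20, 1)
    R <- simulate_ld_matrix(n, sample(1:4, 1), runif(1, 0, 0.8))
    bx <- runif(n, 0.05, 0.4)
    sy <- runif(n, 0.02, 0.1)
    by <- rnorm(n, 0.3 * bx, 0.05)
    instr <- make_instr(bx, by, sy, R)
    q_ivw <- fit_gls(instr)$q_statistic
    q_egger <- fit_gls(instr, with_intercept = TRUE)$q_statistic
    expect_gte(q_ivw, q_egger - 1e-8)
  }
})

test_that("negating exposure betas negates the slope and nothing else", {
  set.seed(21)
  n <- 20
  R <- simulate_ld_matrix(n, 5, 0.5)
  bx <- runif(n, 0.05, 0.4)
  sy <- runif(n, 0.02, 0.1)
  by <- 0.3 * bx + drop(crossprod(chol(R), rnorm(n))) * sy
  a <- fit_gls(make_instr(bx, by, sy, R))
  b <- fit_gls(make_instr(-bx, by, sy, R))
  expect_equal(b$slope, -a$slope)
  expect_equal(b$slope_se, a$slope_se)
  expect_equal(b$q_statistic, a$q_statistic)
  expect_equal(b$leverage, a$leverage)
  expect_equal(b$outlier_stats, a$outlier_stats)
})

test_that("analyses with fewer than the minimum variants are discarded", {
  d <- simulate_mr_dataset(sim_config(n_variants = 5, seed = 2))
  res <- run_mr(d$exposure, d$outcome, d$ld, outcome_type = "binary")
  expect_equal(res$result$status, "discarded")
  expect_equal(res$result$estimator, "discarded")
  expect_true(is.na(res$result$estimate))

  d2 <- simulate_mr_dataset(sim_config(n_variants = 30, seed = 2))
  res2 <- run_mr(d2$exposure, d2$outcome, d2$ld, outcome_type = "binary",
                 config = mr_config(min_variants = 40))
  expect_equal(res2$result$status, "discarded")
})

test_that("null simulations rarely stray beyond 2.5 standard errors", {
  inside <- vapply(1:100, function(s) {
    d <- simulate_mr_dataset(sim_config(n_variants = 50, causal_effect = 0,
                                        seed = 700 + s))
    r <- run_mr(d$exposure, d$outcome, d$ld, outcome_type = "binary")
    abs(r$ivw$slope) < 2.5 * r$ivw$slope_se
  }, logical(1))
  expect_gte(mean(inside), 0.95)
})

test_that("effects are reported as OR or mean difference with 1.96 intervals", {
  null <- to_reported_effect(0, 0.1, "binary")
  expect_equal(null$estimate, 1)
  expect_lt(null$ci_lower, 1)
  expect_gt(null$ci_upper, 1)
  cont <- to_reported_effect(-0.5, 0.2, "continuous")
  expect_equal(cont$estimate, -0.5)
  expect_equal(cont$ci_lower, -0.5 - 1.96 * 0.2)
  expect_equal(cont$effect_scale, "mean difference")
  expect_error(to_reported_effect(0.1, 0, "binary"), "slope_se")
})
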