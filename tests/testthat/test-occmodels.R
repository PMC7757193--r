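test_that("Laplace fit reduces to plain logistic regression without random variation", {
  set.seed(11)
  n <- 1500
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * x1 - 0.5 * x2))
  d <- data.frame(outcome = y, patch_id = sprintf("q%04d", 1:n),
                  year = 2000L + seq_len(n), x1 = x1, x2 = x2)
  fit <- fit_occupancy_glmm(d, c("x1", "x2"))
  X <- cbind("(Intercept)" = 1, x1 = x1, x2 = x2)
  b_newton <- newton_logistic(X, y)
  expect_lt(max(abs(fit$beta - b_newton)), 1e-4)
  expect_equal(fit$sigma2_patch, 0, tolerance = 1e-6)
  expect_equal(fit$sigma2_year, 0, tolerance = 1e-6)
  # likelihood sanity: the mixed deviance with variances forced to zero
  # equals the plain logistic deviance at the oracle coefficients
  d$patch_f <- factor(d$patch_id); d$year_f <- factor(d$year)
  devf <- lme4::glmer(outcome ~ x1 + x2 + (1 | patch_f) + (1 | year_f),
                      data = d, family = binomial(), devFunOnly = TRUE)
  expect_equal(devf(c(0, 0, b_newton)),
               -2 * logistic_loglik(X, y, b_newton), tolerance = 1e-8)
  # AIC identity: two variance components enter the parameter count
  expect_equal(fit$aic, -2 * fit$loglik + 2 * (length(fit$beta) + 2))
})

test_that("an intercept-only fit on a balanced response sits at logit 0.5", {
  d <- data.frame(outcome = rep(0:1, 60),
                  patch_id = sprintf("p%03d", rep(1:60, each = 2)),
                  year = rep(2000:2003, 30))
  fit <- fit_occupancy_glmm(d, character(0))
  expect_lt(abs(fit$beta[["(Intercept)"]]), 1e-2)
})

test_that("known GLMM parameters are recovered within sampling error", {
  beta <- c("(Intercept)" = -2, x1 = 0.8, x2 = -0.5)
  d <- simulate_glmm_data(150, 20, beta, s2_patch = 0.3, s2_year = 0.3,
                          seed = 21)
  fit <- fit_occupancy_glmm(d, c("x1", "x2"))
  se <- sqrt(diag(fit$vcov))
  for (nm in names(beta))
    expect_lt(abs(fit$beta[[nm]] - beta[[nm]]), 3 * se[[nm]])
  expect_gt(fit$sigma2_patch, 0.05)
  expect_lt(fit$sigma2_patch, 1)
  r2 <- r2_nakagawa(fit)
  expect_lte(r2$r2_marginal, r2$r2_conditional)
  expect_gte(r2$r2_marginal, 0)
  expect_lte(r2$r2_conditional, 1)
})

test_that("weather model selection enumerates every month subset", {
  beta <- c("(Intercept)" = -1, x1 = 0.5)
  d <- simulate_glmm_data(40, 8, beta, seed = 31)
  set.seed(32)
  for (m in c("logp_may", "logp_june", "logp_july", "logp_august"))
    d[[m]] <- rnorm(nrow(d))
  sel <- suppressWarnings(select_weather_model(d, "x1"))
  expect_equal(nrow(sel$table), 16L)
  expect_equal(sort(sel$table$npar), sort(2 + 2 + c(0, 1, 1, 1, 1, 2, 2, 2,
                                                    2, 2, 2, 3, 3, 3, 3, 4)))
  expect_equal(sel$table$rank, 1:16)
  sel0 <- select_weather_model(d, "x1", months = character(0))
  expect_equal(nrow(sel0$table), 1L)
  expect_identical(sel0$best$terms, "x1")
})

test_that("the true precipitation month wins the AIC ranking", {
  wins <- 0L
  for (seed in 1:4) {
    beta <- c("(Intercept)" = -1.2, x1 = 0.4, logp_may = 0.5)
    d <- simulate_glmm_data(75, 20, beta, s2_year = 0.05, seed = 100 + seed,
                            year_level = "logp_may")
    set.seed(200 + seed)
    yv <- rnorm(20)
    d$logp_june <- yv[match(d$year, sort(unique(d$year)))]
    sel <- suppressWarnings(
      select_weather_model(d, "x1", months = c("may", "june")))
    if ("logp_may" %in% sel$best$terms) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})

test_that("r2 decomposition follows the closed form", {
  # sigma2_f = 1 by construction: unit-variance covariate with slope 1
  x <- as.numeric(scale(1:100))
  X <- cbind("(Intercept)" = 1, x = x)
  fit <- fake_fit(c("(Intercept)" = 0, x = 1), X,
                  sigma2_patch = 0.5, sigma2_year = 0.5)
  r2 <- r2_nakagawa(fit)
  denom <- 1 + 0.5 + 0.5 + pi^2 / 3
  expect_equal(r2$r2_marginal, 1 / denom)
  expect_equal(r2$r2_conditional, 2 / denom)
  # no random variance: marginal equals conditional
  fit0 <- fake_fit(c("(Intercept)" = 0, x = 1), X)
  r20 <- r2_nakagawa(fit0)
  expect_equal(r20$r2_marginal, r20$r2_conditional)
  # degenerate design warns and reports 0
  fitc <- fake_fit(c("(Intercept)" = 1), X[, 1, drop = FALSE])
  expect_warning(r2c <- r2_nakagawa(fitc), "zero variance")
  expect_equal(r2c$r2_marginal, 0)
})

test_that("variance shares follow beta_j^2 var(x_j)", {
  set.seed(5)
  x1 <- as.numeric(scale(rnorm(200)))
  x2 <- as.numeric(scale(residuals(lm(rnorm(200) ~ x1))))
  X <- cbind("(Intercept)" = 1, x1 = x1, x2 = x2)
  fit <- fake_fit(c("(Intercept)" = 0, x1 = 1, x2 = 2), X)
  sh <- fixed_effect_variance_share(fit)
  expect_equal(unname(sh), c(20, 80), tolerance = 1e-8)
  fit1 <- fake_fit(c("(Intercept)" = 0, x1 = 1.7), X[, 1:2])
  expect_equal(unname(fixed_effect_variance_share(fit1)), 100)
  fit0 <- fake_fit(c("(Intercept)" = 0, x1 = 0, x2 = 0), X)
  expect_error(fixed_effect_variance_share(fit0), "undefined")
})

test_that("a single-level state factor collapses to the base model", {
  d <- simulate_glmm_data(50, 8, c("(Intercept)" = -0.5, x1 = 0.5), seed = 41)
  d$state_prev <- "M"
  base <- fit_occupancy_glmm(d, "x1")
  expect_warning(st <- fit_state_model(d, "x1"), "one patch state")
  expect_equal(st$loglik, base$loglik, tolerance = 1e-8)
  expect_equal(st$state_levels, "M")
})

test_that("a known patch-state contrast is recovered", {
  d <- simulate_glmm_data(150, 20, c("(Intercept)" = -2.5, x1 = 0.5),
                          s2_patch = 0.2, s2_year = 0.2, seed = 51,
                          state_effect = c("0" = 0, "P" = 0.5))
  st <- fit_state_model(d, "x1")
  expect_equal(st$state_levels, c("0", "P"))
  est <- st$beta[["state_prevP"]]
  se <- sqrt(st$vcov["state_prevP", "state_prevP"])
  expect_lt(abs(est - 0.5), 3 * se)
  scr <- state_effect_screen(d, "x1")
  expect_equal(scr$base$n, scr$state$n)
  expect_equal(scr$delta_aic, scr$state$aic - scr$base$aic)
})

test_that("eligible previous states are restricted by the response", {
  pa <- generate_landscape(80, years = 2000:2005, extent_km = c(15, 20),
                           seed = 61)
  pr <- generate_covariates(2000:2005, seed = 62)
  h <- generate_history(pa, pr, default_truth_params(), years = 2000:2005,
                        seed = 63, init_occ = c(M = 0.4, C = 0.4, P = 0.3))
  tab_c <- build_transition_table(h, pa, pr, "M", "colonization")
  expect_true(all(tab_c$state_prev %in% c("0", "P")))
  tab_e <- build_transition_table(h, pa, pr, "M", "extinction")
  expect_true(all(tab_e$state_prev %in% c("M", "MC", "MCP", "MP")))
  tab_pc <- build_transition_table(h, pa, pr, "P", "colonization")
  expect_true(all(tab_pc$state_prev %in% c("0", "M", "MC")))
  # parasitoid extinction rows require host persistence
  tab_ce <- build_transition_table(h, pa, pr, "C", "extinction")
  expect_true(all(tab_ce$state_prev %in% c("MC", "MCP")))
})

test_that("state rate tables inverse-logit the linear predictor at covariate means", {
  X <- cbind("(Intercept)" = rep(1, 10), state_prevP = rep(0:1, 5))
  V <- diag(c(0.04, 0.09))
  dimnames(V) <- list(colnames(X), colnames(X))
  fit <- fake_fit(c("(Intercept)" = 0, state_prevP = -4.6), X, vcov = V,
                  state_levels = c("0", "P"))
  tab <- state_rates(fit)
  expect_equal(tab$rate_pct[tab$state == "0"], 50)
  expect_equal(tab$rate_pct[tab$state == "P"], 100 * plogis(-4.6),
               tolerance = 1e-12)
  expect_equal(100 * plogis(-4.6), 1.0, tolerance = 0.01)
  expect_true(all(tab$lo95 < tab$rate_pct & tab$rate_pct < tab$hi95))
})

test_that("delta AIC is a plain difference with a row-count guard", {
  X <- cbind("(Intercept)" = rep(1, 50))
  f1 <- fake_fit(c("(Intercept)" = 0), X, loglik = -100, aic = 210, n = 50)
  f2 <- fake_fit(c("(Intercept)" = 0), X, loglik = -95, aic = 204, n = 50)
  expect_equal(delta_aic(f1, f1), 0)
  expect_equal(delta_aic(f2, f1), -6)
  expect_equal(-2 * (-100) + 2 * 5, 210)  # AIC arithmetic behind f1
  f3 <- fake_fit(c("(Intercept)" = 0), X, loglik = -95, aic = 204, n = 49)
  expect_error(delta_aic(f3, f1), "different row counts")
})

test_that("separation triggers the ridge fallback with finite estimates", {
  d <- data.frame(outcome = rep(c(0, 1), each = 30),
                  patch_id = sprintf("p%03d", 1:60),
                  year = rep(2000:2005, 10),
                  x1 = rep(c(-1, 1), each = 30))
  expect_warning(fit <- fit_occupancy_glmm(d, "x1"), "separation")
  expect_true(all(is.finite(fit$beta)))
  expect_true(fit$separated)
})

test_that("a constant response yields the half-count-corrected fallback", {
  d <- data.frame(outcome = rep(0L, 40), patch_id = sprintf("p%03d", 1:40),
                  year = rep(2000:2003, 10), x1 = rnorm(40))
  expect_warning(fit <- fit_occupancy_glmm(d, "x1"), "constant")
  expect_equal(plogis(fit$beta[["(Intercept)"]]), 0.5 / 41, tolerance = 1e-12)
  expect_equal(fit$beta[["x1"]], 0)
})
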