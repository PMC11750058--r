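# The two-site toy (A: x=(1,2), y=(1,3); B: x=(3,5), y=(10,14)) has
# pooled slope 24/7 but within slope exactly 2, so it separates the
# designs that absorb site-level confounding from the ones that do not.

test_that("naive, within, dummy and group-mean designs agree with hand algebra on the toy", {
  pd <- toy_panel()
  expect_equal(beta1(fit_naive(pd))$estimate, 24 / 7, tolerance = 1e-12)

  fw <- fit_fe_within(pd)
  expect_equal(beta1(fw)$estimate, 2, tolerance = 1e-12)

  fd <- fit_fe_dummy(pd)
  expect_equal(beta1(fd)$estimate, 2, tolerance = 1e-12)
  # unit intercepts recover unit means net of the slope
  co <- fd$coefficients
  expect_equal(co$estimate[co$term == "unit::A"], 2 - 2 * 1.5, tolerance = 1e-10)
  expect_equal(co$estimate[co$term == "unit::B"], 12 - 2 * 4, tolerance = 1e-10)
  # within and dummy share the standard error
  expect_equal(beta1(fw)$se, beta1(fd)$se, tolerance = 1e-10)

  expect_equal(beta1(fit_group_mean_covariate(pd))$estimate, 2, tolerance = 1e-12)
  expect_equal(beta1(fit_group_mean_centered(pd))$estimate, 2, tolerance = 1e-12)
})

test_that("outcome = exposure + unit constant is recovered exactly by fixed effects", {
  df <- data.frame(unit = rep(c("A", "B"), each = 5), time = rep(1:5, 2),
                   x = c(1, 4, 2, 8, 5, 3, 1, 7, 2, 9))
  df$y <- df$x + ifelse(df$unit == "A", 100, -50)
  pd <- panel_data(df)
  fit <- fit_fe_within(pd)
  expect_equal(beta1(fit)$estimate, 1, tolerance = 1e-10)
  expect_equal(fit$sigma2, 0, tolerance = 1e-16)
})

test_that("all within-type designs return identical slopes on balanced panels", {
  for (seed in 1:5) {
    sim <- simulate_panel(dgp_config(seed = seed))
    ests <- c(
      beta1(fit_fe_within(sim$panel))$estimate,
      beta1(fit_fe_dummy(sim$panel))$estimate,
      beta1(fit_group_mean_covariate(sim$panel))$estimate,
      beta1(fit_group_mean_centered(sim$panel))$estimate,
      beta1(fit_group_mean_covariate(sim$panel, include_random_effect = TRUE))$estimate,
      beta1(fit_group_mean_centered(sim$panel, include_random_effect = TRUE))$estimate)
    expect_lt(max(ests) - min(ests), 1e-6)
  }
})

test_that("centering reparameterisation: between slope = within slope + contextual slope", {
  for (seed in c(2, 13)) {
    sim <- simulate_panel(dgp_config(seed = seed, n_sites = 6, n_years = 4))
    mu <- fit_group_mean_covariate(sim$panel)
    ce <- fit_group_mean_centered(sim$panel)
    b1 <- beta1(mu)$estimate
    b2_mundlak <- mu$coefficients$estimate[mu$coefficients$term == "unit_mean_x"]
    b2_centered <- ce$coefficients$estimate[ce$coefficients$term == "unit_mean_x"]
    expect_equal(b2_centered, b1 + b2_mundlak, tolerance = 1e-8)
  }
})

test_that("OLS designs match the lm oracle on random small panels", {
  set.seed(301)
  for (i in 1:50) {
    pd <- random_panel()
    d <- as.data.frame(pd)
    d$xbar <- ave(d$x, d$unit)

    expect_equal(beta1(fit_naive(pd))$estimate,
                 unname(coef(lm(y ~ x, d))["x"]), tolerance = 1e-8)
    expect_equal(beta1(fit_fe_dummy(pd))$estimate,
                 unname(coef(lm(y ~ x + factor(unit), d))["x"]), tolerance = 1e-8)
    expect_equal(beta1(fit_group_mean_covariate(pd))$estimate,
                 unname(coef(lm(y ~ x + xbar, d))["x"]), tolerance = 1e-8)
  }
})

test_that("random-intercept REML matches the reference mixed-model fit", {
  skip_if_not_installed("lme4")
  set.seed(302)
  for (i in 1:20) {
    sim <- simulate_panel(dgp_config(seed = 1000 + i, n_sites = 8, n_years = 6))
    d <- as.data.frame(sim$panel)
    ref <- lme4::lmer(y ~ x + (1 | unit), d, REML = TRUE)
    ours <- fit_random_intercept(sim$panel)
    b_ref <- unname(lme4::fixef(ref)["x"])
    expect_equal(beta1(ours)$estimate, b_ref, tolerance = 1e-4)
    expect_equal(beta1(ours)$se, unname(sqrt(vcov(ref)["x", "x"])),
                 tolerance = 1e-4)
  }
})

test_that("REML hits the zero-variance boundary and collapses to pooled OLS", {
  set.seed(303)
  df <- data.frame(unit = rep(sprintf("U%d", 1:6), each = 10),
                   time = rep(1:10, 6), x = rnorm(60))
  e <- rnorm(60)
  e <- e - ave(e, df$unit)              # residual site means exactly zero
  df$y <- 2 * df$x + e
  pd <- panel_data(df)
  re <- fit_random_intercept(pd)
  ols <- fit_naive(pd)
  expect_lt(re$sigma2_site, 1e-6)
  expect_equal(beta1(re)$estimate, beta1(ols)$estimate, tolerance = 1e-5)
})

test_that("the random-effects slope lies between the within and between slopes", {
  for (seed in 1:10) {
    sim <- simulate_panel(dgp_config(seed = seed))
    d <- as.data.frame(sim$panel)
    within <- beta1(fit_fe_within(sim$panel))$estimate
    means <- aggregate(cbind(y, x) ~ unit, d, mean)
    between <- unname(coef(lm(y ~ x, means))["x"])
    re <- beta1(fit_random_intercept(sim$panel))$estimate
    expect_gte(re, min(within, between) - 1e-8)
    expect_lte(re, max(within, between) + 1e-8)
  }
})

test_that("first differences recover the slope and per-site trends by construction", {
  set.seed(304)
  df <- data.frame(unit = rep(c("A", "B", "C"), each = 6),
                   time = rep(1:6, 3), x = rnorm(18))
  df$y <- df$x + 5 * df$time + ifelse(df$unit == "A", 10, -3)
  pd <- panel_data(df)
  fit <- fit_first_difference(pd)
  expect_equal(beta1(fit)$estimate, 1, tolerance = 1e-10)
  lam <- fit$coefficients
  expect_equal(lam$estimate[startsWith(lam$term, "unit::")], rep(5, 3),
               tolerance = 1e-10)
})

test_that("second differences annihilate site-specific linear trends exactly", {
  set.seed(305)
  df <- data.frame(unit = rep(c("A", "B", "C"), each = 6),
                   time = rep(1:6, 3), x = rnorm(18))
  trend <- c(A = 2, B = -1, C = 0.5)
  df$y <- df$x + trend[df$unit] * df$time + ifelse(df$unit == "A", 7, 0)
  pd <- panel_data(df)
  expect_equal(beta1(fit_second_difference(pd))$estimate, 1, tolerance = 1e-10)

  # constant exposure after double differencing is unidentifiable
  ldf <- data.frame(unit = rep(c("A", "B"), each = 4),
                    time = rep(1:4, 2), x = rep(1:4, 2) * 2, y = rnorm(8))
  lin <- panel_data(ldf)
  expect_error(fit_second_difference(lin), class = "panelcausal_estimation_error")
})

test_that("two-way fixed effects absorb plot and site-year confounding exactly", {
  cfg <- dgp_config(seed = 21, variant = "spatiotemporal", n_plots = 3,
                    noise_sd = 0)
  sim <- simulate_panel(cfg)
  fit <- suppressMessages(fit_twoway_fe(sim$panel))
  expect_equal(beta1(fit)$estimate, 1, tolerance = 1e-8)

  # one plot per site: the site-by-year effects saturate
  one <- dgp_config(seed = 22, variant = "spatiotemporal", n_plots = 1)
  sim1 <- simulate_panel(one)
  expect_error(fit_twoway_fe(sim1$panel), class = "panelcausal_estimation_error")
  expect_error(fit_twoway_mundlak(sim1$panel), class = "panelcausal_estimation_error")
})

test_that("two-way Mundlak matches two-way fixed effects on balanced panels", {
  skip_if_not_installed("lme4")
  cfg <- dgp_config(seed = 23, variant = "spatiotemporal", n_plots = 4)
  sim <- simulate_panel(cfg)
  fe <- suppressMessages(fit_twoway_fe(sim$panel))
  mu <- fit_twoway_mundlak(sim$panel)
  # equality is exact only in the infinite-variance-ratio limit; at the
  # REML estimates the two should agree within the estimate's own SE
  expect_lt(abs(beta1(mu)$estimate - beta1(fe)$estimate), beta1(fe)$se)

  # and the REML solution matches the reference mixed-model fit
  d <- as.data.frame(sim$panel)
  d$plot_id <- paste(d$unit, d$subunit)
  d$st <- paste(d$unit, d$time)
  d$pm <- ave(d$x, d$plot_id)
  d$stm <- ave(d$x, d$st)
  ref <- lme4::lmer(y ~ x + pm + stm + (1 | plot_id) + (1 | st), d, REML = TRUE)
  expect_equal(beta1(mu)$estimate, unname(lme4::fixef(ref)["x"]),
               tolerance = 1e-4)
})

test_that("with no site-year pulses the two-way contextual effect is null", {
  cfg <- dgp_config(seed = 24, variant = "spatiotemporal", n_plots = 4,
                    pulse_recruit_slope = 0, pulse_temp_slope = 0)
  ests <- sapply(1:20, function(r) {
    sim <- simulate_panel(cfg, replicate = r)
    mu <- fit_twoway_mundlak(sim$panel)
    mu$coefficients$estimate[mu$coefficients$term == "unit_time_mean_x"]
  })
  expect_lt(abs(mean(ests)), 3 * sd(ests) / sqrt(length(ests)))
})

test_that("design_spec dispatch covers the menu and rejects unknown designs", {
  sim <- simulate_panel(dgp_config(seed = 31))
  expect_equal(beta1(fit_design(sim$panel, design_spec("fe_within")))$estimate,
               beta1(fit_fe_within(sim$panel))$estimate)
  expect_error(design_spec("banana"), class = "panelcausal_config_error")
})

test_that("cluster-robust standard errors are available per design", {
  sim <- simulate_panel(dgp_config(seed = 32))
  a <- fit_naive(sim$panel, se_type = "model")
  b <- fit_naive(sim$panel, se_type = "cluster_robust")
  expect_equal(beta1(a)$estimate, beta1(b)$estimate)
  expect_false(isTRUE(all.equal(beta1(a)$se, beta1(b)$se)))
  expect_equal(b$se_type, "cluster_robust")
})
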