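test_that("read_panel parses a small CSV and standardises roles", {
  p <- write_panel_csv(data.frame(site = c("A", "A", "B", "B"),
                                  year = c(1, 2, 1, 2),
                                  snails = c(1, 3, 10, 14),
                                  temp = c(1, 2, 3, 5)))
  pd <- read_panel(p, unit = "site", time = "year",
                   outcome = "snails", exposure = "temp")
  expect_s3_class(pd, "panel_data")
  expect_equal(nrow(pd), 4)
  expect_equal(sort(unique(pd$unit)), c("A", "B"))
  expect_type(pd$time, "integer")
  expect_equal(attr(pd, "roles")$outcome, "snails")
})

test_that("rows with blank or non-numeric outcome are dropped and logged", {
  p <- write_panel_csv(data.frame(site = c("A", "A", "B", "B"),
                                  year = c(1, 2, 1, 2),
                                  snails = c(1, NA, "oops", 14),
                                  temp = c(1, 2, 3, 5)))
  expect_message(
    pd <- read_panel(p, unit = "site", time = "year",
                     outcome = "snails", exposure = "temp"),
    "dropped 2 row")
  expect_equal(nrow(pd), 2)
})

test_that("missing mandatory columns and duplicate keys are rejected by name", {
  p <- write_panel_csv(data.frame(site = c("A", "A", "B"), year = c(1, 2, 1),
                                  snails = 1:3, temp = 1:3))
  expect_error(read_panel(p, unit = "site", time = "yr",
                          outcome = "snails", exposure = "temp"),
               "'yr'", class = "panelcausal_config_error")

  dup <- write_panel_csv(data.frame(site = c("A", "A", "B"), year = c(1, 1, 2),
                                    snails = 1:3, temp = 1:3))
  expect_error(read_panel(dup, unit = "site", time = "year",
                          outcome = "snails", exposure = "temp"),
               "unit 'A', time 1", class = "panelcausal_validation_error")
})

test_that("panels with fewer than two units are rejected", {
  expect_error(panel_data(data.frame(unit = "A", time = 1:3, y = 1:3, x = 1:3)),
               "2 distinct units", class = "panelcausal_validation_error")
})

test_that("write_panel round-trips through read_panel", {
  sim <- simulate_panel(dgp_config(seed = 4, n_sites = 3, n_years = 4))
  f <- tempfile(fileext = ".csv")
  write_panel(sim$panel, f)
  back <- read_panel(f, unit = "site", time = "year",
                     outcome = "snails", exposure = "temp")
  expect_equal(back$y, sim$panel$y)
  expect_equal(back$x, sim$panel$x)
  expect_equal(back$unit, sim$panel$unit)
})

test_that("group means average observed rows, balanced or not", {
  pd <- panel_data(data.frame(unit = c("A", "A", "B", "B", "B"),
                              time = c(1, 2, 1, 2, 3),
                              y = c(1, 3, 2, 2, 2),
                              x = c(1, 2, 1, 2, 6)))
  g <- add_group_means(pd, "unit")
  expect_equal(g$unit_mean_x, c(1.5, 1.5, 3, 3, 3))
  expect_equal(g$unit_mean_y, c(2, 2, 2, 2, 2))

  # constant exposure: every mean equals the constant, anomalies vanish
  const <- panel_data(data.frame(unit = rep(c("A", "B"), each = 3),
                                 time = rep(1:3, 2), y = rnorm(6), x = 7))
  gc <- add_group_means(const, "unit")
  expect_true(all(gc$unit_mean_x == 7))
  expect_true(all(gc$x - gc$unit_mean_x == 0))
})

test_that("group-mean augmentation is idempotent", {
  sim <- simulate_panel(dgp_config(seed = 11, n_sites = 3, n_years = 5))
  once <- add_group_means(sim$panel, "unit")
  twice <- add_group_means(once, "unit")
  expect_identical(as.data.frame(once), as.data.frame(twice))
})

test_that("within centering zeroes per-unit sums and kills unit constants", {
  pd <- toy_panel()
  w <- within_center(pd)
  expect_equal(w$x[w$unit == "A"], c(-0.5, 0.5))
  expect_equal(w$y[w$unit == "A"], c(-1, 1))
  for (u in unique(w$unit)) {
    expect_lt(abs(sum(w$x[w$unit == u])), 1e-10 * sum(w$unit == u))
    expect_lt(abs(sum(w$y[w$unit == u])), 1e-10 * sum(w$unit == u))
  }

  # any column constant within units maps to all zeros
  pd2 <- panel_data(data.frame(unit = rep(c("A", "B"), each = 4),
                               time = rep(1:4, 2),
                               y = rep(c(3, -2), each = 4),
                               x = rnorm(8)))
  w2 <- within_center(pd2)
  expect_equal(w2$y, rep(0, 8))

  # a unit observed once transforms to exactly zero
  pd3 <- panel_data(data.frame(unit = c("A", "B", "B"), time = c(1, 1, 2),
                               y = c(5, 1, 2), x = c(9, 1, 3)))
  w3 <- within_center(pd3)
  expect_equal(w3$y[w3$unit == "A"], 0)
  expect_equal(w3$x[w3$unit == "A"], 0)
})

test_that("differencing emits rows only for consecutive times", {
  pd <- panel_data(data.frame(unit = rep(c("A", "B"), each = 3),
                              time = c(1, 2, 3, 1, 2, 3),
                              y = c(10, 12, 15, 1, 1, 1),
                              x = c(1, 2, 4, 1, 2, 3)))
  d1 <- difference(pd, 1)
  expect_equal(d1$y[d1$unit == "A"], c(2, 3))
  expect_equal(d1$y[d1$unit == "B"], c(0, 0))  # constant outcome -> zero diffs
  d2 <- difference(pd, 2)
  expect_equal(d2$y[d2$unit == "A"], 1)

  # gapped unit contributes no rows; the gap is logged
  gap <- panel_data(data.frame(unit = rep(c("A", "B"), each = 2),
                               time = c(1, 3, 1, 2),
                               y = 1:4, x = 1:4))
  expect_message(dg <- difference(gap, 1), "skipped")
  expect_equal(unique(dg$unit), "B")
  expect_equal(nrow(dg), 1)
  # no unit has three consecutive years: second differencing is impossible
  expect_error(suppressMessages(difference(gap, 2)),
               "order 2", class = "panelcausal_estimation_error")
})

test_that("second differencing equals differencing twice on gap-free panels", {
  sim <- simulate_panel(dgp_config(seed = 5, n_sites = 4, n_years = 6))
  d2 <- difference(sim$panel, 2)
  d11 <- difference(difference(sim$panel, 1), 1)
  expect_equal(d2$y, d11$y)
  expect_equal(d2$x, d11$x)
  expect_equal(d2$time, d11$time)
})
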