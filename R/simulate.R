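#' Configuration of the confounded snail-panel generator
#'
#' Bundles every parameter of the data-generating process in which a
#' latent site-level oceanographic driver \eqn{O_i} raises site mean
#' temperature while lowering site recruitment, so that temperature and
#' recruitment are confounded across sites:
#' \deqn{O_i \sim N(0, \sigma_O^2)}
#' \deqn{R_i = a_R O_i + \mu_R, \qquad T_i = a_T O_i + \mu_T}
#' \deqn{T_{ij} \sim N(T_i, \sigma_T^2), \qquad
#'       S_{ij} \sim N(\beta_1 T_{ij} + \gamma R_i, \sigma_\epsilon^2)}
#' The returned panel uses temperature \eqn{T_{ij}} as the exposure and
#' snail abundance \eqn{S_{ij}} as the outcome; recruitment is latent
#' (recorded only in the truth record), which is what makes the system a
#' testbed for omitted-variable bias.
#'
#' Variants:
#' * `"snail"`: the confounded system above;
#' * `"no_confounding"`: recruitment slope forced to 0, so the exposure
#'   is exogenous and every design should be unbiased;
#' * `"site_trend"`: adds a site-specific linear time trend
#'   \eqn{\lambda_i t} (\eqn{\lambda_i \sim N(0, \sigma_\lambda^2)}) to
#'   the outcome via a development-like confounder and (by default) the
#'   same trend to the exposure, the scenario that first differencing is
#'   built to remove;
#' * `"spatiotemporal"`: `n_plots` plots per site; site-by-year pulses
#'   \eqn{P_{ij} \sim N(0, \sigma_P^2)} enter both recruitment and
#'   temperature (cold-water pulses bring unusually high recruitment),
#'   plus a time-invariant plot-level intercept; this is the scenario
#'   for the two-way (plot + site-by-year) designs.
#'
#' @param n_sites number of sites (units). Default 10.
#' @param n_years number of years (times) per site. Default 10.
#' @param oce_sd SD of the latent oceanography variable. Default 1.
#' @param recruit_slope coefficient of oceanography in site recruitment.
#'   Default -2.
#' @param recruit_mean mean recruitment (individuals per plot). Default 10.
#' @param temp_slope coefficient of oceanography in site mean temperature.
#'   Default 2.
#' @param temp_mean mean site temperature, degrees C. Default 15.
#' @param temp_within_sd SD of yearly temperature around the site mean.
#'   Default 1.
#' @param effect_temp true causal effect of temperature on abundance
#'   (the target of every estimator). Default 1.
#' @param effect_recruit effect of recruitment on abundance. Default 1.
#' @param noise_sd SD of the Gaussian outcome noise. Default 1.
#' @param seed master seed (integer).
#' @param variant one of `"snail"`, `"no_confounding"`, `"site_trend"`,
#'   `"spatiotemporal"`.
#' @param trend_sd SD of the site trend slopes (site_trend only). Default 0.5.
#' @param trend_in_exposure should the site trend also enter the exposure
#'   (site_trend only)? Default TRUE.
#' @param n_plots plots per site (spatiotemporal only). Default 4.
#' @param pulse_sd SD of the site-by-year pulses (spatiotemporal only).
#'   Default 1.
#' @param pulse_recruit_slope effect of a pulse on recruitment. Default 2.
#' @param pulse_temp_slope effect of a pulse on temperature (negative:
#'   pulses are cold). Default -2.
#' @param plot_sd SD of time-invariant plot intercepts (spatiotemporal
#'   only). Default 1.
#'
#' @return A `dgp_config` object (validated list).
#' @export
dgp_config <- function(n_sites = 10, n_years = 10,
                       oce_sd = 1, recruit_slope = -2, recruit_mean = 10,
                       temp_slope = 2, temp_mean = 15, temp_within_sd = 1,
                       effect_temp = 1, effect_recruit = 1, noise_sd = 1,
                       seed = 1,
                       variant = c("snail", "no_confounding", "site_trend",
                                   "spatiotemporal"),
                       trend_sd = 0.5, trend_in_exposure = TRUE,
                       n_plots = 4, pulse_sd = 1,
                       pulse_recruit_slope = 2, pulse_temp_slope = -2,
                       plot_sd = 1) {
  if (is.character(variant) && length(variant) == 1 &&
      !variant %in% c("snail", "no_confounding", "site_trend", "spatiotemporal")) {
    stop_config("unknown variant '%s'", variant)
  }
  variant <- match.arg(variant)
  cfg <- list(n_sites = as.integer(n_sites), n_years = as.integer(n_years),
              oce_sd = oce_sd, recruit_slope = recruit_slope,
              recruit_mean = recruit_mean, temp_slope = temp_slope,
              temp_mean = temp_mean, temp_within_sd = temp_within_sd,
              effect_temp = effect_temp, effect_recruit = effect_recruit,
              noise_sd = noise_sd, seed = as.integer(seed), variant = variant,
              trend_sd = trend_sd, trend_in_exposure = isTRUE(trend_in_exposure),
              n_plots = as.integer(n_plots), pulse_sd = pulse_sd,
              pulse_recruit_slope = pulse_recruit_slope,
              pulse_temp_slope = pulse_temp_slope, plot_sd = plot_sd)
  sds <- c("oce_sd", "temp_within_sd", "noise_sd", "trend_sd", "pulse_sd", "plot_sd")
  for (s in sds) if (cfg[[s]] < 0) stop_config("%s must be >= 0, got %g", s, cfg[[s]])
  if (cfg$n_sites < 2) stop_config("n_sites must be >= 2, got %d", cfg$n_sites)
  if (cfg$n_years < 2) stop_config("n_years must be >= 2, got %d", cfg$n_years)
  if (variant == "spatiotemporal" && cfg$n_plots < 1)
    stop_config("n_plots must be >= 1, got %d", cfg$n_plots)
  class(cfg) <- "dgp_config"
  cfg
}

site_labels <- function(n) sprintf("S%02d", seq_len(n))

#' Simulate one confounded panel
#'
#' Draws one realisation of the system described in [dgp_config()]. All
#' randomness is derived from `(config$seed, replicate)` through
#' independent RNG substreams, one per generation stage, so the same
#' `(config, replicate)` pair always yields a byte-identical panel and
#' replicate `r` of [simulate_many()] can be regenerated alone.
#'
#' @param config a [dgp_config()] object.
#' @param replicate replicate index (0 for a single run); replicate `r`
#'   uses the `r`-th RNG stream derived from the master seed.
#' @return A list with elements `panel` (a [panel_data] object; roles
#'   `site`, `year`\[, `plot`\], outcome `snails`, exposure `temp`) and
#'   `truth` (per-site latent variables and the true effect size).
#' @export
#' @examples
#' sim <- simulate_panel(dgp_config(seed = 1))
#' nrow(sim$panel)           # 10 sites x 10 years
#' sim$truth$beta1           # true temperature effect
simulate_panel <- function(config, replicate = 0L) {
  stopifnot(inherits(config, "dgp_config"))
  cfg <- config
  ns <- cfg$n_sites; ny <- cfg$n_years
  rs_eff <- if (cfg$variant == "no_confounding") 0 else cfg$recruit_slope

  O <- with_rng_substream(cfg$seed, replicate, 1L,
                          stats::rnorm(ns, 0, cfg$oce_sd))
  R <- rs_eff * O + cfg$recruit_mean
  T_site <- cfg$temp_slope * O + cfg$temp_mean

  lambda <- NULL; pulses <- NULL; plot_eff <- NULL

  if (cfg$variant %in% c("snail", "no_confounding", "site_trend")) {
    site <- rep(site_labels(ns), each = ny)
    year <- rep(seq_len(ny), times = ns)
    x_mean <- rep(T_site, each = ny)
    conf <- cfg$effect_recruit * rep(R, each = ny)
    if (cfg$variant == "site_trend") {
      lambda <- with_rng_substream(cfg$seed, replicate, 2L,
                                   stats::rnorm(ns, 0, cfg$trend_sd))
      trend <- rep(lambda, each = ny) * year
      if (cfg$trend_in_exposure) x_mean <- x_mean + trend
      conf <- conf + trend                      # development-like confounder
    }
    x <- x_mean + with_rng_substream(cfg$seed, replicate, 3L,
                                     stats::rnorm(ns * ny, 0, cfg$temp_within_sd))
    y <- cfg$effect_temp * x + conf +
      with_rng_substream(cfg$seed, replicate, 4L,
                         stats::rnorm(ns * ny, 0, cfg$noise_sd))
    df <- data.frame(site = site, year = year, plot = NA_character_,
                     snails = y, temp = x, stringsAsFactors = FALSE)
    df$plot <- NULL
    panel <- panel_data(df, unit = "site", time = "year",
                        outcome = "snails", exposure = "temp")
  } else {                                      # spatiotemporal
    np <- cfg$n_plots
    pulses <- with_rng_substream(cfg$seed, replicate, 2L,
                                 matrix(stats::rnorm(ns * ny, 0, cfg$pulse_sd), ns, ny))
    plot_eff <- with_rng_substream(cfg$seed, replicate, 5L,
                                   stats::rnorm(ns * np, 0, cfg$plot_sd))
    site <- rep(site_labels(ns), each = ny * np)
    year <- rep(rep(seq_len(ny), each = np), times = ns)
    plot <- rep(sprintf("P%02d", seq_len(np)), times = ns * ny)
    i <- rep(seq_len(ns), each = ny * np)
    ij <- cbind(i, year)
    k <- (i - 1L) * np + rep(seq_len(np), times = ns * ny)
    R_ij <- cfg$recruit_mean + rs_eff * O[i] + cfg$pulse_recruit_slope * pulses[ij]
    x_mean <- cfg$temp_mean + cfg$temp_slope * O[i] + cfg$pulse_temp_slope * pulses[ij]
    x <- x_mean + with_rng_substream(cfg$seed, replicate, 3L,
                                     stats::rnorm(ns * ny * np, 0, cfg$temp_within_sd))
    y <- cfg$effect_temp * x + cfg$effect_recruit * R_ij + plot_eff[k] +
      with_rng_substream(cfg$seed, replicate, 4L,
                         stats::rnorm(ns * ny * np, 0, cfg$noise_sd))
    df <- data.frame(site = site, year = year, plot = plot,
                     snails = y, temp = x, stringsAsFactors = FALSE)
    panel <- panel_data(df, unit = "site", time = "year",
                        outcome = "snails", exposure = "temp",
                        subunit = "plot")
  }

  truth <- list(oceanography = O, recruitment = R, site_temp = T_site,
                site_trend = lambda, pulses = pulses, plot_effects = plot_eff,
                beta1 = cfg$effect_temp, replicate = as.integer(replicate),
                seed = cfg$seed, variant = cfg$variant)
  list(panel = panel, truth = truth)
}

#' Simulate a stream of independent replicate panels
#'
#' @param config a [dgp_config()] object.
#' @param n_reps number of replicates (>= 1).
#' @return A list of `n_reps` results of [simulate_panel()], replicate
#'   `r` identical to `simulate_panel(config, replicate = r)`.
#' @export
simulate_many <- function(config, n_reps) {
  stopifnot(inherits(config, "dgp_config"))
  if (n_reps < 1) stop_config("n_reps must be >= 1, got %s", n_reps)
  lapply(seq_len(n_reps), function(r) simulate_panel(config, replicate = r))
}
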