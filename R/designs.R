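#' Specify a statistical design
#'
#' A `design_spec` names one estimator from the design menu and the
#' standard-error machinery to use with it. The menu:
#'
#' * `naive`: pooled OLS of outcome on intercept + exposure, ignoring
#'   clustering;
#' * `random_effects`: Gaussian random site intercept, fitted by REML;
#' * `fe_within`: econometric fixed effects via the within (mean
#'   differencing) transformation;
#' * `fe_dummy`: econometric fixed effects via one mean-coded indicator
#'   per site (no global intercept), algebraically identical to
#'   `fe_within`;
#' * `group_mean_covariate`: correlated random effects (Mundlak device):
#'   exposure plus its site mean as a covariate, with or without a site
#'   random intercept;
#' * `group_mean_centered`: the within/between decomposition: site-centred
#'   exposure plus the site mean, with or without a site random intercept;
#' * `first_difference`: consecutive-year differences with one intercept
#'   per site (the site-specific trend slope);
#' * `second_difference`: twice-differenced outcome on twice-differenced
#'   exposure, no intercepts;
#' * `twoway_fe`: plot fixed effects plus site-by-year fixed effects
#'   (subunit panels);
#' * `twoway_mundlak`: plot means and site-year means as covariates with
#'   plot and site-year random intercepts (subunit panels).
#'
#' @param design design name (see above).
#' @param include_random_effect for the two group-mean designs: estimate
#'   with a site random intercept (REML) rather than OLS. Default FALSE.
#' @param se_type `"model"` or `"cluster_robust"` (CR1, clustered on
#'   `cluster_level`). Applies to the OLS-based designs.
#' @param cluster_level role to cluster on, currently `"unit"`.
#' @param truth true effect value used only for coverage bookkeeping in
#'   the study engine. Default 1.
#' @param label optional display label; defaults to a readable name.
#' @return A `design_spec` object.
#' @export
design_spec <- function(design = c("naive", "random_effects", "fe_within",
                                   "fe_dummy", "group_mean_covariate",
                                   "group_mean_centered", "first_difference",
                                   "second_difference", "twoway_fe",
                                   "twoway_mundlak"),
                        include_random_effect = FALSE,
                        se_type = c("model", "cluster_robust"),
                        cluster_level = "unit", truth = 1, label = NULL) {
  if (is.character(design) && length(design) == 1 &&
      !design %in% eval(formals(design_spec)$design)) {
    stop_config("unknown design '%s'", design)
  }
  design <- match.arg(design)
  se_type <- match.arg(se_type)
  if (is.null(label)) {
    label <- design
    if (design %in% c("group_mean_covariate", "group_mean_centered")) {
      label <- paste0(design, if (include_random_effect) "_re" else "_ols")
    }
  }
  structure(list(design = design,
                 include_random_effect = isTRUE(include_random_effect),
                 se_type = se_type, cluster_level = cluster_level,
                 truth = truth, label = label),
            class = "design_spec")
}

#' Fit one design to a panel
#'
#' Dispatches to the `fit_*` function named by the spec.
#'
#' @param data a [panel_data] object.
#' @param spec a [design_spec()].
#' @return A `fit_result`.
#' @export
fit_design <- function(data, spec) {
  stopifnot(inherits(spec, "design_spec"))
  switch(spec$design,
    naive = fit_naive(data, se_type = spec$se_type),
    random_effects = fit_random_intercept(data),
    fe_within = fit_fe_within(data, se_type = spec$se_type),
    fe_dummy = fit_fe_dummy(data, se_type = spec$se_type),
    group_mean_covariate = fit_group_mean_covariate(
      data, include_random_effect = spec$include_random_effect,
      se_type = spec$se_type),
    group_mean_centered = fit_group_mean_centered(
      data, include_random_effect = spec$include_random_effect,
      se_type = spec$se_type),
    first_difference = fit_first_difference(data, se_type = spec$se_type),
    second_difference = fit_second_difference(data, se_type = spec$se_type),
    twoway_fe = fit_twoway_fe(data, se_type = spec$se_type),
    twoway_mundlak = fit_twoway_mundlak(data))
}

coef_table <- function(fit, terms = names(fit$coef)) {
  data.frame(term = terms, estimate = unname(fit$coef),
             se = unname(fit$se), stringsAsFactors = FALSE)
}

ols_result <- function(design, data, y, X, beta1_term, se_type,
                       cluster = NULL, absorbed = 0L) {
  fit <- fit_ols_core(y, X, cluster = cluster, se_type = se_type,
                      absorbed = absorbed)
  new_fit_result(design, coef_table(fit), beta1_term, fit$sigma2,
                 n_obs = fit$n, n_units = length(unique(data$unit)),
                 dof = fit$dof, se_type = fit$se_type, dropped = fit$dropped)
}

#' Naive pooled regression
#'
#' OLS of outcome on intercept plus exposure, pooling all rows and
#' ignoring the clustered structure. Under cross-site confounding this
#' estimator absorbs omitted-variable bias
#' \eqn{\beta_1 + \gamma\,\mathrm{Cov}(x, w)/\mathrm{Var}(x)}.
#'
#' @param data a [panel_data] object.
#' @param se_type `"model"` or `"cluster_robust"`.
#' @return A `fit_result` with terms `(Intercept)` and `x`.
#' @export
fit_naive <- function(data, se_type = "model") {
  stopifnot(inherits(data, "panel_data"))
  X <- cbind("(Intercept)" = 1, x = data$x)
  ols_result("naive", data, data$y, X, "x", se_type, cluster = data$unit)
}

#' Fixed effects via the within transformation
#'
#' OLS of the unit-mean-centred outcome on the unit-mean-centred
#' exposure, no intercept. Residual degrees of freedom account for the
#' absorbed unit means (`n - n_units - 1`) so standard errors match the
#' dummy-variable parameterisation exactly.
#'
#' @inheritParams fit_naive
#' @return A `fit_result` with term `x`.
#' @export
fit_fe_within <- function(data, se_type = "model") {
  stopifnot(inherits(data, "panel_data"))
  w <- within_center(data)
  if (sum(w$x^2) <= 0) {
    stop_estimation("design not identified: no within-unit exposure variance")
  }
  X <- cbind(x = w$x)
  ols_result("fe_within", data, w$y, X, "x", se_type, cluster = w$unit,
             absorbed = length(unique(data$unit)))
}

#' Fixed effects via mean-coded unit dummies
#'
#' OLS of the outcome on the exposure plus one indicator per unit and no
#' global intercept, so each \eqn{\lambda_i} is the unit's own intercept.
#' Point estimate and standard error of the exposure effect are
#' algebraically identical to [fit_fe_within()].
#'
#' @inheritParams fit_naive
#' @return A `fit_result`; unit intercepts are terms `unit::<label>`.
#' @export
fit_fe_dummy <- function(data, se_type = "model") {
  stopifnot(inherits(data, "panel_data"))
  u <- factor(data$unit)
  D <- stats::model.matrix(~ 0 + u)
  colnames(D) <- paste0("unit::", levels(u))
  X <- cbind(x = data$x, D)
  ols_result("fe_dummy", data, data$y, X, "x", se_type, cluster = data$unit)
}

#' Group mean covariate (Mundlak / correlated random effects)
#'
#' Regresses the outcome on an intercept, the exposure, and the unit
#' mean of the exposure. The coefficient on the unit mean is the
#' contextual effect \eqn{\beta_2}; the exposure coefficient is purged
#' of unit-level confounding and equals the within estimator on balanced
#' panels. With `include_random_effect` the model adds a Gaussian unit
#' intercept and is fitted by REML.
#'
#' @inheritParams fit_naive
#' @param include_random_effect add a unit random intercept (REML)?
#' @return A `fit_result` with terms `(Intercept)`, `x`, `unit_mean_x`.
#' @export
fit_group_mean_covariate <- function(data, include_random_effect = FALSE,
                                     se_type = "model") {
  stopifnot(inherits(data, "panel_data"))
  d <- add_group_means(data, "unit")
  if (sum((d$x - d$unit_mean_x)^2) <= 0) {
    stop_estimation("design not identified: unit mean exposure collinear with exposure")
  }
  X <- cbind("(Intercept)" = 1, x = d$x, unit_mean_x = d$unit_mean_x)
  if (include_random_effect) {
    fit <- reml_random_intercept(d$y, X, d$unit)
    res <- new_fit_result("group_mean_covariate", coef_table(fit), "x",
                          fit$sigma2, n_obs = fit$n,
                          n_units = length(unique(d$unit)), dof = fit$dof,
                          se_type = "model", sigma2_site = fit$sigma2_group)
    return(res)
  }
  ols_result("group_mean_covariate", d, d$y, X, "x", se_type,
             cluster = d$unit)
}

#' Group mean centering (within/between decomposition)
#'
#' Regresses the outcome on an intercept, the unit-centred exposure
#' anomaly, and the unit mean of the exposure. The anomaly coefficient
#' is the within effect \eqn{\beta_1}; the unit-mean coefficient is the
#' between estimator and satisfies
#' \eqn{\beta_2^{centered} = \beta_1 + \beta_2^{mundlak}}.
#'
#' @inheritParams fit_group_mean_covariate
#' @return A `fit_result` with terms `(Intercept)`, `x_centered`,
#'   `unit_mean_x`.
#' @export
fit_group_mean_centered <- function(data, include_random_effect = FALSE,
                                    se_type = "model") {
  stopifnot(inherits(data, "panel_data"))
  d <- add_group_means(data, "unit")
  xc <- d$x - d$unit_mean_x
  if (sum(xc^2) <= 0) {
    stop_estimation("design not identified: no within-unit exposure variance")
  }
  X <- cbind("(Intercept)" = 1, x_centered = xc, unit_mean_x = d$unit_mean_x)
  if (include_random_effect) {
    fit <- reml_random_intercept(d$y, X, d$unit)
    return(new_fit_result("group_mean_centered", coef_table(fit), "x_centered",
                          fit$sigma2, n_obs = fit$n,
                          n_units = length(unique(d$unit)), dof = fit$dof,
                          se_type = "model", sigma2_site = fit$sigma2_group))
  }
  ols_result("group_mean_centered", d, d$y, X, "x_centered", se_type,
             cluster = d$unit)
}

#' Random-intercept mixed model (REML)
#'
#' The model ecologists reach for by default: outcome on intercept plus
#' exposure with a Gaussian site intercept, fitted by restricted maximum
#' likelihood. The REML criterion is profiled over the variance ratio
#' \eqn{\theta = \sigma^2_{site}/\sigma^2} by bounded one-dimensional
#' search on \eqn{[10^{-8}, 10^8]} with GLS for the fixed effects at
#' each ratio. When the site intercept is correlated with the exposure
#' (the confounded system), the random-effects assumption fails and this
#' estimator is biased — which is exactly what the Monte-Carlo study
#' engine demonstrates.
#'
#' @param data a [panel_data] object with at least two units.
#' @return A `fit_result` with terms `(Intercept)` and `x`, and variance
#'   components `sigma2_site` and residual `sigma2`.
#' @export
fit_random_intercept <- function(data) {
  stopifnot(inherits(data, "panel_data"))
  X <- cbind("(Intercept)" = 1, x = data$x)
  fit <- reml_random_intercept(data$y, X, data$unit)
  new_fit_result("random_effects", coef_table(fit), "x", fit$sigma2,
                 n_obs = fit$n, n_units = length(unique(data$unit)),
                 dof = fit$dof, se_type = "model",
                 sigma2_site = fit$sigma2_group)
}

#' First-difference design
#'
#' Differences outcome and exposure between consecutive years within
#' each site and regresses the outcome differences on the exposure
#' differences with one mean-coded intercept per site; each intercept
#' \eqn{\lambda_i} estimates that site's linear trend slope, so
#' time-invariant site confounding and site-specific linear trends are
#' both removed. One year of data is lost per site. Set
#' `per_unit_intercept = FALSE` for trend-free settings.
#'
#' @inheritParams fit_naive
#' @param per_unit_intercept include the per-site intercepts (default
#'   TRUE).
#' @return A `fit_result` with term `x` (the differenced exposure) and
#'   site intercept terms `unit::<label>`.
#' @export
fit_first_difference <- function(data, se_type = "model",
                                 per_unit_intercept = TRUE) {
  stopifnot(inherits(data, "panel_data"))
  d <- difference(data, 1)
  if (per_unit_intercept) {
    u <- factor(d$unit)
    D <- stats::model.matrix(~ 0 + u)
    colnames(D) <- paste0("unit::", levels(u))
    X <- cbind(x = d$x, D)
  } else {
    X <- cbind("(Intercept)" = 1, x = d$x)
  }
  res <- ols_result("first_difference", d, d$y, X, "x", se_type,
                    cluster = d$unit)
  if ("x" %in% res$dropped) {
    stop_estimation("design not identified: differenced exposure collinear with unit intercepts")
  }
  res
}

#' Second-difference design
#'
#' Differences the first differences again and regresses
#' \eqn{\Delta^2 y} on \eqn{\Delta^2 x} with no intercepts: double
#' differencing annihilates site constants and site-specific linear
#' trends, eliminating the need to estimate the trend slopes. Two years
#' of data are lost per site; at least one site must contribute three
#' consecutive years.
#'
#' @inheritParams fit_naive
#' @return A `fit_result` with term `x`.
#' @export
fit_second_difference <- function(data, se_type = "model") {
  stopifnot(inherits(data, "panel_data"))
  d <- difference(data, 2)
  if (sum(d$x^2) <= 0) {
    stop_estimation("design not identified: twice-differenced exposure is constant")
  }
  X <- cbind(x = d$x)
  ols_result("second_difference", d, d$y, X, "x", se_type, cluster = d$unit)
}

twoway_matrices <- function(data) {
  if (is.null(data$subunit)) {
    stop_config("two-way designs require a subunit (plot) column")
  }
  plot_id <- factor(paste(data$unit, data$subunit, sep = ":"))
  st_id <- factor(paste(data$unit, data$time, sep = ":"))
  list(plot_id = plot_id, st_id = st_id)
}

#' Two-way fixed effects (plot and site-by-year)
#'
#' OLS of the outcome on the exposure plus mean-coded plot intercepts
#' \eqn{\lambda_k} and site-by-year intercepts \eqn{\eta_{ij}}, for
#' panels with multiple plots per site observed over years. The
#' site-by-year terms absorb spatiotemporal confounding (e.g. site-year
#' recruitment pulses); the plot terms absorb time-invariant plot
#' differences. Jointly collinear cells are dropped and reported.
#'
#' @inheritParams fit_naive
#' @return A `fit_result` with term `x`, plot terms `plot::<id>` and
#'   site-year terms `siteyear::<id>`.
#' @export
fit_twoway_fe <- function(data, se_type = "model") {
  stopifnot(inherits(data, "panel_data"))
  ids <- twoway_matrices(data)
  if (!any(tapply(as.character(ids$plot_id), as.character(ids$st_id),
                  function(p) length(unique(p))) > 1)) {
    stop_estimation("design not identified: site-by-year effects saturate (one plot per site)")
  }
  P <- stats::model.matrix(~ 0 + ids$plot_id)
  colnames(P) <- paste0("plot::", levels(ids$plot_id))
  S <- stats::model.matrix(~ 0 + ids$st_id)
  colnames(S) <- paste0("siteyear::", levels(ids$st_id))
  X <- cbind(x = data$x, P, S)
  res <- ols_result("twoway_fe", data, data$y, X, "x", se_type,
                    cluster = data$unit)
  if ("x" %in% res$dropped) {
    stop_estimation("design not identified: no exposure variance after absorbing plot and site-year effects")
  }
  res
}

#' Two-way Mundlak design (correlated random effects)
#'
#' The efficient alternative to [fit_twoway_fe()] for small panels:
#' outcome on intercept, exposure, plot-mean exposure and site-year-mean
#' exposure, with Gaussian random intercepts for plot and for each
#' site-year combination, fitted by two-component REML (nested profile
#' over the two variance ratios).
#'
#' @param data a [panel_data] object with a subunit column.
#' @return A `fit_result` with terms `(Intercept)`, `x`,
#'   `subunit_mean_x` (plot mean) and `unit_time_mean_x` (site-year
#'   mean), plus variance components for plot, site-year and residual.
#' @export
fit_twoway_mundlak <- function(data) {
  stopifnot(inherits(data, "panel_data"))
  ids <- twoway_matrices(data)
  if (!any(tapply(as.character(ids$plot_id), as.character(ids$st_id),
                  function(p) length(unique(p))) > 1)) {
    stop_estimation("design not identified: one plot per site")
  }
  d <- add_group_means(add_group_means(data, "subunit"), "unit_time")
  X <- cbind("(Intercept)" = 1, x = d$x,
             subunit_mean_x = d$subunit_mean_x,
             unit_time_mean_x = d$unit_time_mean_x)
  fit <- reml_two_component(d$y, X, ids$plot_id, ids$st_id)
  new_fit_result("twoway_mundlak", coef_table(fit), "x", fit$sigma2,
                 n_obs = fit$n, n_units = length(unique(d$unit)),
                 dof = fit$dof, se_type = "model",
                 sigma2_plot = fit$sigma2_group1,
                 sigma2_site_time = fit$sigma2_group2)
}
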