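#' Fitted-design container
#'
#' Every design fit returns a `fit_result`: a coefficient table (term,
#' estimate, standard error, interval), variance components where a
#' random intercept was estimated, and bookkeeping (sample sizes,
#' residual degrees of freedom, standard-error type). Intervals in the
#' table use the plus/minus two standard errors rule by default; the
#' study engine recomputes intervals under its own configured rule.
#'
#' @param design design name.
#' @param coefficients data frame with columns `term`, `estimate`, `se`.
#' @param beta1_term name of the term carrying the exposure effect.
#' @param sigma2 residual variance.
#' @param sigma2_site site-level variance component (random-intercept
#'   fits), `NA` otherwise.
#' @param sigma2_site_time site-by-time variance component (two-way
#'   Mundlak), `NA` otherwise.
#' @param sigma2_plot plot-level variance component (two-way Mundlak),
#'   `NA` otherwise.
#' @param n_obs,n_units,dof sample size, number of units, residual
#'   degrees of freedom.
#' @param se_type standard-error type used.
#' @param rule interval rule used for the table's `ci_low`/`ci_high`.
#' @param dropped names of collinear columns dropped, if any.
#' @return A `fit_result` object.
#' @keywords internal
new_fit_result <- function(design, coefficients, beta1_term, sigma2,
                           n_obs, n_units, dof, se_type,
                           sigma2_site = NA_real_,
                           sigma2_site_time = NA_real_,
                           sigma2_plot = NA_real_,
                           rule = interval_rule(), dropped = character(0)) {
  ci <- make_interval(coefficients$estimate, coefficients$se, dof = dof, rule = rule)
  coefficients$ci_low <- ci$low
  coefficients$ci_high <- ci$high
  structure(list(design = design, coefficients = coefficients,
                 beta1_term = beta1_term, sigma2 = sigma2,
                 sigma2_site = sigma2_site,
                 sigma2_site_time = sigma2_site_time,
                 sigma2_plot = sigma2_plot,
                 n_obs = n_obs, n_units = n_units, dof = dof,
                 se_type = se_type, dropped = dropped),
            class = "fit_result")
}

#' Extract the exposure coefficient of a fitted design
#'
#' @param fit a `fit_result`.
#' @return One-row data frame with `term`, `estimate`, `se`, `ci_low`,
#'   `ci_high` for the exposure (within) effect.
#' @export
beta1 <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  fit$coefficients[fit$coefficients$term == fit$beta1_term, , drop = FALSE]
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> design: %s  (n = %d, units = %d, dof = %d, SE: %s)\n",
              x$design, x$n_obs, x$n_units, x$dof, x$se_type))
  tab <- x$coefficients
  tab$estimate <- signif(tab$estimate, 5)
  tab$se <- signif(tab$se, 5)
  tab$ci_low <- signif(tab$ci_low, 5)
  tab$ci_high <- signif(tab$ci_high, 5)
  # keep printed output short for designs with many cluster intercepts
  if (nrow(tab) > 8) {
    print(tab[seq_len(8), ], row.names = FALSE)
    cat(sprintf("... and %d more terms\n", nrow(tab) - 8))
  } else print(tab, row.names = FALSE)
  if (is.finite(x$sigma2_site))
    cat(sprintf("sigma2_site = %.5g  ", x$sigma2_site))
  if (is.finite(x$sigma2_plot))
    cat(sprintf("sigma2_plot = %.5g  sigma2_site_time = %.5g  ",
                x$sigma2_plot, x$sigma2_site_time))
  cat(sprintf("residual sigma2 = %.5g\n", x$sigma2))
  invisible(x)
}

#' Serialise a fit result to JSON
#'
#' @param fit a `fit_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
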