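#' The shipped nine-design comparison menu
#'
#' The fixed menu the Monte-Carlo engine uses to compare designs on the
#' confounded snail system: naive, random effects, fixed effects (within
#' and dummy coded), group mean covariate and group mean centered (each
#' with and without a site random effect), and first differences.
#'
#' @param truth true effect used for coverage bookkeeping. Default 1.
#' @return A named list of [design_spec()] objects in table order.
#' @export
table1_designs <- function(truth = 1) {
  specs <- list(
    design_spec("naive", truth = truth, label = "naive"),
    design_spec("random_effects", truth = truth, label = "random_effects"),
    design_spec("fe_within", truth = truth, label = "fe_within"),
    design_spec("fe_dummy", truth = truth, label = "fe_dummy"),
    design_spec("group_mean_covariate", include_random_effect = TRUE,
                truth = truth, label = "group_mean_covariate_re"),
    design_spec("group_mean_centered", include_random_effect = TRUE,
                truth = truth, label = "group_mean_centered_re"),
    design_spec("group_mean_covariate", include_random_effect = FALSE,
                truth = truth, label = "group_mean_covariate_ols"),
    design_spec("group_mean_centered", include_random_effect = FALSE,
                truth = truth, label = "group_mean_centered_ols"),
    design_spec("first_difference", truth = truth, label = "first_difference")
  )
  names(specs) <- vapply(specs, `[[`, "", "label")
  specs
}

#' Configure a Monte-Carlo design-comparison study
#'
#' @param dgp a [dgp_config()] describing the data-generating process.
#' @param designs list of [design_spec()] objects (non-empty). Defaults
#'   to [table1_designs()].
#' @param n_reps number of simulation replicates (>= 2). Default 100.
#' @param rule an [interval_rule()] for the coverage columns. Default
#'   plus/minus two standard errors.
#' @param truth true exposure effect for coverage bookkeeping; defaults
#'   to the generator's `effect_temp`.
#' @return A `study_config` object.
#' @export
study_config <- function(dgp = dgp_config(), designs = table1_designs(),
                         n_reps = 100, rule = interval_rule(),
                         truth = NULL) {
  stopifnot(inherits(dgp, "dgp_config"))
  if (n_reps < 2) stop_config("n_reps must be >= 2, got %s", n_reps)
  if (length(designs) == 0) stop_config("designs list must be non-empty")
  if (inherits(designs, "design_spec")) designs <- list(designs)
  for (d in designs) {
    if (!inherits(d, "design_spec")) stop_config("designs must be design_spec objects")
  }
  if (is.null(names(designs)) || any(names(designs) == "")) {
    names(designs) <- vapply(designs, `[[`, "", "label")
  }
  if (anyDuplicated(names(designs))) stop_config("design labels must be unique")
  structure(list(dgp = dgp, designs = designs, n_reps = as.integer(n_reps),
                 rule = rule, truth = truth %||% dgp$effect_temp),
            class = "study_config")
}

#' Run a Monte-Carlo design-comparison study
#'
#' Simulates `n_reps` independent panels from the configured generator,
#' fits every design in the menu to each panel, and aggregates per
#' design: the mean and sample standard deviation of the exposure point
#' estimates, the fraction of replicates whose interval contains zero,
#' the fraction whose interval excludes the true effect, and the number
#' of replicates on which the fit succeeded. Replicates where a design
#' fails are excluded from that design's aggregates only. Results are
#' deterministic given the generator's master seed.
#'
#' @param config a [study_config()].
#' @param progress_every log progress every this many replicates
#'   (0 disables). Default 0.
#' @return A `study_result`: list with `summary` (one row per design),
#'   `estimates` (tidy per-replicate table for distribution plots) and
#'   the `config`.
#' @export
run_study <- function(config, progress_every = 0) {
  stopifnot(inherits(config, "study_config"))
  labels <- names(config$designs)
  rows <- vector("list", config$n_reps * length(labels))
  idx <- 0L
  for (r in seq_len(config$n_reps)) {
    sim <- simulate_panel(config$dgp, replicate = r)
    for (lab in labels) {
      spec <- config$designs[[lab]]
      fit <- tryCatch(suppressMessages(fit_design(sim$panel, spec)),
                      error = function(e) NULL)
      idx <- idx + 1L
      if (is.null(fit)) {
        rows[[idx]] <- data.frame(replicate = r, design = lab,
                                  estimate = NA_real_, se = NA_real_,
                                  dof = NA_integer_, converged = FALSE,
                                  stringsAsFactors = FALSE)
      } else {
        b <- beta1(fit)
        rows[[idx]] <- data.frame(replicate = r, design = lab,
                                  estimate = b$estimate, se = b$se,
                                  dof = fit$dof, converged = TRUE,
                                  stringsAsFactors = FALSE)
      }
    }
    if (progress_every > 0 && r %% progress_every == 0) {
      log_msg("replicate %d/%d done", r, config$n_reps)
    }
  }
  estimates <- do.call(rbind, rows)

  summary <- do.call(rbind, lapply(labels, function(lab) {
    e <- estimates[estimates$design == lab & estimates$converged, , drop = FALSE]
    n_conv <- nrow(e)
    if (n_conv == 0) {
      return(data.frame(design = lab, mean_estimate = NA_real_,
                        sd_estimate = NA_real_,
                        frac_ci_contains_zero = NA_real_,
                        frac_ci_excludes_truth = NA_real_,
                        n_converged = 0L, stringsAsFactors = FALSE))
    }
    ci <- make_interval(e$estimate, e$se, rule = config$rule, dof = e$dof)
    fl <- interval_flags(ci$low, ci$high, config$truth)
    data.frame(design = lab,
               mean_estimate = mean(e$estimate),
               sd_estimate = stats::sd(e$estimate),
               frac_ci_contains_zero = mean(fl$contains_zero),
               frac_ci_excludes_truth = mean(fl$excludes_truth),
               n_converged = n_conv, stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(summary = summary, estimates = estimates, config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d replicates, %d designs, truth = %g\n",
              x$config$n_reps, length(x$config$designs), x$config$truth))
  tab <- x$summary
  for (col in c("mean_estimate", "sd_estimate", "frac_ci_contains_zero",
                "frac_ci_excludes_truth")) tab[[col]] <- signif(tab[[col]], 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Export study results to CSV
#'
#' Writes the per-design summary (one row per design: mean and SD of
#' point estimates, the two coverage fractions, and the number of
#' converged replicates) and, optionally, the tidy per-replicate
#' estimate table for plotting estimate distributions.
#'
#' @param result a `study_result`.
#' @param path output CSV path for the summary table.
#' @param estimates_path optional CSV path for per-replicate estimates.
#' @return `path`, invisibly.
#' @export
export_table <- function(result, path, estimates_path = NULL) {
  stopifnot(inherits(result, "study_result"))
  utils::write.csv(result$summary, path, row.names = FALSE)
  if (!is.null(estimates_path)) {
    utils::write.csv(result$estimates, estimates_path, row.names = FALSE)
  }
  invisible(path)
}
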