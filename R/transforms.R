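#' Attach group-mean columns to a panel
#'
#' Computes means of the exposure (and, for the unit level, the outcome)
#' over observed rows at the requested grouping level and attaches them as
#' derived columns. Unbalanced groups use their own observed `n`; no
#' reweighting is applied.
#'
#' Levels and the columns they add:
#' * `"unit"`: `unit_mean_x` (site-mean exposure, the Mundlak covariate)
#'   and `unit_mean_y`;
#' * `"subunit"`: `subunit_mean_x` (plot-mean exposure across years);
#' * `"unit_time"`: `unit_time_mean_x` (site-by-year mean exposure across
#'   plots).
#'
#' Adding group means to an already-augmented panel simply recomputes the
#' same values (idempotent).
#'
#' @param data a [panel_data] object.
#' @param level one of `"unit"`, `"subunit"`, `"unit_time"`. The subunit
#'   and unit-time levels require a subunit column.
#' @return `data` with the derived mean columns attached.
#' @export
add_group_means <- function(data, level = c("unit", "subunit", "unit_time")) {
  stopifnot(inherits(data, "panel_data"))
  level <- match.arg(level)
  if (level %in% c("subunit", "unit_time") && is.null(data$subunit)) {
    stop_config("level '%s' requires a subunit column", level)
  }
  g <- switch(level,
    unit = data$unit,
    subunit = paste(data$unit, data$subunit, sep = "\r"),
    unit_time = paste(data$unit, data$time, sep = "\r"))
  if (level == "unit") {
    data$unit_mean_x <- stats::ave(data$x, g)
    data$unit_mean_y <- stats::ave(data$y, g)
  } else if (level == "subunit") {
    data$subunit_mean_x <- stats::ave(data$x, g)
  } else {
    data$unit_time_mean_x <- stats::ave(data$x, g)
  }
  data
}

#' Within-transform a panel (centre on unit means)
#'
#' Replaces the outcome and exposure by their deviations from the unit
#' (site) means, the algebraic heart of the econometric fixed-effects
#' design: any column that is constant within units is annihilated, so
#' time-invariant site-level confounding cannot reach the slope. After
#' the transform the per-unit sums of `y` and `x` are zero.
#'
#' @param data a [panel_data] object.
#' @return A [panel_data] object with centred `y` and `x`; the original
#'   values are kept as `y_orig` / `x_orig` and the unit means as
#'   `unit_mean_x` / `unit_mean_y`.
#' @export
within_center <- function(data) {
  stopifnot(inherits(data, "panel_data"))
  data <- add_group_means(data, "unit")
  data$y_orig <- data$y
  data$x_orig <- data$x
  data$y <- data$y - data$unit_mean_y
  data$x <- data$x - data$unit_mean_x
  attr(data, "within_centered") <- TRUE
  data
}

#' Difference a panel over consecutive times
#'
#' Emits, per unit, one row for every pair of consecutive times
#' (`time` differing by exactly 1), with `y` and `x` replaced by their
#' first differences; `order = 2` differences the first differences
#' again. Gaps in the time grid produce no row; the number of skipped
#' non-consecutive transitions is reported via a message. The emitted
#' row carries the later time of each pair.
#'
#' @param data a [panel_data] object (subunit panels are differenced
#'   within unit-subunit series).
#' @param order 1 for first differences, 2 for second differences.
#' @return A [panel_data] object of difference rows.
#' @export
difference <- function(data, order = 1) {
  stopifnot(inherits(data, "panel_data"))
  if (!order %in% c(1, 2)) stop_config("difference order must be 1 or 2, got %s", order)
  if (order == 2) {
    return(tryCatch(difference(difference(data, 1), 1),
      panelcausal_estimation_error = function(e)
        stop_estimation("no unit with enough consecutive times for differencing (order 2)")))
  }
  df <- as_plain_df(data)
  gkey <- if (is.null(df$subunit)) df$unit else paste(df$unit, df$subunit, sep = "\r")
  pieces <- split(df, gkey)
  skipped <- 0L
  res <- lapply(pieces, function(s) {
    s <- s[base::order(s$time), , drop = FALSE]  # arg `order` shadows base
    if (nrow(s) < 2) return(NULL)
    dt <- diff(s$time)
    keep <- dt == 1L
    skipped <<- skipped + sum(!keep)
    if (!any(keep)) return(NULL)
    i <- which(keep) + 1L                       # row of the later time
    out <- s[i, , drop = FALSE]
    out$y <- s$y[i] - s$y[i - 1L]
    out$x <- s$x[i] - s$x[i - 1L]
    out
  })
  res <- do.call(rbind, res)
  if (skipped > 0) log_msg("skipped %d non-consecutive time transition(s)", skipped)
  if (is.null(res) || nrow(res) == 0) {
    stop_estimation("no unit with enough consecutive times for differencing (order %d)", order)
  }
  rownames(res) <- NULL
  attr(res, "roles") <- attr(data, "roles")
  attr(res, "diff_order") <- (attr(data, "diff_order") %||% 0L) + 1L
  class(res) <- c("panel_data", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
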