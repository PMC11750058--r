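#' Interval rules
#'
#' Two interval constructions are supported: `"two_se"`, the estimate
#' plus/minus two standard errors (the rule used by the study engine's
#' coverage bookkeeping), and `"t_quantile"`, the estimate plus/minus the
#' Student-t quantile at the requested level times the standard error.
#'
#' @param kind `"two_se"` or `"t_quantile"`.
#' @param level confidence level in (0, 1); only used by `"t_quantile"`.
#' @return An `interval_rule` object.
#' @export
interval_rule <- function(kind = c("two_se", "t_quantile"), level = 0.95) {
  kind <- match.arg(kind)
  if (!(level > 0 && level < 1)) stop_config("level must be in (0, 1), got %g", level)
  structure(list(kind = kind, level = level), class = "interval_rule")
}

#' Build an interval around an estimate
#'
#' @param estimate point estimate(s).
#' @param se standard error(s), must be >= 0. A zero standard error gives
#'   the degenerate interval `(estimate, estimate)`.
#' @param dof residual degrees of freedom; required (>= 1) for the
#'   t-quantile rule.
#' @param rule an [interval_rule()].
#' @return A list with numeric vectors `low` and `high`.
#' @export
#' @examples
#' make_interval(1, 0.2)                                   # (0.6, 1.4)
#' make_interval(0, 1, dof = 10, interval_rule("t_quantile"))
make_interval <- function(estimate, se, rule = interval_rule(), dof = NULL) {
  if (any(se < 0, na.rm = TRUE)) stop_config("standard errors must be >= 0")
  mult <- if (rule$kind == "two_se") 2 else {
    if (is.null(dof) || any(dof < 1)) stop_config("t_quantile rule needs dof >= 1")
    stats::qt((1 + rule$level) / 2, df = dof)
  }
  list(low = estimate - mult * se, high = estimate + mult * se)
}

#' Coverage flags for one interval
#'
#' The two Monte-Carlo bookkeeping columns: does the interval contain
#' zero (a type-II-error proxy when the true effect is non-zero), and
#' does it exclude the true effect (a coverage failure). Boundary values
#' count as contained.
#'
#' @param low,high interval endpoints (`low <= high`).
#' @param truth true effect value.
#' @return A list with logicals `contains_zero` and `excludes_truth`.
#' @export
interval_flags <- function(low, high, truth) {
  if (any(low > high)) stop_config("interval has low > high")
  list(contains_zero = low <= 0 & 0 <= high,
       excludes_truth = !(low <= truth & truth <= high))
}
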