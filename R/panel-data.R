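#' Construct a panel dataset
#'
#' A `panel_data` object is a long-format data frame of repeated
#' observations of units (sites) over time (years), optionally with
#' subunits (plots within sites). Internally the key columns are
#' standardised to `unit` (character), `time` (integer), `subunit`
#' (character, optional), `y` (outcome) and `x` (exposure); any further
#' columns are carried along as covariates. The mapping back to the
#' original column names is kept in `attr(, "roles")`.
#'
#' Validation enforces: unique `(unit, time[, subunit])` keys, finite
#' outcome and exposure values, at least two distinct units, and
#' orderable times within each unit.
#'
#' @param df data frame in long format.
#' @param unit name of the column identifying the cluster (site).
#' @param time name of the integer-orderable time column (year).
#' @param outcome name of the outcome column (e.g. snail abundance).
#' @param exposure name of the exposure column (e.g. temperature, degrees C).
#' @param subunit optional name of the subunit column (plot within site).
#'
#' @return A `panel_data` object (a data frame).
#' @export
panel_data <- function(df, unit = "unit", time = "time",
                       outcome = "y", exposure = "x", subunit = NULL) {
  roles <- list(unit = unit, time = time, outcome = outcome,
                exposure = exposure, subunit = subunit)
  needed <- c(unit, time, outcome, exposure, subunit)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop_config("column '%s' (role: %s) not found in data",
                missing_cols[[1]],
                names(roles)[match(missing_cols[[1]], unlist(roles))])
  }

  out <- data.frame(
    unit = as.character(df[[unit]]),
    time = as.integer(df[[time]]),
    stringsAsFactors = FALSE
  )
  if (!is.null(subunit)) out$subunit <- as.character(df[[subunit]])
  out$y <- suppressWarnings(as.numeric(df[[outcome]]))
  out$x <- suppressWarnings(as.numeric(df[[exposure]]))

  covars <- setdiff(names(df), needed)
  covars <- setdiff(covars, c("unit", "time", "subunit", "y", "x"))
  for (cv in covars) out[[cv]] <- df[[cv]]

  # drop-and-log: estimators never see missing or non-numeric values
  bad <- !is.finite(out$y) | !is.finite(out$x) | is.na(out$time) |
    is.na(out$unit) | out$unit == ""
  if (any(bad)) {
    log_msg("dropped %d row(s) with missing or non-numeric outcome/exposure/key",
            sum(bad))
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0) stop_validation("no usable rows after validation")

  key <- if (is.null(subunit)) paste(out$unit, out$time, sep = "\r")
         else paste(out$unit, out$time, out$subunit, sep = "\r")
  if (anyDuplicated(key)) {
    first <- out[which(duplicated(key))[1], ]
    stop_validation("duplicate key: unit '%s', time %d%s",
                    first$unit, first$time,
                    if (!is.null(subunit)) sprintf(", subunit '%s'", first$subunit) else "")
  }
  if (length(unique(out$unit)) < 2) {
    stop_validation("panel needs at least 2 distinct units, got %d",
                    length(unique(out$unit)))
  }

  rownames(out) <- NULL
  attr(out, "roles") <- roles
  class(out) <- c("panel_data", "data.frame")
  out
}

#' Read a long-format panel table from CSV
#'
#' Reads a comma-separated file (header row required, UTF-8) and validates
#' it into a [panel_data] object. Units and subunits are read as strings,
#' time as integer. Rows with missing or non-numeric outcome or exposure
#' are dropped and the count is reported via a message.
#'
#' @inheritParams panel_data
#' @param path path to a CSV file.
#' @return A validated [panel_data] object.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(site = c("A", "A", "B", "B"), year = c(1, 2, 1, 2),
#'                      snails = c(1, 3, 10, 14), temp = c(1, 2, 3, 5)),
#'           f, row.names = FALSE)
#' pd <- read_panel(f, unit = "site", time = "year",
#'                  outcome = "snails", exposure = "temp")
#' nrow(pd)
read_panel <- function(path, unit = "unit", time = "time",
                       outcome = "y", exposure = "x", subunit = NULL) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  panel_data(df, unit = unit, time = time, outcome = outcome,
             exposure = exposure, subunit = subunit)
}

#' Write a panel dataset to CSV
#'
#' Columns are written under their original (role-mapped) names so a
#' written file round-trips through [read_panel()].
#'
#' @param data a [panel_data] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(data, path) {
  stopifnot(inherits(data, "panel_data"))
  roles <- attr(data, "roles")
  out <- as.data.frame(data)
  ren <- c(unit = roles$unit, time = roles$time, y = roles$outcome,
           x = roles$exposure)
  if (!is.null(roles$subunit)) ren <- c(ren, subunit = roles$subunit)
  names(out)[match(names(ren), names(out))] <- unname(ren)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.panel_data <- function(x, ...) {
  cat(sprintf("<panel_data> %d rows, %d units%s, times %d..%d\n",
              nrow(x), length(unique(x$unit)),
              if (!is.null(x$subunit)) sprintf(", %d subunits", length(unique(paste(x$unit, x$subunit)))) else "",
              min(x$time), max(x$time)))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more rows\n", nrow(x) - 6))
  invisible(x)
}

# strip the panel_data class (e.g. before rbind/split internals)
as_plain_df <- function(x) {
  class(x) <- "data.frame"
  x
}
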