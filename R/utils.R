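# internal helpers shared across modules

#' Assign single ages to 5-year age groups
#'
#' Ages are grouped into 5-year bands starting at 35 ("35-39", "40-44", ...,
#' "95-99") with a closed top interval "100+".
#'
#' @param age Integer vector of completed ages (35-100).
#' @return Character vector of age-group labels.
#' @export
#' @examples
#' age_group(c(35, 42, 100))
age_group <- function(age) {
  stopifnot(is.numeric(age))
  if (any(age < 35 | age > 100, na.rm = TRUE)) {
    abort("ages must lie in [35, 100]")
  }
  lo <- 35 + 5 * ((age - 35) %/% 5)
  if_else(age >= 100, "100+", paste0(lo, "-", lo + 4))
}

#' All 5-year age-group labels from 35
#' @return Character vector "35-39" ... "95-99", "100+".
#' @export
age_group_levels <- function() {
  c(paste0(seq(35, 95, 5), "-", seq(39, 99, 5)), "100+")
}

# check a data frame has the required columns; error names the missing ones
check_columns <- function(df, required, what = "input") {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

check_sex <- function(x, what = "input") {
  bad <- setdiff(unique(x), SEXES)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s has unknown sex value%s: %s (expected %s)",
      what, if (length(bad) > 1) "s" else "", paste(bad, collapse = ", "),
      paste(SEXES, collapse = ", ")
    ))
  }
  invisible(x)
}

# warning with a package condition class so pipeline code can collect them
bamsim_warn <- function(msg, class = "bamsim_warning") {
  warn(msg, class = c(class, "bamsim_condition"))
}
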