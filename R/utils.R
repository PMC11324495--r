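#' Age groups used throughout the screening analysis
#'
#' The cohort is partitioned into the four entry-age groups used for
#' age-specific PSA cut-offs: `<60`, `60-64`, `65-69`, `>=70`.
#'
#' @return Character vector of the four age-group labels, in order.
#' @export
age_group_levels <- function() c("<60", "60-64", "65-69", ">=70")

#' Assign entry ages to screening age groups
#'
#' @param age Numeric vector of ages in years.
#' @return Factor with levels [age_group_levels()].
#' @examples
#' assign_age_group(c(55, 62, 68, 74))
#' @export
assign_age_group <- function(age) {
  stopifnot(is.numeric(age))
  cut(age,
    breaks = c(-Inf, 60, 65, 70, Inf), right = FALSE,
    labels = age_group_levels()
  )
}

# shared input checks ---------------------------------------------------------

check_binary <- function(x, name) {
  if (anyNA(x) || !all(x %in% c(0, 1, FALSE, TRUE))) {
    abort(sprintf("`%s` must be 0/1 with no missing values.", name))
  }
  as.integer(x)
}

check_both_classes <- function(y) {
  if (length(unique(y)) < 2L) {
    abort("Both cases and controls must be present.")
  }
  invisible(y)
}
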