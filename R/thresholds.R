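# Threshold tables: per-zone mean +/- sd cutpoints and the three-level
# discretization they induce.

validate_thresholds <- function(thresholds) {
  required <- c("zone", "attribute", "low_cut", "high_cut")
  missing_cols <- setdiff(required, names(thresholds))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("threshold table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (any(is.na(thresholds$low_cut)) || any(is.na(thresholds$high_cut))) {
    bad <- thresholds$attribute[is.na(thresholds$low_cut) | is.na(thresholds$high_cut)]
    rlang::abort(paste0("missing cutpoint(s) for attribute(s): ",
                        paste(unique(bad), collapse = ", ")))
  }
  bad <- thresholds$low_cut > thresholds$high_cut
  if (any(bad)) {
    rlang::abort(paste0("invalid threshold table: low_cut > high_cut for ",
                        paste(unique(thresholds$attribute[bad]), collapse = ", ")))
  }
  invisible(thresholds)
}

#' Compute per-zone discretization thresholds
#'
#' For every attribute of every zone, the cutpoints are mean - sd and
#' mean + sd over that zone's monthly records (sample sd, n - 1 denominator).
#' Values at or below `low_cut` are "low", at or above `high_cut` "high",
#' strictly in between "medium".
#'
#' @param records Tibble of monthly records with columns `zone` and the
#'   attribute columns (`Tmin`, `Tmax`, ..., `yield_kg_ha`). Attributes absent
#'   from the table are skipped.
#' @param zone Optional zone name(s) to restrict to.
#' @return Threshold tibble: `zone`, `attribute`, `low_cut`, `high_cut`.
#' @seealso [discretize()], [benin_thresholds()]
#' @export
compute_thresholds <- function(records, zone = NULL) {
  if (!is.null(zone)) {
    records <- dplyr::filter(records, .data$zone %in% !!zone)
    if (nrow(records) == 0) rlang::abort(paste0("no records for zone ", zone))
  }
  attrs <- all_attributes()[attribute_column(all_attributes()) %in% names(records)]
  counts <- dplyr::count(records, .data$zone)
  if (any(counts$n < 2)) {
    rlang::abort(paste0("standard deviation undefined: zone(s) with a single record: ",
                        paste(counts$zone[counts$n < 2], collapse = ", ")))
  }
  records |>
    dplyr::select("zone", dplyr::all_of(attribute_column(attrs))) |>
    tidyr::pivot_longer(-"zone", names_to = "attribute", values_to = "value") |>
    dplyr::mutate(attribute = ifelse(.data$attribute == "yield_kg_ha", "Yield",
                                     .data$attribute)) |>
    dplyr::summarise(
      low_cut = mean(.data$value) - stats::sd(.data$value),
      high_cut = mean(.data$value) + stats::sd(.data$value),
      .by = c("zone", "attribute")
    )
}

#' Discretize values into low / medium / high
#'
#' Cutpoints belong to the extreme categories: `value <= low_cut` is "low",
#' `value >= high_cut` is "high", the medium band is open on both sides.
#' For a degenerate table with `low_cut == high_cut`, "low" wins (<= is
#' tested before >=).
#'
#' @param value Numeric vector.
#' @param low_cut,high_cut Cutpoints, `low_cut <= high_cut` (recycled).
#' @return Character vector in `c("low", "medium", "high")`.
#' @examples
#' discretize(c(2.5, 3.009, 4, 6.585), 3.009, 6.585)
#' @export
discretize <- function(value, low_cut, high_cut) {
  if (any(is.na(value))) {
    rlang::abort("missing value passed to discretize(); exclude or impute upstream")
  }
  if (any(low_cut > high_cut)) rlang::abort("low_cut must be <= high_cut")
  dplyr::case_when(
    value <= low_cut ~ "low",
    value >= high_cut ~ "high",
    .default = "medium"
  )
}

#' Recover a zone climate profile from a threshold table
#'
#' Inverts the mean +/- sd construction: per attribute,
#' `mean = (low_cut + high_cut) / 2` and `sd = (high_cut - low_cut) / 2`.
#' Together with [thresholds_from_profile()] this is an exact round trip.
#'
#' @param thresholds Threshold tibble (`zone`, `attribute`, `low_cut`,
#'   `high_cut`).
#' @return Profile tibble: `zone`, `attribute`, `mean`, `sd`.
#' @examples
#' profile_from_thresholds(benin_thresholds())
#' @export
profile_from_thresholds <- function(thresholds) {
  validate_thresholds(thresholds)
  thresholds |>
    dplyr::transmute(
      .data$zone, .data$attribute,
      mean = (.data$low_cut + .data$high_cut) / 2,
      sd = (.data$high_cut - .data$low_cut) / 2
    )
}

#' Threshold table implied by a zone climate profile
#'
#' @param profile Profile tibble (`zone`, `attribute`, `mean`, `sd`).
#' @return Threshold tibble with `low_cut = mean - sd`, `high_cut = mean + sd`.
#' @export
thresholds_from_profile <- function(profile) {
  if (any(profile$sd < 0)) rlang::abort("profile sd must be nonnegative")
  profile |>
    dplyr::transmute(
      .data$zone, .data$attribute,
      low_cut = .data$mean - .data$sd,
      high_cut = .data$mean + .data$sd
    )
}
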