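# Attribute vocabulary shared across the package.
#
# Climate predictors are station-month means; "Yield" is the monthly crop
# yield category. The yield column in record tables is `yield_kg_ha`; the
# threshold/transaction attribute name is "Yield".

climate_attributes <- function() c("Tmin", "Tmax", "Umin", "Umax", "RR", "Sun", "ET")

all_attributes <- function() c(climate_attributes(), "Yield")

# Fixed keep-priority used to break ties when the correlation filter must
# choose which member of a redundant pair to drop (earlier = kept).
drop_priority <- function() c("Tmin", "Tmax", "Umax", "Umin", "RR", "Sun", "ET")

# Physical truncation bounds per attribute: rainfall, sunshine,
# evapotranspiration and yield are nonnegative, relative humidities live in
# [0, 100], temperatures are unbounded.
attribute_bounds <- function(attribute) {
  stopifnot(is.character(attribute))
  lower <- c(
    Tmin = -Inf, Tmax = -Inf, Umin = 0, Umax = 0,
    RR = 0, Sun = 0, ET = 0, Yield = 0
  )
  upper <- c(
    Tmin = Inf, Tmax = Inf, Umin = 100, Umax = 100,
    RR = Inf, Sun = Inf, ET = Inf, Yield = Inf
  )
  unknown <- setdiff(attribute, names(lower))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown attribute(s): ", paste(unknown, collapse = ", ")))
  }
  tibble::tibble(attribute = attribute,
                 lower = unname(lower[attribute]),
                 upper = unname(upper[attribute]))
}

# Column name in a records tibble holding a given attribute.
attribute_column <- function(attribute) {
  ifelse(attribute == "Yield", "yield_kg_ha", attribute)
}

#' Published zone threshold tables for Benin
#'
#' Mean +/- standard-deviation cutpoints separating "low", "medium" and
#' "high" categories of the monthly climate attributes and monthly tomato
#' yield in the three agro-ecological zones of Benin (Sudanian,
#' Sudano-Guinean, Guinean), as computed from 26 years (1995-2020) of
#' synoptic-station records. A value v is "low" when v <= low_cut, "high"
#' when v >= high_cut, and "medium" strictly in between.
#'
#' @return A tibble with columns `zone`, `attribute`, `low_cut`, `high_cut`;
#'   one row per zone x attribute (7 attributes: Sun, ET, RR, Tmax, Tmin,
#'   Umax, Yield).
#' @examples
#' benin_thresholds()
#' @export
benin_thresholds <- function() {
  sudanian <- tibble::tribble(
    ~attribute, ~low_cut, ~high_cut,
    "Sun",      6.727,    9.157,
    "ET",       3.009,    6.585,
    "RR",       0.109,    0.323,
    "Tmax",    31.733,   37.793,
    "Tmin",    19.024,   25.120,
    "Umax",    52.850,   94.264,
    "Yield",  192.671,  689.989
  )
  sudano_guinean <- tibble::tribble(
    ~attribute, ~low_cut, ~high_cut,
    "Sun",      4.664,    7.994,
    "ET",       2.387,    3.887,
    "RR",       4.504,    8.347,
    "Tmax",    31.079,   36.545,
    "Tmin",    21.968,   23.825,
    "Umax",    88.161,   95.710,
    "Yield",  208.159,  322.760
  )
  guinean <- tibble::tribble(
    ~attribute, ~low_cut, ~high_cut,
    "Sun",      4.664,    7.528,
    "ET",       1.971,    2.673,
    "RR",       1.331,    3.250,
    "Tmax",    29.214,   32.282,
    "Tmin",    24.424,   26.213,
    "Umax",    90.036,   93.962,
    "Yield", 1739.144, 3618.280
  )
  dplyr::bind_rows(
    dplyr::mutate(sudanian, zone = "Sudanian", .before = 1),
    dplyr::mutate(sudano_guinean, zone = "Sudano-Guinean", .before = 1),
    dplyr::mutate(guinean, zone = "Guinean", .before = 1)
  )
}
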