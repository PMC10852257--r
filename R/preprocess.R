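# Pre-processing: daily -> monthly aggregation, yield disaggregation,
# correlation filter, transaction encoding.

#' Aggregate daily climate records to monthly means
#'
#' One output record per (zone, year, month), each attribute the arithmetic
#' mean over that month's available days. Days with a missing value for an
#' attribute are ignored for that attribute; a month with no usable day for
#' some attribute is dropped with a warning.
#'
#' @param daily Tibble with columns `zone`, `date` (Date or parseable
#'   string), and numeric climate attribute columns.
#' @return Monthly records tibble: `zone`, `year`, `month`, attributes.
#' @export
aggregate_daily_to_monthly <- function(daily) {
  required <- c("zone", "date")
  missing_cols <- setdiff(required, names(daily))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("daily records lack column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  attrs <- intersect(climate_attributes(), names(daily))
  for (a in attrs) {
    if (!is.numeric(daily[[a]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(daily[[a]]))))[1]
      rlang::abort(paste0("non-numeric values in attribute ", a,
                          " (first offending row: ", bad, ")"))
    }
  }
  date <- as.Date(daily$date)
  monthly <- daily |>
    dplyr::mutate(year = as.integer(format(date, "%Y")),
                  month = as.integer(format(date, "%m"))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(attrs), ~ mean(.x, na.rm = TRUE)),
                     .by = c("zone", "year", "month")) |>
    dplyr::arrange(.data$zone, .data$year, .data$month)
  empty <- monthly |>
    dplyr::filter(dplyr::if_any(dplyr::all_of(attrs), is.nan))
  if (nrow(empty) > 0) {
    rlang::warn(paste0("dropping ", nrow(empty),
                       " month(s) with no usable daily values"))
    monthly <- dplyr::anti_join(monthly, empty, by = c("zone", "year", "month"))
  }
  monthly
}

#' Attach disaggregated monthly yield to climate records
#'
#' The average monthly yield is the annual yield divided by 12, constant
#' over the year's months.
#'
#' @param monthly Monthly records tibble (`zone`, `year`, `month`, ...).
#' @param annual_yields Tibble `zone`, `year`, `annual_yield_kg_ha`.
#' @return `monthly` with a `yield_kg_ha` column appended.
#' @export
attach_monthly_yield <- function(monthly, annual_yields) {
  joined <- dplyr::left_join(monthly, annual_yields, by = c("zone", "year"))
  if (any(is.na(joined$annual_yield_kg_ha))) {
    missing_keys <- joined |>
      dplyr::filter(is.na(.data$annual_yield_kg_ha)) |>
      dplyr::distinct(.data$zone, .data$year)
    rlang::abort(paste0(
      "no annual yield for (zone, year): ",
      paste(missing_keys$zone, missing_keys$year, sep = "/", collapse = ", ")
    ))
  }
  joined |>
    dplyr::mutate(yield_kg_ha = .data$annual_yield_kg_ha / 12) |>
    dplyr::select(-"annual_yield_kg_ha")
}

#' Drop highly correlated predictors
#'
#' Pearson correlations among climate predictors are computed on the pooled
#' (all-zone) monthly records. From every pair with |r| above the threshold
#' one member is dropped: the variable involved in more above-threshold
#' pairs goes first, ties broken by a fixed keep-priority
#' (Tmin > Tmax > Umax > Umin > RR > Sun > ET, earlier kept). The yield
#' response is never considered for dropping. Zero-variance predictors get
#' undefined correlations, a warning, and are retained.
#'
#' @param records Monthly records tibble.
#' @param threshold Correlation magnitude above which a pair is redundant,
#'   in (0, 1); default 0.8.
#' @return A list of class `"correlation_filter"`: `retained` and `dropped`
#'   predictor names and the full correlation `matrix`.
#' @export
correlation_filter <- function(records, threshold = 0.8) {
  if (threshold <= 0 || threshold >= 1) rlang::abort("threshold must be in (0, 1)")
  if (nrow(records) < 3) rlang::abort("need at least 3 records")
  predictors <- intersect(climate_attributes(), names(records))
  X <- as.matrix(records[predictors])
  zero_var <- apply(X, 2, stats::sd) == 0
  if (any(zero_var)) {
    rlang::warn(paste0("zero-variance predictor(s) retained, correlations undefined: ",
                       paste(predictors[zero_var], collapse = ", ")))
  }
  cmat <- suppressWarnings(stats::cor(X))
  priority <- drop_priority()

  retained <- predictors
  dropped <- character(0)
  repeat {
    sub <- abs(cmat[retained, retained, drop = FALSE])
    diag(sub) <- 0
    sub[is.na(sub)] <- 0
    counts <- rowSums(sub > threshold)
    if (all(counts == 0)) break
    worst <- names(counts)[counts == max(counts)]
    # drop the tied variable with the lowest keep-priority
    victim <- worst[which.max(match(worst, priority))]
    dropped <- c(dropped, victim)
    retained <- setdiff(retained, victim)
  }
  structure(
    list(retained = retained, dropped = dropped, matrix = cmat,
         threshold = threshold),
    class = "correlation_filter"
  )
}

#' @export
print.correlation_filter <- function(x, ...) {
  cat("Correlation filter (|r| > ", x$threshold, ")\n", sep = "")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  cat("  dropped: ", if (length(x$dropped)) paste(x$dropped, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Encode monthly records as transactions
#'
#' One transaction per record; items are `"attribute=category"` strings
#' obtained by discretizing each retained attribute (plus yield) with the
#' record's zone thresholds.
#'
#' @param records Monthly records tibble with `yield_kg_ha`.
#' @param thresholds Threshold table covering every zone present.
#' @param attributes Predictor attributes to encode; default all climate
#'   attributes present in `records` and covered by `thresholds` (pass a
#'   correlation filter's `retained` to restrict further). `"Yield"` is
#'   always encoded.
#' @return Tibble `zone`, `year`, `month`, `items` (list-column of character
#'   item vectors, one item per encoded attribute).
#' @export
to_transactions <- function(records, thresholds,
                            attributes = intersect(
                              intersect(climate_attributes(), names(records)),
                              thresholds$attribute)) {
  validate_thresholds(thresholds)
  attrs <- union(attributes, "Yield")
  missing_zone <- setdiff(unique(records$zone), unique(thresholds$zone))
  if (length(missing_zone) > 0) {
    rlang::abort(paste0("no threshold table for zone(s): ",
                        paste(missing_zone, collapse = ", ")))
  }
  items_mat <- matrix(NA_character_, nrow = nrow(records), ncol = length(attrs))
  for (j in seq_along(attrs)) {
    attr <- attrs[j]
    th <- thresholds[thresholds$attribute == attr, c("zone", "low_cut", "high_cut")]
    missing_th <- setdiff(unique(records$zone), th$zone)
    if (length(missing_th) > 0) {
      rlang::abort(paste0("thresholds for attribute ", attr, " missing in zone(s): ",
                          paste(missing_th, collapse = ", ")))
    }
    idx <- match(records$zone, th$zone)
    cat <- discretize(records[[attribute_column(attr)]],
                      th$low_cut[idx], th$high_cut[idx])
    items_mat[, j] <- paste0(attr, "=", cat)
  }
  tibble::tibble(
    zone = records$zone, year = records$year, month = records$month,
    items = lapply(seq_len(nrow(records)), function(i) items_mat[i, ])
  )
}
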