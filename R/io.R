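# Readers and writers for the package's plain-text formats.
# CSV dialect is fixed: comma separator, header row, dot decimal, UTF-8, LF.

climate_col_types <- function(daily) {
  if (daily) {
    readr::cols(zone = readr::col_character(), date = readr::col_date(),
                .default = readr::col_double())
  } else {
    readr::cols(zone = readr::col_character(), year = readr::col_integer(),
                month = readr::col_integer(), .default = readr::col_double())
  }
}

#' Read a climate CSV
#'
#' Accepts either monthly records (`zone,year,month,Tmin,...,ET[,yield_kg_ha]`)
#' or daily records (`zone,date,Tmin,...,ET`); the presence of a `date`
#' column selects the daily schema.
#'
#' @param path File path.
#' @return A records tibble.
#' @export
read_climate_csv <- function(path) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  readr::read_csv(path, col_types = climate_col_types("date" %in% header),
                  progress = FALSE)
}

#' Write a climate CSV
#' @param records Records tibble (monthly or daily).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_climate_csv <- function(records, path) {
  readr::write_csv(records, path, eol = "\n")
  invisible(path)
}

#' Read / write annual-yield CSV (`zone,year,annual_yield_kg_ha`)
#' @param path File path.
#' @return A tibble.
#' @export
read_annual_yields_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    zone = readr::col_character(), year = readr::col_integer(),
    annual_yield_kg_ha = readr::col_double()
  ), progress = FALSE)
}

#' @rdname read_annual_yields_csv
#' @param yields Tibble `zone`, `year`, `annual_yield_kg_ha`.
#' @export
write_annual_yields_csv <- function(yields, path) {
  readr::write_csv(yields, path, eol = "\n")
  invisible(path)
}

#' Read / write a threshold table CSV (`zone,attribute,low_cut,high_cut`)
#' @param path File path.
#' @return Threshold tibble.
#' @export
read_thresholds_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    zone = readr::col_character(), attribute = readr::col_character(),
    low_cut = readr::col_double(), high_cut = readr::col_double()
  ), progress = FALSE)
}

#' @rdname read_thresholds_csv
#' @param thresholds Threshold tibble.
#' @export
write_thresholds_csv <- function(thresholds, path) {
  readr::write_csv(thresholds, path, eol = "\n")
  invisible(path)
}

#' Read / write basket-format transaction files
#'
#' One transaction per line, items whitespace-separated.
#'
#' @param path File path.
#' @return `read_baskets()`: a list of character item vectors.
#' @export
read_baskets <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  strsplit(lines, "[[:space:]]+")
}

#' @rdname read_baskets
#' @param transactions List of item vectors or tibble with `items`
#'   list-column.
#' @export
write_baskets <- function(transactions, path) {
  tx <- normalize_transactions(transactions)
  readr::write_lines(vapply(tx, paste, character(1), collapse = " "), path)
  invisible(path)
}

#' Write frequent itemsets as CSV (`items,support_count,support`)
#'
#' Items are sorted ascending and joined by ";".
#'
#' @param itemsets `"fp_itemsets"` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_itemsets_csv <- function(itemsets, path) {
  itemsets |>
    dplyr::transmute(items = .data$itemset, .data$support_count, .data$support) |>
    readr::write_csv(path, eol = "\n")
  invisible(path)
}

#' Write a rule table as CSV
#'
#' Columns `antecedents,consequent,support,confidence,lift`; antecedents
#' ";"-joined in sorted order, metrics formatted with 3 decimals.
#'
#' @param rules Rule tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_rules_csv <- function(rules, path) {
  rules |>
    dplyr::transmute(
      .data$antecedents, .data$consequent,
      support = sprintf("%.3f", .data$support),
      confidence = sprintf("%.3f", .data$confidence),
      lift = sprintf("%.3f", .data$lift)
    ) |>
    readr::write_csv(path, eol = "\n")
  invisible(path)
}
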