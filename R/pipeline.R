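# End-to-end orchestration: (aggregate ->) attach yield -> correlation
# filter -> per-zone thresholds -> transactions -> FP-Growth -> rules.

#' Pipeline configuration
#'
#' Defaults are the reference settings of the analysis: minimum support 0.2,
#' confidence 0.8, lift 1, at least three antecedents, top five rules,
#' correlation threshold 0.8, consequent the high-yield category.
#'
#' @param zones Optional character vector restricting the zones mined.
#' @param min_support Fractional minimum support in (0, 1\].
#' @param min_confidence Confidence floor in \[0, 1\].
#' @param min_lift Lift floor >= 0.
#' @param min_antecedents Minimum antecedent size >= 1.
#' @param top_k Rules kept per zone, >= 0.
#' @param correlation_threshold Redundancy threshold in (0, 1).
#' @param consequent Consequent item mined for.
#' @return A `"run_config"` list.
#' @export
run_config <- function(zones = NULL, min_support = 0.2, min_confidence = 0.8,
                       min_lift = 1, min_antecedents = 3L, top_k = 5L,
                       correlation_threshold = 0.8, consequent = "Yield=high") {
  stopifnot(min_support > 0, min_support <= 1,
            min_confidence >= 0, min_confidence <= 1,
            min_lift >= 0, min_antecedents >= 1, top_k >= 0,
            correlation_threshold > 0, correlation_threshold < 1)
  structure(
    list(zones = zones, min_support = min_support,
         min_confidence = min_confidence, min_lift = min_lift,
         min_antecedents = as.integer(min_antecedents),
         top_k = as.integer(top_k),
         correlation_threshold = correlation_threshold,
         consequent = consequent),
    class = "run_config"
  )
}

zone_slug <- function(zone) gsub("[^A-Za-z0-9]+", "_", zone)

#' Run the full climate-yield rule-mining pipeline
#'
#' Steps: read inputs (daily climate is aggregated to monthly means; annual
#' yields, when given, are disaggregated to monthly yield), drop redundant
#' predictors with the pooled correlation filter, compute per-zone mean +/-
#' sd thresholds, encode transactions, mine frequent itemsets per zone with
#' FP-Growth at the configured support, score rules toward the configured
#' consequent and keep the filtered top k per zone. The run is fully
#' deterministic given its inputs.
#'
#' @param climate Monthly or daily records tibble, or path to a climate CSV.
#' @param annual_yields Optional annual-yield tibble or CSV path; when
#'   absent, `climate` must already carry `yield_kg_ha`.
#' @param config A [run_config()].
#' @param thresholds Optional threshold table (e.g. [benin_thresholds()] or
#'   the table a rule was planted with); by default thresholds are computed
#'   from the records via [compute_thresholds()].
#' @param out_dir Optional directory; when given, writes `thresholds.csv`,
#'   per-zone `transactions_<zone>.txt`, `itemsets_<zone>.csv`,
#'   `rules_<zone>.csv` and a `manifest.csv` of MD5 file hashes.
#' @return An `"agrorules_run"` list: `config`, `records`, `cor_filter`,
#'   `thresholds`, `transactions`, `itemsets` (per-zone named list), `rules`
#'   (all scored rules, per zone), `selected` (filtered top-k per zone),
#'   `manifest` (or NULL).
#' @examples
#' prof <- profile_from_thresholds(benin_thresholds())
#' rec <- generate_monthly_records(prof, 2000, 2005, seed = 7)
#' run <- run_pipeline(rec, config = run_config(min_antecedents = 1))
#' tidy(run)
#' @export
run_pipeline <- function(climate, annual_yields = NULL, config = run_config(),
                         thresholds = NULL, out_dir = NULL) {
  if (is.character(climate)) climate <- read_climate_csv(climate)
  if (is.character(annual_yields)) annual_yields <- read_annual_yields_csv(annual_yields)
  if ("date" %in% names(climate)) climate <- aggregate_daily_to_monthly(climate)
  if (!is.null(annual_yields)) climate <- attach_monthly_yield(climate, annual_yields)
  if (!"yield_kg_ha" %in% names(climate)) {
    rlang::abort("records carry no yield_kg_ha column and no annual yields were given")
  }
  if (!is.null(config$zones)) {
    climate <- dplyr::filter(climate, .data$zone %in% config$zones)
  }
  zone_n <- dplyr::count(climate, .data$zone)
  small <- zone_n$zone[zone_n$n < 2]
  if (length(small) > 0) {
    rlang::warn(paste0("skipping zone(s) with < 2 records: ",
                       paste(small, collapse = ", ")))
    climate <- dplyr::filter(climate, !.data$zone %in% small)
  }
  if (nrow(climate) == 0) rlang::abort("no zone with enough records")

  cf <- correlation_filter(climate, config$correlation_threshold)
  if (is.null(thresholds)) thresholds <- compute_thresholds(climate)
  transactions <- to_transactions(climate, thresholds, attributes = cf$retained)

  zones <- unique(climate$zone)
  per_zone <- purrr::map(zones, function(z) {
    tx <- transactions[transactions$zone == z, ]
    itemsets <- fp_growth(tx$items, min_support = config$min_support)
    rules <- generate_rules(itemsets, config$consequent)
    selected <- rules |>
      filter_rules(config$min_confidence, config$min_lift, config$min_antecedents) |>
      rank_top_k(config$top_k)
    list(itemsets = itemsets,
         rules = dplyr::mutate(rules, zone = z, .before = 1),
         selected = dplyr::mutate(selected, zone = z, .before = 1))
  })
  names(per_zone) <- zones

  res <- structure(
    list(config = config, records = climate, cor_filter = cf,
         thresholds = thresholds, transactions = transactions,
         itemsets = purrr::map(per_zone, "itemsets"),
         rules = dplyr::bind_rows(purrr::map(per_zone, "rules")),
         selected = dplyr::bind_rows(purrr::map(per_zone, "selected")),
         manifest = NULL),
    class = "agrorules_run"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    p <- file.path(out_dir, "thresholds.csv")
    write_thresholds_csv(thresholds, p); files <- c(files, p)
    for (z in zones) {
      slug <- zone_slug(z)
      p <- file.path(out_dir, paste0("transactions_", slug, ".txt"))
      write_baskets(transactions[transactions$zone == z, ], p); files <- c(files, p)
      p <- file.path(out_dir, paste0("itemsets_", slug, ".csv"))
      write_itemsets_csv(per_zone[[z]]$itemsets, p); files <- c(files, p)
      p <- file.path(out_dir, paste0("rules_", slug, ".csv"))
      write_rules_csv(per_zone[[z]]$selected, p); files <- c(files, p)
    }
    manifest <- tibble::tibble(
      file = basename(files),
      md5 = unname(tools::md5sum(files))
    )
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"), eol = "\n")
    res$manifest <- manifest
  }
  res
}

#' @export
print.agrorules_run <- function(x, ...) {
  zones <- unique(x$records$zone)
  cat("Climate-yield rule mining run\n")
  cat("  zones:       ", paste(zones, collapse = ", "), "\n")
  cat("  records:     ", nrow(x$records), "\n")
  cat("  predictors:  ", paste(x$cor_filter$retained, collapse = ", "),
      if (length(x$cor_filter$dropped))
        paste0(" (dropped: ", paste(x$cor_filter$dropped, collapse = ", "), ")"),
      "\n", sep = "")
  cat("  min support ", x$config$min_support,
      ", confidence >= ", x$config$min_confidence,
      ", lift >= ", x$config$min_lift,
      ", |antecedent| >= ", x$config$min_antecedents, "\n", sep = "")
  cat("  selected rules:", nrow(x$selected), "\n")
  if (nrow(x$selected) > 0) print(x$selected, n = 15)
  invisible(x)
}

#' Tidy the selected rules of a pipeline run
#'
#' @param x An `"agrorules_run"`.
#' @param ... Unused.
#' @return Tibble of the filtered top-k rules per zone: `zone`,
#'   `antecedents`, `consequent`, `n_antecedents`, `support`, `confidence`,
#'   `lift`.
#' @method tidy agrorules_run
#' @export
tidy.agrorules_run <- function(x, ...) x$selected

#' One-row-per-zone summary of a pipeline run
#'
#' @param x An `"agrorules_run"`.
#' @param ... Unused.
#' @return Tibble: `zone`, `n_transactions`, `n_frequent_itemsets`,
#'   `n_rules`, `n_selected`.
#' @method glance agrorules_run
#' @export
glance.agrorules_run <- function(x, ...) {
  zones <- names(x$itemsets)
  tibble::tibble(
    zone = zones,
    n_transactions = vapply(zones, function(z)
      sum(x$transactions$zone == z), integer(1), USE.NAMES = FALSE),
    n_frequent_itemsets = vapply(zones, function(z)
      nrow(x$itemsets[[z]]), integer(1), USE.NAMES = FALSE),
    n_rules = vapply(zones, function(z)
      sum(x$rules$zone == z), integer(1), USE.NAMES = FALSE),
    n_selected = vapply(zones, function(z)
      sum(x$selected$zone == z), integer(1), USE.NAMES = FALSE)
  )
}

#' Plot rule metrics of a pipeline run
#'
#' Scatter of support versus confidence for every scored rule, sized by
#' lift, faceted by zone; the selected rules are highlighted.
#'
#' @param object An `"agrorules_run"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot agrorules_run
#' @export
autoplot.agrorules_run <- function(object, ...) {
  rules <- dplyr::mutate(object$rules, selected = paste(
    .data$zone, .data$antecedents) %in%
      paste(object$selected$zone, object$selected$antecedents))
  ggplot2::ggplot(rules, ggplot2::aes(x = .data$support, y = .data$confidence,
                                      size = .data$lift,
                                      colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$zone)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "#b2182b"),
                                 name = "selected") +
    ggplot2::labs(x = "support", y = "confidence", size = "lift",
                  title = "Association rules toward the high-yield category")
}

#' Plot a zone threshold table
#'
#' Low/medium/high bands per attribute, one panel per attribute, coloured by
#' zone.
#'
#' @param thresholds Threshold tibble.
#' @return A ggplot object.
#' @export
plot_thresholds <- function(thresholds) {
  ggplot2::ggplot(thresholds,
                  ggplot2::aes(y = .data$zone, xmin = .data$low_cut,
                               xmax = .data$high_cut, colour = .data$zone)) +
    ggplot2::geom_linerange(linewidth = 3, alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(x = .data$low_cut)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$high_cut)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$attribute), scales = "free_x") +
    ggplot2::labs(x = "value", y = NULL,
                  title = "Medium band (mean ± sd) per attribute and zone") +
    ggplot2::theme(legend.position = "none")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
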