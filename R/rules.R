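# Association rules from frequent itemsets: support / confidence / lift
# scoring, threshold filtering, top-k selection.
#
# For a rule X => Y over N transactions:
#   support    = Frequency(X u Y) / N
#   confidence = Frequency(X u Y) / Frequency(X)
#   lift       = support / (support(X) * support(Y))
# Only single-item consequents are generated; the pipeline mines rules whose
# consequent is the high-yield category.

#' Generate rules with a fixed single-item consequent
#'
#' For every frequent itemset Z containing `consequent`, emits the rule
#' (Z \\ consequent) => consequent, scored by support, confidence and lift.
#' Rules with an empty antecedent are not emitted. Downward closure
#' guarantees every needed subset count is present in `itemsets`.
#'
#' @param itemsets `"fp_itemsets"` tibble from [fp_growth()],
#'   [mine_fptree()] or [enumerate_bruteforce()].
#' @param consequent Single item label, e.g. `"Yield=high"`.
#' @param n_transactions Total transaction count N; defaults to the
#'   `n_transactions` attribute of `itemsets`.
#' @return Tibble: `antecedents` (";"-joined, sorted), `consequent`,
#'   `n_antecedents`, `support`, `confidence`, `lift`.
#' @export
generate_rules <- function(itemsets, consequent,
                           n_transactions = attr(itemsets, "n_transactions")) {
  if (length(consequent) != 1) rlang::abort("consequent must be a single item")
  if (is.null(n_transactions)) rlang::abort("n_transactions not supplied")
  counts <- stats::setNames(itemsets$support_count, itemsets$itemset)
  empty <- tibble::tibble(
    antecedents = character(0), consequent = character(0),
    n_antecedents = integer(0), support = numeric(0),
    confidence = numeric(0), lift = numeric(0)
  )
  if (!consequent %in% names(counts)) {
    rlang::warn(paste0("consequent item ", consequent,
                       " is not frequent; no rule can reach the support floor"))
    return(empty)
  }
  conseq_support <- counts[[consequent]] / n_transactions
  has_c <- purrr::map_lgl(itemsets$items, ~ consequent %in% .x)
  sizes <- lengths(itemsets$items)
  sel <- which(has_c & sizes >= 2)
  if (length(sel) == 0) return(empty)

  purrr::map(sel, function(i) {
    z_items <- itemsets$items[[i]]
    x_items <- setdiff(z_items, consequent)
    x_key <- paste(x_items, collapse = ";")
    conf <- itemsets$support_count[i] / counts[[x_key]]
    tibble::tibble(
      antecedents = x_key,
      consequent = consequent,
      n_antecedents = length(x_items),
      support = itemsets$support_count[i] / n_transactions,
      confidence = conf,
      lift = conf / conseq_support
    )
  }) |>
    dplyr::bind_rows()
}

#' Filter rules on confidence, lift and antecedent size
#'
#' Keeps exactly the rules with at least `min_antecedents` antecedent items,
#' confidence >= `min_confidence` and lift >= `min_lift` (all inclusive);
#' input order is preserved.
#'
#' @param rules Rule tibble from [generate_rules()].
#' @param min_confidence Confidence floor in \[0, 1\]; default 0.8.
#' @param min_lift Lift floor >= 0; default 1.
#' @param min_antecedents Minimum antecedent itemset size >= 1; default 3.
#' @return Filtered rule tibble.
#' @export
filter_rules <- function(rules, min_confidence = 0.8, min_lift = 1,
                         min_antecedents = 3) {
  stopifnot(min_confidence >= 0, min_confidence <= 1,
            min_lift >= 0, min_antecedents >= 1)
  dplyr::filter(
    rules,
    .data$n_antecedents >= min_antecedents,
    .data$confidence >= min_confidence,
    .data$lift >= min_lift
  )
}

#' Select the k most relevant rules
#'
#' Relevance order: confidence descending, then lift, then support, then
#' antecedent labels ascending — total and deterministic.
#'
#' @param rules Rule tibble.
#' @param k Number of rules to keep, >= 0; default 5.
#' @return The top `k` rules in relevance order.
#' @export
rank_top_k <- function(rules, k = 5) {
  stopifnot(k >= 0)
  rules |>
    dplyr::arrange(dplyr::desc(.data$confidence), dplyr::desc(.data$lift),
                   dplyr::desc(.data$support), .data$antecedents) |>
    utils::head(k)
}
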