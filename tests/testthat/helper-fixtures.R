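# Shared fixtures, all built in code.

# Classic 5-transaction toy database with hand-countable supports.
toy_db <- function() {
  list(c("a", "b"), c("b", "c"), c("a", "b", "c"), "b", c("a", "c"))
}

# Random small transaction database for property tests.
random_db <- function(n_items = sample(1:8, 1), n_tx = sample(1:40, 1)) {
  items <- letters[seq_len(n_items)]
  lapply(seq_len(n_tx), function(i) {
    k <- sample(0:n_items, 1)
    sort(sample(items, k))
  })
}

# Itemsets as a canonical "key:count" character vector for set comparison.
itemset_signature <- function(itemsets) {
  sort(paste0(itemsets$itemset, ":", itemsets$support_count))
}

# Build + mine in one step, reduced to a comparable signature.
fp_growth_sig <- function(tx, min_count) {
  tree <- build_fptree(tx, min_count)
  itemset_signature(mine_fptree(tree, min_count))
}

benin_profile <- function() profile_from_thresholds(benin_thresholds())

sudanian_profile <- function() {
  dplyr::filter(benin_profile(), zone == "Sudanian")
}

# One planted-rule Sudanian zone: 312 records, 1995-2020.
planted_sudanian <- function(seed = 11, plant_seed = 5,
                             support = 0.25, confidence = 1.0) {
  th <- benin_thresholds()
  rec <- generate_monthly_records(sudanian_profile(), 1995, 2020, seed = seed)
  plant_rule(rec, c("ET=low", "Tmin=medium", "Umax=high"), "Yield=high",
             target_support = support, target_confidence = confidence,
             thresholds = th, seed = plant_seed)
}
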