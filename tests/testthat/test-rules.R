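# Rule generation, metric identities, filtering, top-k ranking.

test_that("rules toward a fixed consequent carry hand-counted metrics", {
  its <- fp_growth(toy_db(), min_support = 0.4)
  rules <- generate_rules(its, "b")
  ab <- dplyr::filter(rules, antecedents == "a")
  expect_equal(ab$support, 0.4)            # count(a,b)/N = 2/5
  expect_equal(ab$confidence, 2 / 3)       # count(a,b)/count(a)
  expect_equal(ab$lift, (2 / 3) / (4 / 5)) # confidence / support(b)
  # no empty antecedents, consequent disjoint from antecedent
  expect_true(all(rules$n_antecedents >= 1))
  expect_false(any(grepl("(^|;)b($|;)", rules$antecedents)))
})

test_that("consequent in every transaction makes lift equal confidence", {
  tx <- list(c("a", "y"), c("b", "y"), c("a", "b", "y"), "y")
  its <- fp_growth(tx, 0.25)
  rules <- generate_rules(its, "y")
  expect_gt(nrow(rules), 0)
  expect_equal(rules$lift, rules$confidence)  # support(y) = 1
})

test_that("statistical independence gives lift exactly 1", {
  # count(x) = 2, count(y) = 2, count(x,y) = 1, N = 4 => 1/4 = (2/4)(2/4)
  tx <- list(c("x", "y"), "x", "y", "w")
  its <- enumerate_bruteforce(tx, 1)
  rules <- generate_rules(its, "y")
  xy <- dplyr::filter(rules, antecedents == "x")
  expect_equal(xy$lift, 1)
  expect_equal(xy$support, 0.25)
  expect_equal(xy$confidence, 0.5)
})

test_that("a non-frequent consequent yields an empty rule set with a warning", {
  its <- fp_growth(toy_db(), min_support = 0.4)
  expect_warning(rules <- generate_rules(its, "zzz"), "not frequent")
  expect_equal(nrow(rules), 0)
})

test_that("metric identities hold against brute-force recounts", {
  set.seed(17)
  for (rep in 1:10) {
    tx <- random_db(n_items = 6, n_tx = 30)
    n <- length(tx)
    its <- fp_growth(tx, 0.15)
    if (!"a" %in% its$itemset) next
    rules <- generate_rules(its, "a")
    count_of <- function(set) {
      sum(vapply(tx, function(t) all(set %in% unique(t)), logical(1)))
    }
    for (i in seq_len(nrow(rules))) {
      x_items <- strsplit(rules$antecedents[i], ";", fixed = TRUE)[[1]]
      expect_length(intersect(x_items, "a"), 0)
      cxy <- count_of(c(x_items, "a"))
      cx <- count_of(x_items)
      cy <- count_of("a")
      expect_equal(rules$support[i], cxy / n)
      expect_equal(rules$confidence[i], cxy / cx)
      expect_equal(rules$lift[i], (cxy / cx) / (cy / n), tolerance = 1e-9)
    }
  }
})

test_that("completeness: every derivable rule with the consequent is emitted once", {
  set.seed(23)
  tx <- random_db(n_items = 5, n_tx = 25)
  its <- enumerate_bruteforce(tx, 2)
  if ("a" %in% its$itemset) {
    rules <- generate_rules(its, "a")
    with_a <- its$items[vapply(its$items, function(s)
      "a" %in% s && length(s) > 1, logical(1))]
    expected <- sort(vapply(with_a, function(s)
      paste(setdiff(s, "a"), collapse = ";"), character(1)))
    expect_equal(sort(rules$antecedents), expected)
    expect_equal(anyDuplicated(rules$antecedents), 0)
    expect_true(all(rules$consequent == "a"))
  }
})

test_that("filter_rules applies inclusive thresholds on all three criteria", {
  rules <- tibble::tibble(
    antecedents = c("p;q", "p;q;r", "p;q;s", "p;q;t", "p;q;u"),
    consequent = "y",
    n_antecedents = c(2L, 3L, 3L, 3L, 3L),
    support = c(0.3, 0.3, 0.3, 0.3, 0.3),
    confidence = c(1, 0.8, 0.79, 1, 1),
    lift = c(2, 1, 2, 1, 0.99)
  )
  kept <- filter_rules(rules, min_confidence = 0.8, min_lift = 1,
                       min_antecedents = 3)
  # |X| = 2 removed; confidence 0.8 kept (inclusive); 0.79 removed;
  # lift 1 kept (inclusive); 0.99 removed
  expect_equal(kept$antecedents, c("p;q;r", "p;q;t"))
  expect_equal(nrow(filter_rules(rules[0, ])), 0)
})

test_that("rank_top_k orders by confidence, lift, support, then labels", {
  rules <- tibble::tibble(
    antecedents = c("b;c;d", "a;c;d", "a;b;c", "a;b;d", "a;b;e", "c;d;e"),
    consequent = "y",
    n_antecedents = 3L,
    support = c(0.30, 0.30, 0.25, 0.35, 0.20, 0.35),
    confidence = c(1, 1, 1, 0.9, 1, 0.9),
    lift = c(1.2, 1.2, 1.3, 1.4, 1.3, 1.4)
  )
  top <- rank_top_k(rules, 5)
  # conf 1 first; among them lift desc; then support desc; then label asc
  expect_equal(top$antecedents,
               c("a;b;c", "a;b;e", "a;c;d", "b;c;d", "a;b;d"))
  expect_equal(nrow(rank_top_k(rules, 0)), 0)
  expect_equal(nrow(rank_top_k(rules[1:2, ], 5)), 2)  # fewer than k
  # full tie broken by antecedent label
  tie <- rules[1:2, ] |> dplyr::mutate(support = 0.3)
  expect_equal(rank_top_k(tie, 2)$antecedents, c("a;c;d", "b;c;d"))
})
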