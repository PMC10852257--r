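# From-scratch FP-Growth: two-pass FP-tree construction and recursive
# conditional-tree mining, plus a levelwise Apriori enumerator used as an
# independent oracle in tests.
#
# Tree representation: parallel vectors inside an environment (item, count,
# parent), a per-node named child map, and a per-item header chain of node
# ids. Node 1 is the root (item NA).

new_fptree <- function(item_counts, n_transactions) {
  e <- new.env(parent = emptyenv())
  e$item <- NA_character_
  e$count <- 0
  e$parent <- 0L
  e$children <- list(integer(0))
  e$header <- stats::setNames(vector("list", length(item_counts)), names(item_counts))
  e$item_counts <- item_counts          # pass-1 supports, freq desc / label asc
  e$n_transactions <- n_transactions
  class(e) <- "fptree"
  e
}

fptree_insert <- function(tree, items, count) {
  node <- 1L
  for (it in items) {
    child <- tree$children[[node]][it]
    if (is.na(child)) {
      new_id <- length(tree$item) + 1L
      tree$item[new_id] <- it
      tree$count[new_id] <- count
      tree$parent[new_id] <- node
      tree$children[[new_id]] <- integer(0)
      kids <- tree$children[[node]]
      kids[it] <- new_id
      tree$children[[node]] <- kids
      tree$header[[it]] <- c(tree$header[[it]], new_id)
      node <- new_id
    } else {
      node <- unname(child)
      tree$count[node] <- tree$count[node] + count
    }
  }
  invisible(tree)
}

normalize_transactions <- function(transactions) {
  if (is.data.frame(transactions)) transactions <- transactions$items
  if (!is.list(transactions)) rlang::abort("transactions must be a list of item vectors")
  lapply(transactions, function(t) unique(as.character(t)))
}

# Core builder on weighted transactions (used for conditional trees too).
build_fptree_counted <- function(tx, weights, min_support_count) {
  counts <- tapply(rep(weights, lengths(tx)), unlist(tx), sum)
  counts <- counts[counts >= min_support_count]
  # global order: frequency descending, label ascending
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  tree <- new_fptree(counts, sum(weights))
  rank <- stats::setNames(seq_along(counts), names(counts))
  for (i in seq_along(tx)) {
    keep <- tx[[i]][tx[[i]] %in% names(rank)]
    if (length(keep) == 0) next
    keep <- keep[order(rank[keep])]
    fptree_insert(tree, keep, weights[i])
  }
  tree
}

#' Build an FP-tree
#'
#' Two passes over the transaction stream: pass 1 counts item frequencies
#' and discards items below `min_support_count`; pass 2 inserts each
#' transaction's surviving items, sorted by global frequency (descending,
#' ties by ascending label), sharing prefixes by incrementing counts.
#'
#' @param transactions A list of character item vectors, a tibble with an
#'   `items` list-column, or a zero-argument function returning the
#'   transaction list (called exactly once per pass, so callers can verify
#'   the two-pass contract).
#' @param min_support_count Minimum absolute support count, >= 1.
#' @return An `"fptree"` environment with fields `item`, `count`, `parent`,
#'   `children`, `header`, `item_counts`, `n_transactions`.
#' @seealso [mine_fptree()], [fp_growth()]
#' @export
build_fptree <- function(transactions, min_support_count) {
  if (min_support_count < 1) rlang::abort("min_support_count must be >= 1")
  reader <- if (is.function(transactions)) transactions else function() transactions
  tx1 <- normalize_transactions(reader())            # pass 1: item frequencies
  if (length(tx1) == 0) rlang::abort("empty transaction set")
  counts <- table(unlist(tx1))
  counts <- counts[counts >= min_support_count]
  ord <- order(-counts, names(counts))
  counts <- stats::setNames(as.numeric(counts)[ord], names(counts)[ord])
  tree <- new_fptree(counts, length(tx1))
  rank <- stats::setNames(seq_along(counts), names(counts))
  tx2 <- normalize_transactions(reader())            # pass 2: insertion
  for (t in tx2) {
    keep <- t[t %in% names(rank)]
    if (length(keep) == 0) next
    keep <- keep[order(rank[keep])]
    fptree_insert(tree, keep, 1)
  }
  tree
}

#' @export
print.fptree <- function(x, ...) {
  cat("FP-tree: ", length(x$item) - 1L, " nodes, ",
      length(x$item_counts), " frequent items over ",
      x$n_transactions, " transactions\n", sep = "")
  if (length(x$item_counts)) {
    cat("  header:", paste0(names(x$item_counts), "(", x$item_counts, ")",
                            collapse = " "), "\n")
  }
  invisible(x)
}

is_single_path <- function(tree) {
  all(lengths(tree$children) <= 1)
}

# Items (root-exclusive) along the path from a node up to the root.
path_to_root <- function(tree, node) {
  items <- character(0)
  node <- tree$parent[node]
  while (node > 1L) {
    items <- c(tree$item[node], items)
    node <- tree$parent[node]
  }
  items
}

mine_tree <- function(tree, suffix, min_support_count, acc) {
  items <- names(tree$item_counts)
  if (length(items) == 0) return(invisible())
  if (is_single_path(tree)) {
    # single path: every combination of path nodes is frequent with the
    # count of its deepest (least-counted) node
    node <- unname(tree$children[[1L]])
    path_items <- character(0)
    path_counts <- numeric(0)
    while (length(node) == 1L) {
      path_items <- c(path_items, tree$item[node])
      path_counts <- c(path_counts, tree$count[node])
      node <- unname(tree$children[[node]])
    }
    k <- length(path_items)
    for (mask in seq_len(2^k - 1)) {
      sel <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
      cnt <- min(path_counts[sel])
      if (cnt >= min_support_count) {
        acc$sets[[length(acc$sets) + 1L]] <-
          list(items = c(path_items[sel], suffix), count = cnt)
      }
    }
    return(invisible())
  }
  for (item in rev(items)) {           # ascending frequency
    acc$sets[[length(acc$sets) + 1L]] <-
      list(items = c(item, suffix), count = tree$item_counts[[item]])
    chain <- tree$header[[item]]
    base <- lapply(chain, path_to_root, tree = tree)
    weights <- tree$count[chain]
    keep <- lengths(base) > 0
    if (!any(keep)) next
    cond <- build_fptree_counted(base[keep], weights[keep], min_support_count)
    mine_tree(cond, c(item, suffix), min_support_count, acc)
  }
  invisible()
}

itemset_tibble <- function(sets, n_transactions) {
  items <- lapply(sets, function(s) sort(s$items))
  out <- tibble::tibble(
    items = items,
    itemset = vapply(items, paste, character(1), collapse = ";"),
    support_count = vapply(sets, function(s) as.integer(round(s$count)), integer(1))
  ) |>
    dplyr::arrange(dplyr::desc(.data$support_count), .data$itemset) |>
    dplyr::mutate(support = .data$support_count / n_transactions)
  attr(out, "n_transactions") <- n_transactions
  class(out) <- c("fp_itemsets", class(out))
  out
}

#' Mine all frequent itemsets from an FP-tree
#'
#' Recursive conditional-tree mining: for each header item in ascending
#' frequency, its conditional pattern base (prefix paths reached through the
#' node-link chain) is turned into a conditional FP-tree and mined with the
#' item appended to the suffix. Trees that collapse to a single path are
#' enumerated combinatorially.
#'
#' @param tree An `"fptree"` from [build_fptree()].
#' @param min_support_count Same count the tree was built with.
#' @return Tibble of class `"fp_itemsets"`: `items` (list-column, sorted),
#'   `itemset` (";"-joined key), `support_count`, `support`
#'   (`support_count / N`); attribute `n_transactions` carries N.
#' @export
mine_fptree <- function(tree, min_support_count) {
  acc <- new.env(parent = emptyenv())
  acc$sets <- list()
  mine_tree(tree, character(0), min_support_count, acc)
  itemset_tibble(acc$sets, tree$n_transactions)
}

#' Frequent itemsets by FP-Growth
#'
#' Convenience wrapper: converts a fractional minimum support into an
#' absolute count by `ceiling(min_support * N)`, builds the FP-tree and
#' mines it.
#'
#' @param transactions As in [build_fptree()].
#' @param min_support Fractional minimum support in (0, 1]; default 0.2.
#' @return As [mine_fptree()].
#' @examples
#' tx <- list(c("a", "b"), c("b", "c"), c("a", "b", "c"), "b", c("a", "c"))
#' fp_growth(tx, min_support = 0.4)
#' @export
fp_growth <- function(transactions, min_support = 0.2) {
  tx <- if (is.function(transactions)) transactions() else transactions
  tx <- normalize_transactions(tx)
  if (length(tx) == 0) rlang::abort("empty transaction set")
  min_count <- max(1L, as.integer(ceiling(min_support * length(tx))))
  tree <- build_fptree(tx, min_count)
  mine_fptree(tree, min_count)
}

#' Frequent itemsets by levelwise enumeration (Apriori oracle)
#'
#' Exhaustive levelwise search relying on downward closure: every candidate
#' of size k has all its (k-1)-subsets frequent. Intended as an independent
#' cross-check of [mine_fptree()] on small inputs; refuses inputs with more
#' than 25 distinct items.
#'
#' @inheritParams build_fptree
#' @return As [mine_fptree()] (same itemsets, same counts).
#' @export
enumerate_bruteforce <- function(transactions, min_support_count) {
  tx <- if (is.function(transactions)) transactions() else transactions
  tx <- normalize_transactions(tx)
  if (length(tx) == 0) rlang::abort("empty transaction set")
  if (min_support_count < 1) rlang::abort("min_support_count must be >= 1")
  universe <- sort(unique(unlist(tx)))
  if (length(universe) > 25) {
    rlang::abort("oracle refused: more than 25 distinct items")
  }
  count_of <- function(set) sum(vapply(tx, function(t) all(set %in% t), logical(1)))

  sets <- list()
  counts <- table(factor(unlist(tx), levels = universe))
  level <- lapply(universe[counts >= min_support_count], identity)
  for (s in level) sets[[length(sets) + 1L]] <- list(items = s, count = count_of(s))
  while (length(level) > 1) {
    keys <- vapply(level, paste, character(1), collapse = ";")
    nxt <- list()
    for (i in seq_along(level)) {
      for (j in seq_along(level)) {
        if (j <= i) next
        a <- level[[i]]; b <- level[[j]]
        k <- length(a)
        # classic join: equal prefixes, differing last item
        if (k > 1 && !identical(a[-k], b[-k])) next
        cand <- sort(union(a, b))
        if (length(cand) != k + 1) next
        # prune: all k-subsets must be frequent
        subs_ok <- all(vapply(seq_along(cand), function(d) {
          paste(cand[-d], collapse = ";") %in% keys
        }, logical(1)))
        if (!subs_ok) next
        cnt <- count_of(cand)
        if (cnt >= min_support_count) {
          nxt[[paste(cand, collapse = ";")]] <- cand
        }
      }
    }
    level <- unname(nxt)
    for (s in level) sets[[length(sets) + 1L]] <- list(items = s, count = count_of(s))
  }
  itemset_tibble(sets, length(tx))
}
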