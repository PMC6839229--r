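#' Apriori frequent-itemset mining on a binary matrix
#'
#' Level-wise Apriori: itemsets are grown one item at a time by joining
#' frequent (k-1)-itemsets that share a prefix, candidates with any
#' infrequent subset are pruned (anti-monotonicity), and the search stops
#' when a level produces no frequent extension. Supports are exact fractions
#' of transactions (samples) containing every item (gene) of the set.
#'
#' @param b Binary samples x genes matrix (transactions x items); see
#'   [as_binary_matrix()].
#' @param min_support Minimum support in (0, 1].
#' @return A data.frame of class \code{"itemset_set"} with list column
#'   \code{items} (sorted gene IDs) and numeric \code{support}, ordered by
#'   (itemset size, lexicographic items).
#' @examples
#' b <- toy_matrix()
#' apriori_frequent_itemsets(b, min_support = 0.6)
#' @export
apriori_frequent_itemsets <- function(b, min_support) {
  b <- as_binary_matrix(b)
  if (!is.numeric(min_support) || length(min_support) != 1L ||
      is.na(min_support) || min_support <= 0 || min_support > 1) {
    stop("min_support must be a single number in (0, 1]", call. = FALSE)
  }
  m <- nrow(b)
  if (m == 0L || ncol(b) == 0L) stop("empty matrix", call. = FALSE)

  ord <- order(colnames(b))
  cols <- colnames(b)[ord]
  logical_b <- b[, ord, drop = FALSE] == 1L
  # count threshold; tolerance guards fractions like 0.3*10
  min_count <- min_support * m - 1e-9

  items_out <- list()
  support_out <- numeric()

  counts1 <- colSums(logical_b)
  level <- unname(which(counts1 >= min_count))
  level_sets <- lapply(level, function(j) j)
  level_rows <- lapply(level, function(j) logical_b[, j])
  level_support <- counts1[level] / m

  while (length(level_sets) > 0L) {
    items_out <- c(items_out,
                   lapply(level_sets, function(ix) cols[ix]))
    support_out <- c(support_out, level_support)

    keys <- vapply(level_sets, paste, "", collapse = "\r")
    nxt_sets <- list(); nxt_rows <- list(); nxt_support <- numeric()
    k <- length(level_sets[[1L]])
    for (i in seq_along(level_sets)) {
      for (j in seq_along(level_sets)) {
        if (j <= i) next
        a <- level_sets[[i]]; d <- level_sets[[j]]
        # prefix join: identical first k-1 items, a's last < d's last
        if (k > 1L && !identical(a[seq_len(k - 1L)], d[seq_len(k - 1L)])) next
        cand <- c(a, d[k])
        if (cand[k] >= cand[k + 1L]) next
        # subset pruning: every k-subset must be frequent
        pruned <- FALSE
        if (k > 1L) {
          for (drop_pos in seq_len(k - 1L)) {
            if (!(paste(cand[-drop_pos], collapse = "\r") %in% keys)) {
              pruned <- TRUE; break
            }
          }
        }
        if (pruned) next
        rows <- level_rows[[i]] & logical_b[, cand[k + 1L]]
        cnt <- sum(rows)
        if (cnt >= min_count) {
          nxt_sets[[length(nxt_sets) + 1L]] <- cand
          nxt_rows[[length(nxt_rows) + 1L]] <- rows
          nxt_support <- c(nxt_support, cnt / m)
        }
      }
    }
    level_sets <- nxt_sets; level_rows <- nxt_rows; level_support <- nxt_support
  }

  sizes <- lengths(items_out)
  keys <- vapply(items_out, paste, "", collapse = "\r")
  o <- order(sizes, keys)
  out <- data.frame(support = support_out[o])
  out$items <- items_out[o]
  out <- out[, c("items", "support")]
  class(out) <- c("itemset_set", "data.frame")
  out
}

#' @export
print.itemset_set <- function(x, ...) {
  cat("Frequent itemsets:", nrow(x), "\n")
  if (nrow(x) > 0L) {
    df <- data.frame(
      items = vapply(x$items, paste, "", collapse = ","),
      support = round(x$support, 4)
    )
    print.data.frame(df, row.names = FALSE, ...)
  }
  invisible(x)
}

#' Generate association rules from frequent itemsets
#'
#' Splits each frequent itemset Z (|Z| >= 2) into every antecedent X and
#' consequent Y = Z \\ X with 1 <= |Y| <= \code{max_rhs}, and keeps rules
#' whose confidence support(Z)/support(X) reaches \code{min_confidence}.
#' Lift is confidence / support(Y); Y is itself frequent, so lift is always
#' defined. The \code{frequent} table must be the complete output of
#' [apriori_frequent_itemsets()] at the operative minimum support; supports
#' are recounted against \code{b} and a mismatch raises an integrity error.
#'
#' @param frequent An \code{itemset_set} from [apriori_frequent_itemsets()].
#' @param b The binary matrix the itemsets were mined from.
#' @param min_confidence Minimum confidence in (0, 1].
#' @param max_rhs Maximum consequent size (default 1, the classical
#'   single-consequent rule induction).
#' @return A [rule_set()] sorted by (support desc, confidence desc,
#'   lexicographic lhs, lexicographic rhs); \code{wcs} and \code{lamda3} are
#'   NA until scored.
#' @examples
#' b <- toy_matrix()
#' fi <- apriori_frequent_itemsets(b, 0.6)
#' generate_rules(fi, b, min_confidence = 0.8)
#' @export
generate_rules <- function(frequent, b, min_confidence, max_rhs = 1L) {
  stopifnot(inherits(frequent, "itemset_set"))
  b <- as_binary_matrix(b)
  if (!is.numeric(min_confidence) || length(min_confidence) != 1L ||
      is.na(min_confidence) || min_confidence <= 0 || min_confidence > 1) {
    stop("min_confidence must be a single number in (0, 1]", call. = FALSE)
  }
  if (max_rhs < 1L) stop("max_rhs must be >= 1", call. = FALSE)

  supp_of <- new.env(parent = emptyenv())
  logical_b <- b == 1L
  m <- nrow(b)
  for (i in seq_len(nrow(frequent))) {
    its <- frequent$items[[i]]
    recount <- mean(rowSums(logical_b[, its, drop = FALSE]) == length(its))
    if (abs(recount - frequent$support[i]) > 1e-9) {
      stop("integrity error: itemset {", paste(its, collapse = ","),
           "} has support ", recount, " in the matrix but ",
           frequent$support[i], " in the frequent table", call. = FALSE)
    }
    assign(paste(its, collapse = "\r"), frequent$support[i], envir = supp_of)
  }

  lhs <- list(); rhs <- list()
  supp <- conf <- lift <- numeric()
  for (i in seq_len(nrow(frequent))) {
    z <- frequent$items[[i]]
    nz <- length(z)
    if (nz < 2L) next
    sz <- frequent$support[i]
    # every nonempty proper subset of z as consequent, capped at max_rhs
    for (ysize in seq_len(min(max_rhs, nz - 1L))) {
      combos <- utils::combn(nz, ysize, simplify = FALSE)
      for (ix in combos) {
        y <- z[ix]; x <- z[-ix]
        sx <- get(paste(x, collapse = "\r"), envir = supp_of)
        cf <- sz / sx
        if (cf >= min_confidence - 1e-12) {
          sy <- get(paste(y, collapse = "\r"), envir = supp_of)
          lhs[[length(lhs) + 1L]] <- x
          rhs[[length(rhs) + 1L]] <- y
          supp <- c(supp, sz); conf <- c(conf, cf); lift <- c(lift, cf / sy)
        }
      }
    }
  }
  rules <- rule_set(lhs, rhs, support = supp, confidence = conf, lift = lift)
  sort_rules(rules)
}

## canonical rule order: support desc, confidence desc, lex lhs, lex rhs
sort_rules <- function(rules) {
  if (nrow(rules) == 0L) return(rules)
  lhs_key <- vapply(rules$lhs, paste, "", collapse = ",")
  rhs_key <- vapply(rules$rhs, paste, "", collapse = ",")
  o <- order(-rules$support, -rules$confidence, lhs_key, rhs_key)
  out <- rules[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rule_set", "data.frame")
  out
}

#' Mine association rules from a binary matrix in one call
#'
#' Convenience wrapper chaining [apriori_frequent_itemsets()] and
#' [generate_rules()].
#'
#' @inheritParams apriori_frequent_itemsets
#' @inheritParams generate_rules
#' @return A [rule_set()].
#' @export
mine_rules <- function(b, min_support = 0.3, min_confidence = 0.8,
                       max_rhs = 1L) {
  fi <- apriori_frequent_itemsets(b, min_support)
  generate_rules(fi, b, min_confidence, max_rhs)
}
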