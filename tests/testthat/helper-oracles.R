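# Independent brute-force oracles. These deliberately share no code with the
# package: itemset supports come from a full power-set scan and Lamda3 from a
# straight-line transcription of its defining formula.

# all frequent itemsets by exhaustive enumeration (<= ~15 genes)
oracle_frequent_itemsets <- function(b, min_support) {
  genes <- sort(colnames(b))
  m <- nrow(b)
  out_items <- list()
  out_support <- numeric()
  for (mask in seq_len(2^length(genes) - 1)) {
    members <- genes[bitwAnd(mask, 2^(seq_along(genes) - 1)) > 0]
    cnt <- sum(apply(b[, members, drop = FALSE] == 1, 1, all))
    if (cnt / m >= min_support - 1e-9) {
      out_items[[length(out_items) + 1]] <- members
      out_support <- c(out_support, cnt / m)
    }
  }
  o <- order(lengths(out_items),
             vapply(out_items, paste, "", collapse = "\r"))
  list(items = out_items[o], support = out_support[o])
}

# all rules from the oracle itemsets, any split with |Y| <= max_rhs
oracle_rules <- function(b, min_support, min_confidence, max_rhs = 1) {
  fi <- oracle_frequent_itemsets(b, min_support)
  key <- vapply(fi$items, paste, "", collapse = "\r")
  supp_of <- function(items) fi$support[key == paste(sort(items), collapse = "\r")]
  rows <- list()
  for (i in seq_along(fi$items)) {
    z <- fi$items[[i]]
    if (length(z) < 2) next
    # every nonempty proper subset as consequent
    for (mask in seq_len(2^length(z) - 2)) {
      y <- z[bitwAnd(mask, 2^(seq_along(z) - 1)) > 0]
      if (length(y) > max_rhs) next
      x <- setdiff(z, y)
      conf <- fi$support[i] / supp_of(x)
      if (conf >= min_confidence - 1e-12) {
        rows[[length(rows) + 1]] <- list(
          lhs = sort(x), rhs = sort(y), support = fi$support[i],
          confidence = conf, lift = conf / supp_of(y))
      }
    }
  }
  rows
}

# canonical string form of an oracle/package rule for set comparison
rule_key <- function(lhs, rhs, support, confidence, lift) {
  sprintf("%s=>%s|%.10f|%.10f|%.10f",
          paste(sort(lhs), collapse = ","), paste(sort(rhs), collapse = ","),
          support, confidence, lift)
}

package_rule_keys <- function(rules) {
  vapply(seq_len(nrow(rules)), function(i)
    rule_key(rules$lhs[[i]], rules$rhs[[i]], rules$support[i],
             rules$confidence[i], rules$lift[i]), "")
}

oracle_rule_keys <- function(rows) {
  vapply(rows, function(r)
    rule_key(r$lhs, r$rhs, r$support, r$confidence, r$lift), "")
}

# straight-line Lamda3 for a 1 -> 1 rule, directly from the definition
oracle_lamda3 <- function(a, c_, cont, bin, method = "pearson") {
  pval <- function(x, y) {
    if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) return(1)
    p <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE)$p.value)
    if (is.na(p)) return(1)
    min(max(p, 1e-300), 1)
  }
  in2 <- bin[, a] == 1 & bin[, c_] == 1
  in0 <- bin[, a] == 0 & bin[, c_] == 0
  others <- setdiff(colnames(cont), c(a, c_))
  if (sum(in2) < 3 || sum(in0) < 3 || length(others) < 1) return(NA_real_)
  p2_ac <- pval(cont[in2, a], cont[in2, c_])
  p0_ac <- pval(cont[in0, a], cont[in0, c_])
  p2 <- median(sapply(others, function(g) pval(cont[in2, a], cont[in2, g])))
  p0 <- median(sapply(others, function(g) pval(cont[in0, a], cont[in0, g])))
  denom <- log10(p2) + log10(p0)
  if (denom == 0) return(NA_real_)
  (log10(p2_ac) + log10(p0_ac)) / denom
}

# seeded random binary matrix with sample/gene labels
random_binary <- function(m, n, p = 0.4, seed) {
  withr::with_seed(seed, {
    b <- matrix(rbinom(m * n, 1, p), m, n,
                dimnames = list(sprintf("s%02d", 1:m), sprintf("G%02d", 1:n)))
    storage.mode(b) <- "integer"
    b
  })
}

# seeded random continuous + binary pair for Lamda3 equivalence checks;
# binary is thresholded so consistent partitions are usually >= 3
random_cont_bin <- function(m, n, seed) {
  withr::with_seed(seed, {
    cont <- matrix(rnorm(m * n), m, n,
                   dimnames = list(sprintf("s%02d", 1:m),
                                   sprintf("G%02d", 1:n)))
    bin <- (cont > quantile(cont, 0.4)) * 1L
    storage.mode(bin) <- "integer"
    dimnames(bin) <- dimnames(cont)
    list(cont = cont, bin = bin)
  })
}
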