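#' Partition samples by the joint binary state of a gene pair
#'
#' For a candidate rule gene pair (A, C), splits the samples into the three
#' groups the Lamda3 measure is built on: \code{both_one} (A and C both
#' dysregulated), \code{both_zero} (both unchanged) and \code{inconsistent}
#' (exactly one of the two altered). The consistent groups carry the signal;
#' the inconsistent group is reported for diagnostics but does not enter the
#' score.
#'
#' @param gene_a,gene_c Gene IDs present in \code{b}.
#' @param b Binary samples x genes matrix.
#' @return A list of class \code{"sample_partition"} with character vectors
#'   \code{both_one}, \code{inconsistent}, \code{both_zero} of sample IDs;
#'   disjoint, union = all samples.
#' @examples
#' partition_samples("NEK2", "CDKN3", toy_matrix())
#' @export
partition_samples <- function(gene_a, gene_c, b) {
  b <- as_binary_matrix(b)
  for (g in c(gene_a, gene_c)) {
    if (!g %in% colnames(b)) {
      stop("gene not found in binary matrix: ", g, call. = FALSE)
    }
  }
  a <- b[, gene_a]; c_ <- b[, gene_c]
  ids <- rownames(b)
  structure(list(
    both_one = ids[a == 1L & c_ == 1L],
    inconsistent = ids[a != c_],
    both_zero = ids[a == 0L & c_ == 0L]
  ), class = "sample_partition")
}

#' Two-sided correlation-test p-value with degenerate-input guards
#'
#' Thin wrapper around [stats::cor.test()] returning the two-sided p-value of
#' the Pearson or Spearman correlation between \code{x} and \code{y}. Inputs
#' too short (< 3 points) or constant in either vector return 1 (no
#' evidence), and the result is clamped to [1e-300, 1] so that its log10 is
#' always finite.
#'
#' @param x,y Numeric vectors of equal length.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return A p-value in [1e-300, 1].
#' @export
correlation_pvalue <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  if (length(x) < 3L) return(1)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(1)
  p <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE)$p.value
  )
  if (is.na(p)) return(1)
  min(max(p, 1e-300), 1)
}

## Lamda3 for one (A, C) gene pair; cont/bin share rows exactly.
.lamda3_pair <- function(gene_a, gene_c, cont, bin, method) {
  part <- partition_samples(gene_a, gene_c, bin)
  background <- setdiff(colnames(cont), c(gene_a, gene_c))
  breakdown <- list(
    gene_a = gene_a, gene_c = gene_c,
    n_both_one = length(part$both_one),
    n_inconsistent = length(part$inconsistent),
    n_both_zero = length(part$both_zero),
    p2_ac = NA_real_, p0_ac = NA_real_,
    p2_bg = NA_real_, p0_bg = NA_real_,
    value = NA_real_
  )
  if (length(part$both_one) < 3L || length(part$both_zero) < 3L ||
      length(background) < 1L) {
    return(breakdown)
  }
  m2 <- cont[part$both_one, , drop = FALSE]
  m0 <- cont[part$both_zero, , drop = FALSE]
  breakdown$p2_ac <- correlation_pvalue(m2[, gene_a], m2[, gene_c], method)
  breakdown$p0_ac <- correlation_pvalue(m0[, gene_a], m0[, gene_c], method)
  p2_all <- vapply(background, function(g)
    correlation_pvalue(m2[, gene_a], m2[, g], method), 0)
  p0_all <- vapply(background, function(g)
    correlation_pvalue(m0[, gene_a], m0[, g], method), 0)
  breakdown$p2_bg <- stats::median(p2_all)
  breakdown$p0_bg <- stats::median(p0_all)
  denom <- log10(breakdown$p2_bg) + log10(breakdown$p0_bg)
  if (denom == 0) return(breakdown)
  breakdown$value <- (log10(breakdown$p2_ac) + log10(breakdown$p0_ac)) / denom
  breakdown
}

#' Lamda3 interestingness of a rule, computed from the continuous matrix
#'
#' Lamda3 scores a rule A => C by the association strength of the two genes
#' in the continuous data relative to the background, evaluated separately
#' in the samples where both genes are dysregulated (both-one partition) and
#' where both are unchanged (both-zero partition):
#' \deqn{Lamda3 = \frac{\log_{10} P^2_{A,C} + \log_{10} P^0_{A,C}}
#'                     {\log_{10} P^2 + \log_{10} P^0}}
#' where \eqn{P^2_{A,C}}, \eqn{P^0_{A,C}} are the correlation-test p-values
#' of A and C within the two partitions and \eqn{P^2}, \eqn{P^0} are the
#' medians of the p-values between A and every other gene of the matrix
#' (excluding A and C) in the same partitions. Values above 1 mean the rule
#' pair is more strongly coupled than the background.
#'
#' Because it reaches back to the continuous values, Lamda3 recovers
#' information lost in binarization and is less sensitive to the
#' discretization cutoff than support/confidence/lift.
#'
#' For rules with several antecedent (or consequent) genes the single-pair
#' formula is applied to every (lhs gene, rhs gene) pair and the median of
#' the pair values is returned, with the breakdown of the pair attaining
#' that median. The score is NA when either consistent partition has fewer
#' than 3 samples, no background gene exists, or both background medians
#' equal 1 (zero denominator).
#'
#' @param lhs,rhs Character vectors of antecedent / consequent gene IDs.
#' @param cont Continuous samples x genes matrix.
#' @param bin Binary matrix with identical dimnames (sample alignment is
#'   checked).
#' @param method Correlation type passed to [correlation_pvalue()].
#' @return A list of class \code{"lamda3_breakdown"}: p2_ac, p0_ac (rule-pair
#'   p-values), p2_bg, p0_bg (median background p-values), partition sizes,
#'   and \code{value} (the Lamda3 score or NA).
#' @examples
#' sim <- generate_single_omics(m = 40, n = 8, seed = 1)
#' lamda3_score("A1", "C1", sim$continuous, sim$binary)$value
#' @export
lamda3_score <- function(lhs, rhs, cont, bin,
                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.matrix(cont))
  bin <- as_binary_matrix(bin)
  if (!identical(rownames(cont), rownames(bin))) {
    stop("continuous and binary matrices have different sample labels/order",
         call. = FALSE)
  }
  genes <- unique(c(lhs, rhs))
  missing <- setdiff(genes, intersect(colnames(cont), colnames(bin)))
  if (length(missing) > 0L) {
    stop("rule gene(s) absent from the matrices: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pairs <- expand.grid(a = lhs, c = rhs, stringsAsFactors = FALSE)
  breakdowns <- lapply(seq_len(nrow(pairs)), function(i)
    .lamda3_pair(pairs$a[i], pairs$c[i], cont, bin, method))
  values <- vapply(breakdowns, function(bd) bd$value, 0)
  ok <- !is.na(values)
  if (!any(ok)) {
    out <- breakdowns[[1L]]
  } else {
    med <- stats::median(values[ok])
    # breakdown of the pair closest to the median (ties: first)
    pick <- which(ok)[which.min(abs(values[ok] - med))]
    out <- breakdowns[[pick]]
    out$value <- med
  }
  out$n_pairs <- nrow(pairs)
  class(out) <- "lamda3_breakdown"
  out
}

#' @export
print.lamda3_breakdown <- function(x, ...) {
  cat(sprintf("Lamda3(%s => %s) = %s\n", x$gene_a, x$gene_c,
              format(x$value, digits = 4)))
  cat(sprintf("  partitions: both-one %d | inconsistent %d | both-zero %d\n",
              x$n_both_one, x$n_inconsistent, x$n_both_zero))
  cat(sprintf("  pair p-values:       P2=%.3g  P0=%.3g\n", x$p2_ac, x$p0_ac))
  cat(sprintf("  background medians:  P2=%.3g  P0=%.3g\n", x$p2_bg, x$p0_bg))
  invisible(x)
}

#' Rank-derived gene weights for weighted condensed support
#'
#' Maps an ordered gene ranking (best first) to weights
#' \eqn{w_g = (n - rank_g + 1) / n}, so the top gene weighs 1 and the last
#' 1/n.
#'
#' @param ranked_genes Character vector of gene IDs, best first.
#' @return Named numeric vector of weights in (0, 1].
#' @export
rank_weights <- function(ranked_genes) {
  stopifnot(length(ranked_genes) > 0L, !anyDuplicated(ranked_genes))
  n <- length(ranked_genes)
  stats::setNames((n - seq_len(n) + 1) / n, ranked_genes)
}

#' Weighted condensed support of a rule
#'
#' wcs = support(lhs u rhs) x mean(gene weights over lhs u rhs). With unit
#' weights (the default when no ranking is available) wcs equals plain
#' support.
#'
#' @param lhs,rhs Character vectors of gene IDs.
#' @param b Binary matrix (support is recounted from it).
#' @param weights Named numeric gene weights in (0, 1]; missing genes default
#'   to 1 only when \code{weights} is NULL, otherwise every rule gene must be
#'   covered.
#' @return A nonnegative number.
#' @export
wcs_score <- function(lhs, rhs, b, weights = NULL) {
  b <- as_binary_matrix(b)
  genes <- unique(c(lhs, rhs))
  absent <- setdiff(genes, colnames(b))
  if (length(absent) > 0L) {
    stop("gene(s) absent from matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(weights)) {
    w <- rep(1, length(genes))
  } else {
    uncovered <- setdiff(genes, names(weights))
    if (length(uncovered) > 0L) {
      stop("missing weight for gene(s): ", paste(uncovered, collapse = ", "),
           call. = FALSE)
    }
    w <- weights[genes]
  }
  supp <- mean(rowSums(b[, genes, drop = FALSE] == 1L) == length(genes))
  supp * mean(w)
}

#' Score a rule set with Lamda3 and wcs
#'
#' Fills the \code{lamda3} and \code{wcs} columns of a mined [rule_set()].
#'
#' @param rules A \code{rule_set}.
#' @param cont,bin Aligned continuous and binary matrices.
#' @param method Correlation type for Lamda3.
#' @param weights Optional gene weights for wcs (see [wcs_score()]).
#' @return The rule set with \code{lamda3} and \code{wcs} populated.
#' @export
score_rules <- function(rules, cont, bin, method = c("pearson", "spearman"),
                        weights = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(rules, "rule_set"))
  if (nrow(rules) == 0L) return(rules)
  rules$lamda3 <- vapply(seq_len(nrow(rules)), function(i)
    lamda3_score(rules$lhs[[i]], rules$rhs[[i]], cont, bin, method)$value, 0)
  rules$wcs <- vapply(seq_len(nrow(rules)), function(i)
    wcs_score(rules$lhs[[i]], rules$rhs[[i]], bin, weights), 0)
  rules
}

#' Rank rules by a measure and keep the top k
#'
#' Orders descending by the chosen measure with NA values last; ties are
#' broken by (lift desc, support desc, lexicographic lhs, lexicographic rhs)
#' so the order is deterministic across platforms.
#'
#' @param rules A \code{rule_set}.
#' @param measure One of \code{"support"}, \code{"confidence"},
#'   \code{"lift"}, \code{"wcs"}, \code{"lamda3"}.
#' @param top_k Number of rules to return (default 20).
#' @return The first \code{min(top_k, nrow(rules))} rules in rank order.
#' @export
rank_rules <- function(rules,
                       measure = c("lamda3", "support", "confidence",
                                   "lift", "wcs"),
                       top_k = 20L) {
  measure <- match.arg(measure)
  stopifnot(inherits(rules, "rule_set"), top_k >= 1L)
  if (nrow(rules) == 0L) return(rules)
  key <- rules[[measure]]
  lhs_key <- vapply(rules$lhs, paste, "", collapse = ",")
  rhs_key <- vapply(rules$rhs, paste, "", collapse = ",")
  o <- order(is.na(key), -ifelse(is.na(key), -Inf, key),
             -rules$lift, -rules$support, lhs_key, rhs_key)
  out <- rules[o[seq_len(min(top_k, nrow(rules)))], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rule_set", "data.frame")
  out
}
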