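#' Combine two omics layers measured on the same patients
#'
#' Restricts both layers to their shared samples (in layer 1's order),
#' suffixes layer-1 gene IDs with \code{".1"} and layer-2 gene IDs with
#' \code{".2"} (e.g. mRNA vs DNA methylation), and concatenates the columns,
#' identically for the continuous and the binary matrices. The combined
#' binary matrix can then be mined as a single transaction database whose
#' rules may span regulation layers.
#'
#' @param cont1,bin1 Continuous and binary matrix of layer 1 (identical
#'   dimnames within the layer).
#' @param cont2,bin2 Same for layer 2.
#' @return A list of class \code{"combined_layers"}: \code{continuous},
#'   \code{binary} (shared samples x suffixed genes) and \code{layer_of}, a
#'   named integer vector mapping each suffixed gene ID to 1 or 2.
#' @examples
#' sim <- generate_paired_omics(m = 20, n1 = 4, n2 = 4, seed = 1)
#' cl <- combine_layers(sim$layer1$continuous, sim$layer1$binary,
#'                      sim$layer2$continuous, sim$layer2$binary)
#' head(colnames(cl$binary))
#' @export
combine_layers <- function(cont1, bin1, cont2, bin2) {
  bin1 <- as_binary_matrix(bin1); bin2 <- as_binary_matrix(bin2)
  stopifnot(is.matrix(cont1), is.matrix(cont2))
  if (!identical(dimnames(cont1), dimnames(bin1))) {
    stop("layer 1: continuous and binary matrices disagree on labels",
         call. = FALSE)
  }
  if (!identical(dimnames(cont2), dimnames(bin2))) {
    stop("layer 2: continuous and binary matrices disagree on labels",
         call. = FALSE)
  }
  s1 <- trimws(rownames(cont1)); s2 <- trimws(rownames(cont2))
  shared <- s1[s1 %in% s2]
  if (length(shared) < 2L) {
    stop("insufficient overlap: layers share ", length(shared),
         " sample(s), need at least 2", call. = FALSE)
  }
  has_suffix <- grepl("\\.[12]$", c(colnames(cont1), colnames(cont2)))
  if (any(has_suffix)) {
    warning("gene ID(s) already end in '.1'/'.2'; layer suffix appended ",
            "anyway: ",
            paste(c(colnames(cont1), colnames(cont2))[has_suffix],
                  collapse = ", "), call. = FALSE)
  }
  g1 <- paste0(colnames(cont1), ".1")
  g2 <- paste0(colnames(cont2), ".2")

  i1 <- match(shared, s1); i2 <- match(shared, s2)
  glue <- function(a, b) {
    out <- cbind(a[i1, , drop = FALSE], b[i2, , drop = FALSE])
    dimnames(out) <- list(shared, c(g1, g2))
    out
  }
  structure(list(
    continuous = glue(cont1, cont2),
    binary = glue(bin1, bin2),
    layer_of = stats::setNames(c(rep(1L, length(g1)), rep(2L, length(g2))),
                               c(g1, g2))
  ), class = "combined_layers")
}

#' Keep rules that associate genes across omics layers
#'
#' Applied to rules mined from a combined two-layer matrix. In the default
#' \code{"span"} mode a rule is retained when its items (lhs and rhs
#' together) include genes from both layers — the mode under which a rule
#' like \{TAP1.1, ANXA5.2\} => \{PSMB9.1\} (mRNA + methylation antecedent,
#' mRNA consequent) is kept. \code{"strict"} additionally requires that no
#' consequent gene shares a layer with any antecedent gene.
#'
#' @param rules A [rule_set()].
#' @param layer_of Named vector mapping suffixed gene IDs to layers, as
#'   returned by [combine_layers()].
#' @param mode \code{"span"} (default) or \code{"strict"}.
#' @return The retained rules, input order preserved.
#' @export
filter_cross_omics <- function(rules, layer_of, mode = c("span", "strict")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rules, "rule_set"))
  if (nrow(rules) == 0L) return(rules)
  keep <- vapply(seq_len(nrow(rules)), function(i) {
    genes <- c(rules$lhs[[i]], rules$rhs[[i]])
    unmapped <- setdiff(genes, names(layer_of))
    if (length(unmapped) > 0L) {
      stop("gene(s) not present in layer map: ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    }
    if (mode == "span") {
      length(unique(layer_of[genes])) == 2L
    } else {
      length(intersect(layer_of[rules$lhs[[i]]],
                       layer_of[rules$rhs[[i]]])) == 0L
    }
  }, TRUE)
  out <- rules[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rule_set", "data.frame")
  out
}
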