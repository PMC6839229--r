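#' Build the bipartite rule network graph
#'
#' Represents a rule set as a directed bipartite graph with one node per
#' gene and one node per rule: edges run antecedent gene -> rule node and
#' rule node -> consequent gene. Hub genes (e.g. a gene that is the shared
#' consequent of several rules) stand out by their degree, and multi-gene
#' antecedents are represented without hyper-edges. Gene nodes are ordered
#' lexicographically, rule nodes follow the input rule order, so construction
#' is deterministic.
#'
#' @param rules A [rule_set()].
#' @return An \code{igraph} directed graph. Vertex attributes: \code{kind}
#'   ("gene" or "rule"), \code{type} (logical bipartite marker, TRUE for rule
#'   nodes), \code{layer} ("1"/"2" for suffixed genes, "" otherwise), and the
#'   rule metrics (support, confidence, lift, wcs, lamda3) on rule nodes.
#' @examples
#' g <- rules_to_graph(mine_rules(toy_matrix(), 0.6, 0.8))
#' igraph::vcount(g)
#' @export
rules_to_graph <- function(rules) {
  stopifnot(inherits(rules, "rule_set"))
  genes <- sort(unique(unlist(c(rules$lhs, rules$rhs))))
  rule_ids <- rule_labels(rules)
  if (anyDuplicated(rule_ids)) {
    rule_ids <- make.unique(rule_ids, sep = " #")
  }
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  if (length(genes) > 0L) {
    layer <- ifelse(grepl("\\.1$", genes), "1",
                    ifelse(grepl("\\.2$", genes), "2", ""))
    g <- igraph::add_vertices(g, length(genes), name = genes, kind = "gene",
                              type = FALSE, layer = layer,
                              support = NA_real_, confidence = NA_real_,
                              lift = NA_real_, wcs = NA_real_,
                              lamda3 = NA_real_)
  }
  if (nrow(rules) > 0L) {
    g <- igraph::add_vertices(g, nrow(rules), name = rule_ids, kind = "rule",
                              type = TRUE, layer = "",
                              support = rules$support,
                              confidence = rules$confidence,
                              lift = rules$lift,
                              wcs = rules$wcs,
                              lamda3 = rules$lamda3)
    edges <- character()
    for (i in seq_len(nrow(rules))) {
      for (a in rules$lhs[[i]]) edges <- c(edges, a, rule_ids[i])
      for (cc in rules$rhs[[i]]) edges <- c(edges, rule_ids[i], cc)
    }
    g <- igraph::add_edges(g, edges)
  }
  g
}

#' Export a rule graph to GraphML or DOT
#'
#' Writes the graph in a standard interchange format for external network
#' tools (Cytoscape, Gephi, Graphviz). Numeric node attributes are rounded
#' to 6 decimals before writing; topology survives a GraphML round-trip.
#'
#' @param g An igraph graph, typically from [rules_to_graph()].
#' @param path Output file path.
#' @param format \code{"graphml"} or \code{"dot"}.
#' @return Invisibly, \code{path}.
#' @export
export_graph <- function(g, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "igraph"))
  for (attr in igraph::vertex_attr_names(g)) {
    v <- igraph::vertex_attr(g, attr)
    if (is.numeric(v)) {
      g <- igraph::set_vertex_attr(g, attr, value = round(v, 6))
    } else if (is.logical(v)) {  # DOT has no boolean attribute type
      g <- igraph::set_vertex_attr(g, attr, value = as.integer(v))
    }
  }
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Group rules by antecedent overlap for a balloon-style plot
#'
#' Collapses the distinct antecedent (lhs) item sets into at most
#' \code{n_groups} groups — identical antecedents merge first, then the two
#' groups with the highest Jaccard similarity between their item unions are
#' merged greedily — and tabulates, per (antecedent group, consequent) cell,
#' the number of rules and the maximum of the chosen measure. This is the
#' tabular form behind a grouped incidence ("group graph") plot of the
#' top-ranked rules.
#'
#' @param rules A [rule_set()].
#' @param n_groups Maximum number of antecedent groups (>= 1).
#' @param measure Measure summarized per cell (default \code{"lift"}).
#' @return A data.frame with columns \code{lhs_group} (comma-joined union of
#'   the group's items), \code{rhs} (comma-joined consequent), \code{n_rules}
#'   and \code{max_measure}; the \code{n_rules} column sums to
#'   \code{nrow(rules)}.
#' @export
rules_to_grouped_table <- function(rules, n_groups,
                                   measure = c("lift", "support",
                                               "confidence", "wcs",
                                               "lamda3")) {
  measure <- match.arg(measure)
  stopifnot(inherits(rules, "rule_set"), n_groups >= 1L)
  if (nrow(rules) == 0L) {
    return(data.frame(lhs_group = character(), rhs = character(),
                      n_rules = integer(), max_measure = numeric()))
  }
  lhs_key <- vapply(rules$lhs, paste, "", collapse = ",")
  # start from exact-lhs groups, each holding its member rule indices
  groups <- lapply(sort(unique(lhs_key)), function(k) {
    list(items = sort(unique(unlist(rules$lhs[lhs_key == k]))),
         rules = which(lhs_key == k))
  })
  jaccard <- function(a, b) {
    length(intersect(a, b)) / length(union(a, b))
  }
  while (length(groups) > n_groups) {
    best <- c(NA_integer_, NA_integer_); best_sim <- -1
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        sim <- jaccard(groups[[i]]$items, groups[[j]]$items)
        if (sim > best_sim) { best_sim <- sim; best <- c(i, j) }
      }
    }
    merged <- list(
      items = sort(union(groups[[best[1L]]]$items, groups[[best[2L]]]$items)),
      rules = sort(c(groups[[best[1L]]]$rules, groups[[best[2L]]]$rules))
    )
    groups <- c(groups[-best], list(merged))
  }
  rhs_key <- vapply(rules$rhs, paste, "", collapse = ",")
  rows <- list()
  for (grp in groups) {
    label <- paste(grp$items, collapse = ",")
    for (rk in sort(unique(rhs_key[grp$rules]))) {
      members <- grp$rules[rhs_key[grp$rules] == rk]
      vals <- rules[[measure]][members]
      rows[[length(rows) + 1L]] <- data.frame(
        lhs_group = label, rhs = rk, n_rules = length(members),
        max_measure = if (all(is.na(vals))) NA_real_
                      else max(vals, na.rm = TRUE),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$lhs_group, out$rhs), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot the rule network graph
#'
#' Quick base-graphics rendering of a [rules_to_graph()] graph: gene nodes
#' as circles, rule nodes as small squares.
#'
#' @param g An igraph rule graph.
#' @param ... Passed to [igraph::plot.igraph()].
#' @return Invisibly, \code{g}.
#' @export
plot_rule_graph <- function(g, ...) {
  kind <- igraph::vertex_attr(g, "kind")
  igraph::plot.igraph(
    g,
    vertex.shape = ifelse(kind == "rule", "square", "circle"),
    vertex.size = ifelse(kind == "rule", 6, 14),
    vertex.color = ifelse(kind == "rule", "grey70", "lightblue"),
    vertex.label = ifelse(kind == "rule", NA, igraph::V(g)$name),
    edge.arrow.size = 0.4, ...
  )
  invisible(g)
}

#' Balloon plot of the grouped rule table
#'
#' Renders [rules_to_grouped_table()] output as a dot-matrix plot (antecedent
#' groups x consequents, dot size = rule count, color = max measure).
#' Requires ggplot2.
#'
#' @param grouped Output of [rules_to_grouped_table()].
#' @return A ggplot object.
#' @export
plot_grouped_rules <- function(grouped) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plot_grouped_rules()", call. = FALSE)
  }
  ggplot2::ggplot(grouped,
                  ggplot2::aes(x = .data_col(grouped, "rhs"),
                               y = .data_col(grouped, "lhs_group"),
                               size = .data_col(grouped, "n_rules"),
                               color = .data_col(grouped, "max_measure"))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "consequent", y = "antecedent group",
                  size = "rules", color = "max measure") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

## aes() helper avoiding a hard tidy-eval dependency
.data_col <- function(df, nm) df[[nm]]
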