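# Bipartite graph container and the topology metrics used to characterise
# drug-pathway, drug-ADR and pathway-ADR networks: density, degree, Latapy
# clustering coefficient, redundancy coefficient, node strength, connected
# components, and the weighted one-to-one-mode projection through shared
# drugs.

#' Construct a bipartite graph
#'
#' Two disjoint node parts and edges only across parts. Isolated nodes are
#' allowed (construction rules decide which part keeps them); duplicate
#' edges are an error.
#'
#' @param part_one,part_two Character vectors of node labels (disjoint).
#' @param edges Data frame with columns `u` (in part one), `v` (in part two)
#'   and optionally `weight` (positive numeric).
#' @param name Tag for the graph.
#' @param weighted Logical; defaults to TRUE when `edges$weight` exists.
#' @return Object of class `bipartite_graph`.
#' @export
bipartite_graph <- function(part_one, part_two,
                            edges = data.frame(u = character(0),
                                               v = character(0)),
                            name = "bipartite", weighted = NULL) {
  part_one <- sort(unique(as.character(part_one)))
  part_two <- sort(unique(as.character(part_two)))
  if (length(intersect(part_one, part_two))) {
    dpa_error("invalid_parameter", "node parts must be disjoint")
  }
  if (is.null(weighted)) weighted <- "weight" %in% names(edges)
  if (!"weight" %in% names(edges)) edges$weight <- rep(1, nrow(edges))
  edges$u <- as.character(edges$u); edges$v <- as.character(edges$v)
  if (nrow(edges)) {
    if (!all(edges$u %in% part_one) || !all(edges$v %in% part_two)) {
      dpa_error("invalid_parameter", "edges must run from part one to part two")
    }
    if (anyDuplicated(paste(edges$u, edges$v, sep = "\r"))) {
      dpa_error("duplicate_edge", "duplicate (u, v) edge")
    }
    if (any(edges$weight < 0)) {
      dpa_error("invalid_parameter", "edge weights must be non-negative")
    }
    edges <- edges[order(edges$u, edges$v), c("u", "v", "weight")]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(u = character(0), v = character(0), weight = numeric(0))
  }
  structure(list(part_one = part_one, part_two = part_two, edges = edges,
                 weighted = weighted, name = name),
            class = "bipartite_graph")
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf(
    "Bipartite graph '%s': %d + %d nodes, %d %s edges\n",
    x$name, length(x$part_one), length(x$part_two), nrow(x$edges),
    if (x$weighted) "weighted" else "unweighted"))
  invisible(x)
}

# neighbourhoods as a named list over all nodes of the graph
neighbourhoods <- function(g) {
  nb <- c(
    stats::setNames(vector("list", length(g$part_one)), g$part_one),
    stats::setNames(vector("list", length(g$part_two)), g$part_two)
  )
  nb[] <- list(character(0))
  if (nrow(g$edges)) {
    by_u <- split(g$edges$v, g$edges$u)
    by_v <- split(g$edges$u, g$edges$v)
    nb[names(by_u)] <- by_u
    nb[names(by_v)] <- by_v
  }
  nb
}

node_part <- function(g, v) {
  if (v %in% g$part_one) return("one")
  if (v %in% g$part_two) return("two")
  dpa_error("unknown_node", sprintf("node '%s' is not in the graph", v))
}

#' Drug-pathway network from enrichment results
#'
#' Unweighted bipartite graph: an edge links a drug to a pathway when the
#' drug's GSEA call on that pathway is significant (adjusted p below
#' `alpha`). All analysed drugs are kept as part-one nodes even with degree
#' zero; part two contains only pathways significant for at least one drug.
#'
#' @param enrichments Data frame from [gsea_run()] (possibly row-bound over
#'   drugs), columns `drug`, `pathway`, `p_adj`.
#' @param drugs Full list of analysed drug ids.
#' @param alpha Significance cutoff in (0, 1) (default 0.1).
#' @return An unweighted `bipartite_graph`.
#' @export
build_drug_pathway <- function(enrichments, drugs, alpha = 0.1) {
  if (alpha <= 0 || alpha >= 1) {
    dpa_error("invalid_parameter", "alpha must lie in (0, 1)")
  }
  sig <- enrichments[enrichments$p_adj < alpha, , drop = FALSE]
  bipartite_graph(
    part_one = drugs,
    part_two = unique(sig$pathway),
    edges = data.frame(u = sig$drug, v = sig$pathway),
    name = "drug-pathway", weighted = FALSE
  )
}

#' Drug-ADR network from drug-HLT edges
#'
#' Weighted bipartite graph over the drugs and HLTs that carry at least one
#' edge; edge weight is the summed PRR from [aggregate_to_hlt()].
#'
#' @param hlt_edges Data frame `drug`, `hlt`, `weight`.
#' @return A weighted `bipartite_graph`.
#' @export
build_drug_adr <- function(hlt_edges) {
  bipartite_graph(
    part_one = unique(hlt_edges$drug),
    part_two = unique(hlt_edges$hlt),
    edges = data.frame(u = hlt_edges$drug, v = hlt_edges$hlt,
                       weight = hlt_edges$weight),
    name = "drug-ADR", weighted = TRUE
  )
}

#' Bipartite network density
#'
#' `n_edges / (n_part_one * n_part_two)`; isolated nodes count in the
#' denominator.
#'
#' @param g A `bipartite_graph` with both parts non-empty.
#' @return Density in `[0, 1]`.
#' @export
bipartite_density <- function(g) {
  if (!length(g$part_one) || !length(g$part_two)) {
    dpa_error("undefined_density", "density needs both parts non-empty")
  }
  nrow(g$edges) / (length(g$part_one) * length(g$part_two))
}

#' Pairwise bipartite clustering coefficient of two same-part nodes
#'
#' Jaccard overlap of the two neighbourhoods,
#' `|N(u) inter N(v)| / |N(u) union N(v)|`; 0 when both are empty.
#'
#' @param g A `bipartite_graph`.
#' @param u,v Distinct node labels from the same part.
#' @return Coefficient in `[0, 1]`.
#' @export
pairwise_cc <- function(g, u, v) {
  if (node_part(g, u) != node_part(g, v)) {
    dpa_error("incompatible_nodes", "u and v must belong to the same part")
  }
  nb <- neighbourhoods(g)
  un <- union(nb[[u]], nb[[v]])
  if (!length(un)) return(0)
  length(intersect(nb[[u]], nb[[v]])) / length(un)
}

#' Latapy clustering coefficient of a node
#'
#' Mean pairwise clustering coefficient of `u` with every node at distance
#' two from it (its same-part co-neighbours); 0 when that second
#' neighbourhood is empty (in particular for isolated nodes), so part-level
#' averages are defined over all nodes.
#'
#' @param g A `bipartite_graph`.
#' @param u Node label.
#' @return Coefficient in `[0, 1]`.
#' @export
node_cc <- function(g, u) {
  node_part(g, u)
  nb <- neighbourhoods(g)
  second <- setdiff(unique(unlist(nb[nb[[u]]], use.names = FALSE)), u)
  if (!length(second)) return(0)
  ccs <- vapply(second, function(v) {
    un <- union(nb[[u]], nb[[v]])
    length(intersect(nb[[u]], nb[[v]])) / length(un)
  }, numeric(1))
  mean(ccs)
}

#' Redundancy coefficient of a node
#'
#' Fraction of unordered pairs of `v`'s neighbours that remain connected
#' through some other node if `v` is removed — i.e. pairs `{u, w}` of
#' neighbours such that some `x != v` links to both. Undefined (NA) when
#' the degree of `v` is below 2.
#'
#' @param g A `bipartite_graph`.
#' @param v Node label.
#' @return Coefficient in `[0, 1]`, or `NA` when undefined.
#' @export
redundancy <- function(g, v) {
  node_part(g, v)
  nb <- neighbourhoods(g)
  nv <- nb[[v]]
  k <- length(nv)
  if (k < 2L) return(NA_real_)
  covered <- 0L
  total <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      total <- total + 1L
      other <- setdiff(intersect(nb[[nv[i]]], nb[[nv[j]]]), v)
      if (length(other)) covered <- covered + 1L
    }
  }
  covered / total
}

#' Node strength
#'
#' Sum of the weights of the node's adjacent edges; 0 for isolated nodes.
#' On an unweighted graph every edge counts 1, so strength equals degree.
#'
#' @param g A `bipartite_graph`.
#' @param v Node label.
#' @return Non-negative number.
#' @export
node_strength <- function(g, v) {
  part <- node_part(g, v)
  sel <- if (part == "one") g$edges$u == v else g$edges$v == v
  sum(g$edges$weight[sel])
}

#' Node degree
#'
#' @param g A `bipartite_graph`.
#' @param v Node label.
#' @return Count of adjacent edges.
#' @export
node_degree <- function(g, v) {
  part <- node_part(g, v)
  sum(if (part == "one") g$edges$u == v else g$edges$v == v)
}

#' Connected components
#'
#' Breadth-first components over the union of both parts; isolated nodes are
#' singleton components. Components are returned sorted by size descending,
#' ties by smallest node label.
#'
#' @param g A `bipartite_graph`.
#' @return List of character vectors (sorted node labels).
#' @export
connected_components <- function(g) {
  nb <- neighbourhoods(g)
  nodes <- names(nb)
  seen <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (start in nodes) {
    if (seen[[start]]) next
    queue <- start
    seen[[start]] <- TRUE
    members <- character(0)
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      members <- c(members, v)
      for (w in nb[[v]]) {
        if (!seen[[w]]) {
          seen[[w]] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  sizes <- lengths(comps)
  first <- vapply(comps, `[`, character(1), 1L)
  comps[order(-sizes, first)]
}

#' Project two bipartite networks through their shared part
#'
#' Connects a part-two node of `g_dp` (pathway) to a part-two node of `g_da`
#' (ADR term) when at least one shared part-one node (drug) links to both;
#' the edge weight is the number of such shared drugs. Only nodes carrying
#' at least one projected edge are retained.
#'
#' @param g_dp Drug-pathway `bipartite_graph`.
#' @param g_da Drug-ADR `bipartite_graph`.
#' @return A weighted `bipartite_graph` with pathways as part one and ADR
#'   terms as part two.
#' @export
project_shared_drugs <- function(g_dp, g_da) {
  shared <- intersect(g_dp$part_one, g_da$part_one)
  e1 <- g_dp$edges[g_dp$edges$u %in% shared, c("u", "v")]
  e2 <- g_da$edges[g_da$edges$u %in% shared, c("u", "v")]
  if (!nrow(e1) || !nrow(e2)) {
    return(bipartite_graph(character(0), character(0),
                           name = "pathway-ADR", weighted = TRUE))
  }
  joined <- merge(e1, e2, by = "u", suffixes = c("_p", "_a"))
  counts <- stats::aggregate(list(weight = joined$u),
                             by = list(u = joined$v_p, v = joined$v_a),
                             FUN = length)
  bipartite_graph(
    part_one = unique(counts$u), part_two = unique(counts$v),
    edges = counts, name = "pathway-ADR", weighted = TRUE
  )
}

#' Per-node topology metrics table
#'
#' @param g A `bipartite_graph`.
#' @return Data frame with `node`, `part`, `degree`, `cc`, `redundancy`
#'   (NA when degree < 2) and `strength` for every node of the graph.
#' @export
node_metrics <- function(g) {
  nb <- neighbourhoods(g)
  nodes <- names(nb)
  parts <- c(rep("one", length(g$part_one)), rep("two", length(g$part_two)))
  data.frame(
    node = nodes,
    part = parts,
    degree = vapply(nodes, function(v) length(nb[[v]]), integer(1)),
    cc = vapply(nodes, function(v) node_cc(g, v), numeric(1)),
    redundancy = vapply(nodes, function(v) redundancy(g, v), numeric(1)),
    strength = vapply(nodes, function(v) node_strength(g, v), numeric(1)),
    row.names = NULL
  )
}

#' Whole-graph summary
#'
#' Node counts per part, edge count, density, and per-part mean Latapy
#' clustering coefficient (degree-0 nodes included at cc 0).
#'
#' @param g A `bipartite_graph` with both parts non-empty.
#' @return One-row data frame `n_part_one`, `n_part_two`, `n_edges`,
#'   `density`, `mean_cc_part_one`, `mean_cc_part_two`.
#' @export
graph_summary <- function(g) {
  nm <- node_metrics(g)
  data.frame(
    n_part_one = length(g$part_one),
    n_part_two = length(g$part_two),
    n_edges = nrow(g$edges),
    density = bipartite_density(g),
    mean_cc_part_one = mean(nm$cc[nm$part == "one"]),
    mean_cc_part_two = mean(nm$cc[nm$part == "two"])
  )
}

#' Complementary cumulative degree frequency
#'
#' For each observed degree value k, the fraction of the part's nodes with
#' degree at least k — the axes used for degree-distribution plots.
#'
#' @param g A `bipartite_graph`.
#' @param part `"one"` or `"two"`.
#' @return Data frame `k`, `ccdf`.
#' @export
degree_ccdf <- function(g, part = c("one", "two")) {
  part <- match.arg(part)
  nodes <- if (part == "one") g$part_one else g$part_two
  deg <- vapply(nodes, function(v) node_degree(g, v), integer(1))
  ks <- sort(unique(deg))
  data.frame(k = ks,
             ccdf = vapply(ks, function(k) mean(deg >= k), numeric(1)))
}
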