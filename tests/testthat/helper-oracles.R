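# Independent brute-force oracles. These re-derive each quantity by the most
# literal route available (exhaustive loops, full enumeration) and are kept
# free of any package internals beyond the public graph accessors.

# ---- bipartite graph oracles ------------------------------------------------

oracle_neighbours <- function(g, v) {
  if (v %in% g$part_one) g$edges$v[g$edges$u == v]
  else g$edges$u[g$edges$v == v]
}

oracle_node_cc <- function(g, u) {
  nu <- oracle_neighbours(g, u)
  same_part <- if (u %in% g$part_one) g$part_one else g$part_two
  second <- character(0)
  for (v in setdiff(same_part, u)) {
    if (length(intersect(oracle_neighbours(g, v), nu))) second <- c(second, v)
  }
  if (!length(second)) return(0)
  vals <- vapply(second, function(v) {
    nv <- oracle_neighbours(g, v)
    length(intersect(nu, nv)) / length(union(nu, nv))
  }, numeric(1))
  mean(vals)
}

oracle_redundancy <- function(g, v) {
  nv <- oracle_neighbours(g, v)
  if (length(nv) < 2) return(NA_real_)
  pairs <- utils::combn(nv, 2)
  ok <- 0
  for (i in seq_len(ncol(pairs))) {
    u <- pairs[1, i]; w <- pairs[2, i]
    others <- setdiff(intersect(oracle_neighbours(g, u),
                                oracle_neighbours(g, w)), v)
    if (length(others)) ok <- ok + 1
  }
  ok / ncol(pairs)
}

oracle_components_igraph <- function(g) {
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("u", "v")], directed = FALSE,
    vertices = data.frame(name = c(g$part_one, g$part_two))
  )
  mem <- igraph::components(ig)$membership
  comps <- split(names(mem), mem)
  comps <- lapply(comps, sort)
  names(comps) <- NULL
  sizes <- lengths(comps)
  first <- vapply(comps, `[`, character(1), 1L)
  comps[order(-sizes, first)]
}

oracle_projection <- function(g_dp, g_da) {
  # triple loop over (pathway, adr, drug)
  out <- list()
  for (p in g_dp$part_two) {
    for (a in g_da$part_two) {
      n <- 0
      for (d in intersect(g_dp$part_one, g_da$part_one)) {
        if (any(g_dp$edges$u == d & g_dp$edges$v == p) &&
            any(g_da$edges$u == d & g_da$edges$v == a)) n <- n + 1
      }
      if (n >= 1) out[[length(out) + 1L]] <- data.frame(u = p, v = a,
                                                        weight = n)
    }
  }
  if (!length(out)) return(data.frame(u = character(0), v = character(0),
                                      weight = numeric(0)))
  df <- do.call(rbind, out)
  df[order(df$u, df$v), ]
}

# random bipartite graph on <= n1 + n2 nodes with edge probability p_edge
random_bipartite <- function(n1, n2, p_edge, weighted = FALSE) {
  p1 <- sprintf("a%02d", seq_len(n1))
  p2 <- sprintf("b%02d", seq_len(n2))
  all_pairs <- expand.grid(u = p1, v = p2, stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(all_pairs)) < p_edge
  e <- all_pairs[keep, , drop = FALSE]
  if (weighted && nrow(e)) e$weight <- round(stats::runif(nrow(e), 0.5, 5), 2)
  bipartite_graph(p1, p2, e)
}

# ---- GSEA oracles -----------------------------------------------------------

# literal running-sum enrichment score on a pre-sorted statistic vector
oracle_es <- function(stats, gene_set, w = 1) {
  ord <- order(-stats, names(stats))
  s <- stats[ord]
  hit <- names(s) %in% gene_set
  G <- length(s)
  N_H <- sum(hit)
  N_R <- sum(abs(s[hit])^w)
  run <- 0
  mx <- -Inf; mn <- Inf
  for (i in seq_len(G)) {
    run <- run + if (hit[i]) unname(abs(s[i]))^w / N_R else -1 / (G - N_H)
    if (run > mx) mx <- run
    if (run < mn) mn <- run
  }
  if (mx >= -mn - 1e-12) mx else mn  # positive wins a tie (fp-cushioned)
}

# exact one-sided exceedance fraction over all C(G, N_H) subsets — the
# population quantity the sampled add-one estimator converges to
oracle_exact_p <- function(observed_es, stats, N_H, w = 1) {
  genes <- names(stats)
  subsets <- utils::combn(genes, N_H, simplify = FALSE)
  null_es <- vapply(subsets, function(ss) oracle_es(stats, ss, w), numeric(1))
  same <- sign(null_es) == sign(observed_es) & null_es != 0
  m <- sum(same)
  if (m == 0) return(NA_real_)
  p <- sum(same & abs(null_es) >= abs(observed_es) - 1e-12) / m
  attr(p, "same_frac") <- m / length(null_es)  # for Monte-Carlo SE scaling
  p
}

# ---- misc oracles -----------------------------------------------------------

oracle_footrule <- function(p, q) {
  tot <- 0
  for (g in names(p$ranks)) tot <- tot + abs(p$ranks[[g]] - q$ranks[[g]])
  tot
}

oracle_contingency <- function(reports, exposure, event, scope) {
  a <- b <- c_ <- d <- 0
  for (i in seq_len(nrow(reports))) {
    if (!(reports$drug[i] %in% scope)) next
    exp_i <- reports$drug[i] %in% exposure
    ev_i <- reports$preferred_term[i] == event
    if (exp_i && ev_i) a <- a + 1
    else if (exp_i) b <- b + 1
    else if (ev_i) c_ <- c_ + 1
    else d <- d + 1
  }
  c(a = a, b = b, c = c_, d = d)
}

# naive O(n^3) complete-linkage agglomeration returning sorted merge heights
oracle_complete_linkage_heights <- function(d) {
  clusters <- as.list(rownames(d))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq.int(i + 1, length(clusters))) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  sort(heights)
}

# tiny helper: random ranked profile over a shared universe
random_profile <- function(genes, id = NA_character_) {
  to_ranked_profile(stats::setNames(stats::rnorm(length(genes)), genes), id)
}
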