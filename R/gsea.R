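# Preranked permutation GSEA: links a drug's consensus ranked profile to the
# pathways it perturbs. Running-sum enrichment score with weight exponent w,
# gene-permutation null (random same-size gene subsets), add-one permutation
# p-value, Benjamini-Hochberg adjustment within each drug's run.

#' Signed gene-level statistic from a ranked profile
#'
#' `s_g = (G + 1) / 2 - r_g`: symmetric about zero, the top-ranked (most
#' up-regulated) gene gets the largest positive value, and the statistics of
#' any valid profile sum to zero.
#'
#' @param profile A `ranked_profile`.
#' @return Named numeric vector of gene statistics.
#' @export
gene_level_statistic <- function(profile) {
  (profile$G + 1) / 2 - profile$ranks
}

# Sort statistics descending with a deterministic tie-break on gene id.
sort_stats <- function(stats) {
  stats[order(-stats, names(stats))]
}

#' Weighted running-sum enrichment score
#'
#' Walks the gene list in decreasing order of the gene statistic. Genes in
#' the set increment the running sum by `|s|^w / N_R` (with `N_R` the sum of
#' `|s|^w` over in-set genes); genes outside decrement it by `1/(G - N_H)`.
#' The enrichment score is the signed deviation from zero with maximal
#' absolute value.
#'
#' @param stats Named numeric vector of gene statistics (any order; sorted
#'   internally, ties broken by gene id).
#' @param gene_set Character vector of gene ids; intersected with the
#'   statistic universe before use.
#' @param w Weight exponent (default 1, the classic GSEA weighting).
#' @return ES in `[-1, 1]` with attribute `N_H` (effective set size).
#' @export
enrichment_score <- function(stats, gene_set, w = 1) {
  s <- sort_stats(stats)
  G <- length(s)
  hit <- names(s) %in% gene_set
  N_H <- sum(hit)
  if (N_H == 0L) {
    dpa_error("empty_after_intersection",
              "gene set has no overlap with the statistic universe")
  }
  if (N_H == G) {
    dpa_error("degenerate_set", "gene set covers the whole universe")
  }
  sw <- abs(s)^w
  N_R <- sum(sw[hit])
  if (N_R == 0 && w > 0) {
    dpa_error("degenerate_statistic",
              "all in-set gene statistics are zero with w > 0")
  }
  inc <- ifelse(hit, sw / N_R, -1 / (G - N_H))
  run <- cumsum(inc)
  mx <- max(run)
  mn <- min(run)
  # positive deviation wins a tie of magnitudes (cushioned against fp jitter)
  es <- unname(if (mx >= -mn - 1e-12) mx else mn)
  attr(es, "N_H") <- N_H
  es
}

# ES of a gene subset given only its positions in the sorted statistic list.
# Equivalent to enrichment_score but O(N_H) per evaluation after the one-off
# sort; used for the permutation null.
es_from_positions <- function(sw_sorted, G, pos, w) {
  pos <- sort.int(pos)
  N_H <- length(pos)
  miss_inc <- 1 / (G - N_H)
  hit_w <- sw_sorted[pos]
  N_R <- sum(hit_w)
  if (N_R == 0) {
    if (w > 0) return(0)  # degenerate subset: flat running sum apart from misses
    hit_w <- rep(1, N_H); N_R <- N_H
  }
  cum_hit <- cumsum(hit_w / N_R)
  misses_before <- (pos - seq_len(N_H)) * miss_inc
  after <- cum_hit - misses_before            # running sum just after each hit
  before <- c(0, cum_hit[-N_H]) - misses_before  # just before each hit
  mx <- max(after)
  mn <- min(before)
  if (mx >= -mn - 1e-12) mx else mn
}

#' Permutation p-value for an observed enrichment score
#'
#' Null distribution from `n_perm` uniformly random gene subsets of size
#' `N_H`. The p-value is one-sided on the observed sign:
#' `p = (1 + k) / (1 + m)` where `m` counts null scores with the same sign as
#' the observed ES and `k` counts those at least as extreme in absolute
#' value. If no null draw shares the observed sign, `p = 1 / (1 + n_perm)`
#' is reported with attribute `degenerate_null = TRUE`.
#'
#' @param observed_es Observed ES (signed).
#' @param stats Named numeric vector of gene statistics.
#' @param N_H Subset size for the null.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; the result is deterministic given it.
#' @param w Weight exponent used for the null scores (match the observed ES).
#' @return p-value in `[1/(n_perm + 1), 1]`.
#' @export
permutation_p <- function(observed_es, stats, N_H, n_perm, seed = 1L, w = 1) {
  n_perm <- check_count(n_perm, "n_perm")
  N_H <- check_count(N_H, "N_H")
  s <- sort_stats(stats)
  G <- length(s)
  if (N_H >= G) dpa_error("degenerate_set", "N_H must be smaller than G")
  sw <- abs(s)^w
  null_es <- with_seed(seed, vapply(
    seq_len(n_perm),
    function(i) es_from_positions(sw, G, sample.int(G, N_H), w),
    numeric(1)
  ))
  same_sign <- sign(null_es) == sign(observed_es) & null_es != 0
  m <- sum(same_sign)
  if (m == 0L) {
    p <- 1 / (1 + n_perm)
    attr(p, "degenerate_null") <- TRUE
    return(p)
  }
  # fp cushion so a null score numerically equal to the observed one always
  # counts as at least as extreme
  k <- sum(same_sign & abs(null_es) >= abs(observed_es) - 1e-12)
  (1 + k) / (1 + m)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving with the input.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    dpa_error("invalid_pvalue", "p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Run preranked GSEA for one drug against a gene-set collection
#'
#' Each set is intersected with the profile's gene universe and retained if
#' its effective size lies in `[min_size, max_size]` (and is strictly smaller
#' than the universe). For each retained set the enrichment score and its
#' gene-permutation p-value are computed; BH adjustment is applied across the
#' sets of this run only, and a set is flagged significant when
#' `p_adj < alpha`.
#'
#' @param profile A `ranked_profile`.
#' @param collection Named list of gene sets (character vectors).
#' @param w Weight exponent (default 1).
#' @param n_perm Permutations per set (default 2000; 50000 reproduces a
#'   full-fidelity analysis).
#' @param alpha Significance cutoff on the adjusted p-value (default 0.1).
#' @param min_size,max_size Effective set-size bounds (defaults 5 and 500).
#' @param seed Integer seed.
#' @return Data frame with columns `drug`, `pathway`, `ES`, `N_H`, `p`,
#'   `p_adj`, `significant`; excluded set names in attribute `excluded`.
#' @export
gsea_run <- function(profile, collection, w = 1, n_perm = 2000L, alpha = 0.1,
                     min_size = 5L, max_size = 500L, seed = 1L) {
  if (!length(collection)) {
    dpa_error("empty_collection", "gene-set collection is empty")
  }
  if (alpha <= 0 || alpha >= 1) {
    dpa_error("invalid_parameter", "alpha must lie in (0, 1)")
  }
  stats_vec <- gene_level_statistic(profile)
  universe <- names(stats_vec)
  eff <- lapply(collection, intersect, x = universe)
  sizes <- lengths(eff)
  keep <- sizes >= min_size & sizes <= max_size & sizes < length(universe)
  excluded <- names(collection)[!keep]
  eff <- eff[keep]
  if (!length(eff)) {
    dpa_error("empty_collection",
              "no gene set retained after universe intersection and size filter")
  }
  res <- with_seed(seed, {
    rows <- lapply(names(eff), function(nm) {
      es <- enrichment_score(stats_vec, eff[[nm]], w = w)
      p <- permutation_p(es, stats_vec, attr(es, "N_H"),
                         n_perm = n_perm, seed = NULL, w = w)
      data.frame(drug = profile$drug_id, pathway = nm,
                 ES = as.numeric(es), N_H = attr(es, "N_H"),
                 p = as.numeric(p))
    })
    do.call(rbind, rows)
  })
  res$p_adj <- bh_adjust(res$p)
  res$significant <- res$p_adj < alpha
  attr(res, "excluded") <- excluded
  res
}
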