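# Ranked perturbation profiles: rank representation of a drug's genome-wide
# transcriptional response, Spearman similarity, and Kruskal-Borda consensus
# merging of replicate profiles.

#' Construct a ranked profile from gene-level scores
#'
#' Rank 1 is the most up-regulated gene (largest score); exact ties receive
#' the average rank. This direction convention is fixed across the package —
#' the GSEA gene-level statistic depends on it.
#'
#' @param scores Named numeric vector of gene scores covering the full gene
#'   universe, no missing values.
#' @param drug_id Optional identifier carried along with the profile.
#' @return A `ranked_profile`: list with `drug_id`, `ranks` (named numeric,
#'   sorted by gene id for reproducible serialisation) and `G`.
#' @examples
#' p <- to_ranked_profile(c(g1 = 2, g2 = 1, g3 = 0))
#' p$ranks  # 1 2 3
#' @export
to_ranked_profile <- function(scores, drug_id = NA_character_) {
  if (is.null(names(scores)) || anyNA(scores)) {
    dpa_error("incomplete_profile",
              "scores must be a complete named vector over the gene universe")
  }
  r <- rank(-scores, ties.method = "average")
  r <- r[order(names(r))]
  structure(list(drug_id = drug_id, ranks = r, G = length(r)),
            class = "ranked_profile")
}

ranked_profile_from_ranks <- function(ranks, drug_id = NA_character_) {
  ranks <- ranks[order(names(ranks))]
  structure(list(drug_id = drug_id, ranks = ranks, G = length(ranks)),
            class = "ranked_profile")
}

#' @export
print.ranked_profile <- function(x, ...) {
  cat(sprintf("Ranked perturbation profile%s over %d genes\n",
              if (is.na(x$drug_id)) "" else paste0(" for ", x$drug_id), x$G))
  invisible(x)
}

check_same_universe <- function(p, q) {
  if (!identical(names(p$ranks), names(q$ranks))) {
    dpa_error("incompatible_profiles",
              "profiles are defined over different gene universes")
  }
}

#' Spearman similarity between two ranked profiles
#'
#' Pearson correlation of the two rank vectors; with no ties this equals
#' `1 - 6 * sum(d^2) / (G * (G^2 - 1))`.
#'
#' @param p,q `ranked_profile` objects over the same gene universe.
#' @return rho in `[-1, 1]`.
#' @export
spearman_similarity <- function(p, q) {
  check_same_universe(p, q)
  stats::cor(p$ranks, q$ranks, method = "pearson")
}

#' Spearman similarity matrix over a set of ranked profiles
#'
#' @param profiles Named list of `ranked_profile` objects sharing a universe.
#' @return Symmetric matrix of rho with unit diagonal, attribute
#'   `kind = "perturbation"`.
#' @export
perturbation_similarity_matrix <- function(profiles) {
  ids <- names(profiles)
  if (is.null(ids) || anyDuplicated(ids)) {
    dpa_error("duplicate_identifier", "profile ids must be present and unique")
  }
  rk <- vapply(profiles, function(p) p$ranks, numeric(profiles[[1]]$G))
  for (p in profiles) check_same_universe(profiles[[1]], p)
  m <- stats::cor(rk, method = "pearson")
  dimnames(m) <- list(ids, ids)
  attr(m, "kind") <- "perturbation"
  m
}

#' Spearman footrule distance between two ranked profiles
#'
#' `sum(|r_g(p) - r_g(q)|)` over the shared gene universe — the pairwise
#' distance used by the Kruskal-Borda merge order.
#'
#' @param p,q `ranked_profile` objects over the same gene universe.
#' @return Non-negative number.
#' @export
footrule_distance <- function(p, q) {
  check_same_universe(p, q)
  sum(abs(p$ranks - q$ranks))
}

#' Borda merge of two ranked profiles
#'
#' Borda score `b_g = r_g(p) + r_g(q)`; the output profile ranks genes by
#' ascending Borda score with average ranks on ties.
#'
#' @param p,q `ranked_profile` objects over the same gene universe.
#' @param drug_id Identifier for the merged profile.
#' @return A `ranked_profile`.
#' @export
borda_merge <- function(p, q, drug_id = NA_character_) {
  check_same_universe(p, q)
  b <- p$ranks + q$ranks
  ranked_profile_from_ranks(rank(b, ties.method = "average"), drug_id)
}

#' Kruskal-Borda consensus of replicate profiles
#'
#' Repeatedly finds the pair of profiles with the smallest Spearman footrule
#' distance (ties broken by the lexicographically smallest pair of profile
#' labels) and replaces the pair by its Borda merge, until a single consensus
#' profile remains. A merged profile is labelled by joining its constituents'
#' labels with `"+"` in sorted order, keeping the tie-break deterministic.
#'
#' @param profiles Non-empty list of `ranked_profile` objects over a shared
#'   gene universe; names are used as labels (defaulting to `drug_id`s, then
#'   positional labels).
#' @param drug_id Identifier for the final consensus profile.
#' @return A `ranked_profile`.
#' @export
kru_bor_merge <- function(profiles, drug_id = NA_character_) {
  if (!length(profiles)) {
    dpa_error("empty_input", "need at least one profile to merge")
  }
  labels <- names(profiles)
  if (is.null(labels)) {
    labels <- vapply(profiles, function(p) p$drug_id, character(1))
  }
  labels[is.na(labels) | labels == ""] <-
    sprintf("profile_%03d", which(is.na(labels) | labels == ""))
  pool <- profiles
  names(pool) <- labels
  for (p in pool) check_same_universe(pool[[1]], p)

  while (length(pool) > 1L) {
    n <- length(pool)
    best <- NULL
    best_d <- Inf
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        d <- footrule_distance(pool[[i]], pool[[j]])
        pair <- sort(c(names(pool)[i], names(pool)[j]))
        if (d < best_d ||
            (d == best_d && paste(pair, collapse = "\r") <
               paste(best, collapse = "\r"))) {
          best_d <- d
          best <- pair
        }
      }
    }
    merged <- borda_merge(pool[[best[1]]], pool[[best[2]]])
    pool[best] <- NULL
    pool[[paste(best, collapse = "+")]] <- merged
  }
  out <- pool[[1]]
  out$drug_id <- drug_id
  out
}
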