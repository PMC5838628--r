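# Structural drug-drug similarity from atom-pair descriptor sets, and
# complete-linkage hierarchical clustering of any similarity matrix.

#' Tanimoto similarity of two descriptor sets
#'
#' Set form of the Tanimoto (Jaccard) coefficient on atom-pair descriptor
#' codes: `|A intersect B| / |A union B|`. Codes are treated as a set
#' (presence/absence), not a multiset.
#'
#' @param a,b Character vectors of descriptor codes; duplicates are collapsed.
#' @return Coefficient in `[0, 1]`.
#' @examples
#' tanimoto_similarity(c("p1", "p2", "p3"), c("p2", "p3", "p4"))  # 0.5
#' @export
tanimoto_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) {
    dpa_error("undefined_similarity",
              "Tanimoto similarity is undefined for an empty descriptor set")
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Pairwise structural similarity matrix
#'
#' @param sets Named list of descriptor-code vectors, one per drug; ids must
#'   be unique and there must be at least two drugs.
#' @return Symmetric numeric matrix with unit diagonal, dimnames = drug ids,
#'   and attribute `kind = "structural"`.
#' @export
structural_similarity_matrix <- function(sets) {
  ids <- names(sets)
  if (length(sets) < 2L) {
    dpa_error("invalid_parameter", "need at least two drugs")
  }
  if (is.null(ids) || anyDuplicated(ids)) {
    dpa_error("duplicate_identifier", "drug ids must be present and unique")
  }
  n <- length(sets)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      m[i, j] <- m[j, i] <- tanimoto_similarity(sets[[i]], sets[[j]])
    }
  }
  attr(m, "kind") <- "structural"
  m
}

#' Complete-linkage hierarchical clustering of a similarity matrix
#'
#' Converts similarity to dissimilarity as `1 - similarity` and runs
#' agglomerative clustering with the complete-linkage (maximum) update.
#' Items are ordered lexicographically by id before clustering so leaf order
#' is deterministic.
#'
#' @param similarity Symmetric similarity matrix with dimnames (Tanimoto or
#'   Spearman rho).
#' @return An `hclust` object.
#' @export
complete_linkage_clustering <- function(similarity) {
  if (!is.matrix(similarity) || nrow(similarity) != ncol(similarity)) {
    dpa_error("shape_error", "similarity must be a square matrix")
  }
  ids <- rownames(similarity)
  if (is.null(ids)) ids <- sprintf("item_%03d", seq_len(nrow(similarity)))
  ord <- order(ids)
  d <- 1 - similarity[ord, ord, drop = FALSE]
  if (any(d < -1e-12)) {
    dpa_error("invalid_parameter", "dissimilarities 1 - similarity are negative")
  }
  d[d < 0] <- 0
  rownames(d) <- colnames(d) <- ids[ord]
  stats::hclust(stats::as.dist(d), method = "complete")
}

#' Cut a dendrogram and compare clusters with a reference partition
#'
#' Convenience for family-recovery checks: cuts the tree at `k` clusters and
#' returns the adjusted Rand index against `reference`.
#'
#' @param hc An `hclust` object.
#' @param k Number of clusters.
#' @param reference Named vector of reference labels (names = item ids).
#' @return Adjusted Rand index in `[-1, 1]`.
#' @export
cluster_recovery_ari <- function(hc, k, reference) {
  cl <- stats::cutree(hc, k = k)
  reference <- reference[names(cl)]
  adjusted_rand_index(cl, reference)
}

# Adjusted Rand index (Hubert & Arabie) from the pair-counting contingency
# table; small enough to keep in-package rather than pull a clustering
# dependency in for one statistic.
adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n_pairs <- comb2(sum(tab))
  expected <- sum_i * sum_j / n_pairs
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Write a dendrogram to a Newick file
#'
#' Merge heights become branch lengths via [ape::as.phylo()].
#'
#' @param hc An `hclust` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
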