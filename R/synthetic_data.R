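# Synthetic-data generators: every pipeline input with the statistical
# structure the downstream analysis assumes, plus planted ground truth for
# recovery tests. All generators are deterministic given (parameters, seed).

#' Generate chemically clustered atom-pair descriptor sets
#'
#' Emulates atom-pair descriptor sets for drugs organised in structural
#' families. Each family has a lead set of descriptor codes drawn uniformly
#' from a code universe; members are copies of the lead in which each code is
#' independently replaced by a random universe code with probability
#' `mutation_rate`. With `mutation_rate < 0.5` the expected within-family
#' Tanimoto similarity exceeds the between-family expectation, giving the
#' cluster structure that hierarchical clustering should recover.
#'
#' @param n_families Number of structural families (positive integer).
#' @param members_per_family Drugs per family (positive integer).
#' @param universe_size Size of the descriptor-code universe; must be at least
#'   ten times `set_size`.
#' @param mutation_rate Per-code replacement probability in `[0, 1]`.
#' @param set_size Number of descriptor codes in each lead set (default 30).
#' @param seed Integer seed; identical inputs give byte-identical output.
#' @return Named list mapping `drug_id` to a character vector of descriptor
#'   codes, with a `family_assignment` attribute (named integer vector).
#' @examples
#' sets <- gen_descriptor_sets(2, 3, 500, 0.1, seed = 1)
#' length(sets)  # 6 drugs
#' @export
gen_descriptor_sets <- function(n_families, members_per_family, universe_size,
                                mutation_rate, set_size = 30L, seed = 1L) {
  n_families <- check_count(n_families, "n_families")
  members_per_family <- check_count(members_per_family, "members_per_family")
  universe_size <- check_count(universe_size, "universe_size")
  set_size <- check_count(set_size, "set_size")
  mutation_rate <- check_probability(mutation_rate, "mutation_rate")
  if (universe_size < 10L * set_size) {
    dpa_error("invalid_parameter",
              "universe_size must be at least 10 * set_size")
  }
  universe <- sprintf("ap%05d", seq_len(universe_size))
  with_seed(seed, {
    sets <- list()
    fam <- integer(0)
    for (f in seq_len(n_families)) {
      lead <- sample(universe, set_size)
      for (m in seq_len(members_per_family)) {
        codes <- lead
        flip <- stats::runif(set_size) < mutation_rate
        if (any(flip)) codes[flip] <- sample(universe, sum(flip), replace = TRUE)
        id <- sprintf("drug_f%02d_m%02d", f, m)
        sets[[id]] <- sort(unique(codes))
        fam[id] <- f
      }
    }
    attr(sets, "family_assignment") <- fam
    sets
  })
}

#' Generate a synthetic gene-set (pathway) collection
#'
#' Each pathway is a uniform random subset of the gene universe with size
#' drawn uniformly on `[size_min, size_max]`; names are unique.
#'
#' @param n_pathways Number of gene sets (non-negative integer).
#' @param size_min,size_max Inclusive bounds on set sizes.
#' @param gene_universe Character vector of gene identifiers.
#' @param seed Integer seed.
#' @return Named list of character vectors (one per pathway).
#' @export
gen_pathway_collection <- function(n_pathways, size_min, size_max,
                                   gene_universe, seed = 1L) {
  n_pathways <- check_count(n_pathways, "n_pathways", positive = FALSE)
  if (n_pathways == 0L) return(stats::setNames(list(), character(0)))
  size_min <- check_count(size_min, "size_min")
  size_max <- check_count(size_max, "size_max")
  if (size_min > size_max) {
    dpa_error("invalid_parameter", "size_min must not exceed size_max")
  }
  if (size_max > length(gene_universe)) {
    dpa_error("invalid_parameter",
              "size_max must not exceed the gene universe size")
  }
  with_seed(seed, {
    sizes <- size_min +
      sample.int(size_max - size_min + 1L, n_pathways, replace = TRUE) - 1L
    out <- lapply(sizes, function(k) sort(sample(gene_universe, k)))
    names(out) <- sprintf("pathway_%03d", seq_len(n_pathways))
    out
  })
}

#' Generate gene-level perturbation scores with family structure and planted
#' pathway shifts
#'
#' Score of gene g for a drug is the sum of a family latent component (shared
#' by all drugs of the family, standard deviation `family_signal`), an
#' independent gaussian noise term (standard deviation `noise_sd`), and a
#' shift `delta` added to every gene of each pathway planted for that drug.
#' Scores are continuous and meant to be converted to ranked profiles
#' downstream.
#'
#' @param drugs Character vector of drug ids.
#' @param gene_universe Character vector of gene ids.
#' @param family_assignment Named integer vector drug -> family index; drugs
#'   absent from it get independent latent components.
#' @param family_signal,noise_sd Non-negative scale parameters (score units).
#' @param planted_effects Data frame with columns `drug`, `pathway`, `delta`
#'   (may have zero rows).
#' @param pathways Named list of gene sets (ids into `gene_universe`).
#' @param seed Integer seed.
#' @return Numeric matrix, genes (rows) by drugs (columns).
#' @export
gen_perturbation_scores <- function(drugs, gene_universe, family_assignment,
                                    family_signal, noise_sd,
                                    planted_effects = NULL, pathways = list(),
                                    seed = 1L) {
  if (is.null(planted_effects)) {
    planted_effects <- data.frame(drug = character(0), pathway = character(0),
                                  delta = numeric(0))
  }
  if (nrow(planted_effects)) {
    bad_d <- setdiff(planted_effects$drug, drugs)
    bad_p <- setdiff(planted_effects$pathway, names(pathways))
    if (length(bad_d) || length(bad_p)) {
      dpa_error("unknown_identifier", sprintf(
        "planted effects reference unknown %s: %s",
        if (length(bad_d)) "drugs" else "pathways",
        paste(c(bad_d, bad_p), collapse = ", ")
      ))
    }
  }
  G <- length(gene_universe)
  with_seed(seed, {
    fam <- family_assignment[drugs]
    # drugs without a family get a private latent component
    fam[is.na(fam)] <- max(c(0L, fam), na.rm = TRUE) + seq_len(sum(is.na(fam)))
    ufam <- unique(fam)
    latent <- matrix(stats::rnorm(G * length(ufam), sd = family_signal),
                     nrow = G, dimnames = list(gene_universe, ufam))
    scores <- latent[, as.character(fam), drop = FALSE] +
      matrix(stats::rnorm(G * length(drugs), sd = noise_sd), nrow = G)
    dimnames(scores) <- list(gene_universe, drugs)
    if (nrow(planted_effects)) {
      for (i in seq_len(nrow(planted_effects))) {
        genes <- intersect(pathways[[planted_effects$pathway[i]]], gene_universe)
        scores[genes, planted_effects$drug[i]] <-
          scores[genes, planted_effects$drug[i]] + planted_effects$delta[i]
      }
    }
    scores
  })
}

#' Generate a synthetic spontaneous-report table
#'
#' Multinomial model of spontaneous reporting: each report carries exactly one
#' drug (drawn from `drug_weights`) and one preferred term (PT). The PT is
#' drawn from the baseline PT distribution, except for planted (drug, PT)
#' pairs, where that PT's probability is multiplied by `lambda` and the
#' drug-specific PT vector renormalised — so `lambda` is the relative
#' reporting rate the PRR estimates (up to renormalisation).
#'
#' @param n_reports Number of reports (non-negative integer).
#' @param class_drugs,other_drugs Character vectors of in-class and comparator
#'   drug ids; together they define the drug universe (order preserved).
#' @param drug_weights Probability vector over `c(class_drugs, other_drugs)`,
#'   summing to 1 within 1e-9.
#' @param pt_baseline Named probability vector over PTs, summing to 1.
#' @param planted_adr_signals Data frame with columns `drug`, `pt`, `lambda`
#'   (`lambda >= 1`); may have zero rows.
#' @param seed Integer seed.
#' @return Data frame with columns `report_id`, `drug`, `preferred_term`.
#' @export
gen_reports <- function(n_reports, class_drugs, other_drugs, drug_weights,
                        pt_baseline, planted_adr_signals = NULL, seed = 1L) {
  n_reports <- check_count(n_reports, "n_reports", positive = FALSE)
  drugs <- c(class_drugs, other_drugs)
  drug_weights <- check_prob_vector(drug_weights, "drug_weights")
  if (length(drug_weights) != length(drugs)) {
    dpa_error("invalid_parameter",
              "drug_weights length must match the drug universe")
  }
  pt_baseline <- check_prob_vector(pt_baseline, "pt_baseline")
  if (is.null(names(pt_baseline))) {
    names(pt_baseline) <- sprintf("pt_%03d", seq_along(pt_baseline))
  }
  if (is.null(planted_adr_signals)) {
    planted_adr_signals <- data.frame(drug = character(0), pt = character(0),
                                      lambda = numeric(0))
  }
  if (nrow(planted_adr_signals) && any(planted_adr_signals$lambda < 1)) {
    dpa_error("invalid_parameter", "planted lambda must be >= 1")
  }
  pts <- names(pt_baseline)
  empty <- data.frame(report_id = character(0), drug = character(0),
                      preferred_term = character(0))
  if (n_reports == 0L) return(empty)

  # per-drug PT distributions: baseline, with planted multiplicative bumps
  pt_dist <- function(d) {
    p <- pt_baseline
    hit <- planted_adr_signals[planted_adr_signals$drug == d, , drop = FALSE]
    if (nrow(hit)) {
      idx <- match(hit$pt, pts)
      if (anyNA(idx)) {
        dpa_error("unknown_identifier", "planted PT not in pt_baseline")
      }
      p[idx] <- p[idx] * hit$lambda
      p <- p / sum(p)
    }
    p
  }
  with_seed(seed, {
    drug_of <- sample(drugs, n_reports, replace = TRUE, prob = drug_weights)
    pt_of <- character(n_reports)
    for (d in unique(drug_of)) {
      sel <- drug_of == d
      pt_of[sel] <- sample(pts, sum(sel), replace = TRUE, prob = pt_dist(d))
    }
    data.frame(
      report_id = sprintf("r%07d", seq_len(n_reports)),
      drug = drug_of,
      preferred_term = pt_of
    )
  })
}

#' Generate a random surjective PT to HLT mapping
#'
#' Random partition of preferred terms into `n_hlts` higher-level terms; every
#' HLT receives at least one PT and every PT maps to exactly one HLT.
#'
#' @param pts Character vector of preferred-term ids.
#' @param n_hlts Number of higher-level terms, `1 <= n_hlts <= length(pts)`.
#' @param seed Integer seed.
#' @return Named character vector PT -> HLT id.
#' @export
gen_pt_hlt_map <- function(pts, n_hlts, seed = 1L) {
  n_hlts <- check_count(n_hlts, "n_hlts")
  if (n_hlts > length(pts)) {
    dpa_error("invalid_parameter", "n_hlts must not exceed the number of PTs")
  }
  hlts <- sprintf("hlt_%03d", seq_len(n_hlts))
  with_seed(seed, {
    # guarantee surjectivity: one PT pinned to each HLT, rest uniform
    assign <- character(length(pts))
    pinned <- sample(seq_along(pts), n_hlts)
    assign[pinned] <- hlts
    rest <- setdiff(seq_along(pts), pinned)
    if (length(rest)) assign[rest] <- sample(hlts, length(rest), replace = TRUE)
    stats::setNames(assign, pts)
  })
}

#' Bundle planted ground truth for recovery tests
#'
#' @param planted_pathway_effects Data frame `drug`, `pathway`, `delta`.
#' @param planted_adr_signals Data frame `drug`, `pt`, `lambda` (`lambda >= 1`).
#' @param family_assignment Named integer vector drug -> family.
#' @param pt_to_hlt Named character vector PT -> HLT.
#' @return Object of class `ground_truth` (a list of the four components).
#' @export
ground_truth <- function(planted_pathway_effects, planted_adr_signals,
                         family_assignment, pt_to_hlt) {
  if (nrow(planted_adr_signals) && any(planted_adr_signals$lambda < 1)) {
    dpa_error("invalid_parameter", "planted lambda must be >= 1")
  }
  structure(
    list(planted_pathway_effects = planted_pathway_effects,
         planted_adr_signals = planted_adr_signals,
         family_assignment = family_assignment,
         pt_to_hlt = pt_to_hlt),
    class = "ground_truth"
  )
}
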