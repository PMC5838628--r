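# End-to-end orchestration: synthetic inputs -> similarity matrices ->
# Kruskal-Borda consensus -> GSEA -> drug-pathway network -> two-stage PRR
# -> drug-ADR network -> pathway-ADR projection -> metrics -> quadrants.
# One config object, one output directory, one manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Defaults describe a compact
#' synthetic study: 20 drugs in 5 structural families, 500 genes, 40
#' pathways, 50 preferred terms under 10 higher-level terms, 50,000
#' spontaneous reports with the drug class holding 40% of the reporting
#' volume. One drug (`hero_drug`, the first drug of family 1) is constructed
#' as the planted best repurposing candidate: it receives the most planted
#' pathway effects and no planted ADR signal, while several other drugs get
#' strong planted ADR elevations.
#'
#' @param n_families,members_per_family Structural family layout.
#' @param n_genes,n_pathways,pathway_size_min,pathway_size_max Gene/pathway
#'   universe.
#' @param n_pts,n_hlts Preferred / higher-level term universe.
#' @param n_reports Number of synthetic spontaneous reports.
#' @param n_other_drugs Comparator (non-class) drugs in the report universe.
#' @param class_report_share Fraction of reports carrying a class drug.
#' @param family_signal,noise_sd Perturbation-score variance components.
#' @param delta Planted pathway shift in score s.d. units (default 3).
#' @param lambda Planted relative reporting rate (default 10).
#' @param n_hero_pathways Planted pathways for the hero drug.
#' @param n_replicates Replicate profiles per drug merged by Kru-Bor.
#' @param w,n_perm,alpha,min_size,max_size GSEA settings; `n_perm = 50000`
#'   reproduces a full-fidelity analysis, 2000 is the fast test setting.
#' @param seed Integer seed for every random stage.
#' @param dataset Label for the perturbation dataset being emulated.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_families = 5L, members_per_family = 4L,
                            n_genes = 500L, n_pathways = 40L,
                            pathway_size_min = 10L, pathway_size_max = 50L,
                            n_pts = 50L, n_hlts = 10L, n_reports = 50000L,
                            n_other_drugs = 10L, class_report_share = 0.4,
                            family_signal = 1, noise_sd = 1, delta = 3,
                            lambda = 10, n_hero_pathways = 5L,
                            n_replicates = 3L, w = 1, n_perm = 50000L,
                            alpha = 0.1, min_size = 5L, max_size = 500L,
                            seed = 1L, dataset = "cmap-like") {
  cfg <- list(
    n_families = check_count(n_families, "n_families"),
    members_per_family = check_count(members_per_family, "members_per_family"),
    n_genes = check_count(n_genes, "n_genes"),
    n_pathways = check_count(n_pathways, "n_pathways"),
    pathway_size_min = check_count(pathway_size_min, "pathway_size_min"),
    pathway_size_max = check_count(pathway_size_max, "pathway_size_max"),
    n_pts = check_count(n_pts, "n_pts"),
    n_hlts = check_count(n_hlts, "n_hlts"),
    n_reports = check_count(n_reports, "n_reports"),
    n_other_drugs = check_count(n_other_drugs, "n_other_drugs"),
    class_report_share = check_probability(class_report_share,
                                           "class_report_share"),
    family_signal = family_signal, noise_sd = noise_sd,
    delta = delta, lambda = lambda,
    n_hero_pathways = check_count(n_hero_pathways, "n_hero_pathways"),
    n_replicates = check_count(n_replicates, "n_replicates"),
    w = w, n_perm = check_count(n_perm, "n_perm"),
    alpha = alpha, min_size = check_count(min_size, "min_size"),
    max_size = check_count(max_size, "max_size"),
    seed = check_count(seed, "seed"), dataset = dataset
  )
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    dpa_error("invalid_parameter", "alpha must lie in (0, 1)")
  }
  structure(cfg, class = "pipeline_config")
}

# Deterministic sub-seed per named stage so stages can be reproduced in
# isolation; kept below 2^31.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1000003 + sum(utf8ToInt(stage))) %%
               2147483647)
}

#' Generate every pipeline input plus ground truth from a config
#'
#' @param config A `pipeline_config`.
#' @return List with `descriptor_sets`, `pathways`, `scores` (replicate
#'   score matrices), `reports`, `pt2hlt`, `class_drugs`, `other_drugs`,
#'   and `truth` (a `ground_truth`).
#' @export
simulate_inputs <- function(config) {
  cfg <- config
  sets <- gen_descriptor_sets(cfg$n_families, cfg$members_per_family,
                              universe_size = 500L, mutation_rate = 0.1,
                              seed = stage_seed(cfg$seed, "descriptors"))
  drugs <- names(sets)
  fam <- attr(sets, "family_assignment")
  genes <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  pathways <- gen_pathway_collection(cfg$n_pathways, cfg$pathway_size_min,
                                     cfg$pathway_size_max, genes,
                                     seed = stage_seed(cfg$seed, "pathways"))

  # planted pathway effects: the hero drug gets the most planted pathways
  # and no ADR signal; two other drugs get one pathway each so the network
  # is not a single star.
  hero <- drugs[1]
  others_with_effects <- drugs[unique(pmin(c(6L, 11L), length(drugs)))]
  others_with_effects <- setdiff(others_with_effects, hero)
  n_side <- length(others_with_effects)
  if (cfg$n_hero_pathways + n_side > length(pathways)) {
    dpa_error("invalid_parameter",
              "not enough pathways for the planted effects")
  }
  planted_pw <- data.frame(
    drug = c(rep(hero, cfg$n_hero_pathways), others_with_effects),
    pathway = names(pathways)[seq_len(cfg$n_hero_pathways + n_side)],
    delta = cfg$delta
  )
  scores <- lapply(seq_len(cfg$n_replicates), function(r) {
    gen_perturbation_scores(
      drugs, genes, fam, cfg$family_signal, cfg$noise_sd,
      planted_effects = planted_pw, pathways = pathways,
      seed = stage_seed(cfg$seed, paste0("scores", r))
    )
  })

  pts <- sprintf("pt_%03d", seq_len(cfg$n_pts))
  pt_baseline <- stats::setNames(rep(1 / cfg$n_pts, cfg$n_pts), pts)
  pt2hlt <- gen_pt_hlt_map(pts, cfg$n_hlts,
                           seed = stage_seed(cfg$seed, "pt2hlt"))
  other_drugs <- sprintf("other_%02d", seq_len(cfg$n_other_drugs))
  n_class <- length(drugs)
  drug_weights <- c(
    rep(cfg$class_report_share / n_class, n_class),
    rep((1 - cfg$class_report_share) / cfg$n_other_drugs, cfg$n_other_drugs)
  )
  # planted ADR signals: every class drug except the hero carries two
  # drug-specific planted elevations, so the hero is the unique drug with no
  # constructed toxicity and ADR strength separates it from the rest.
  adr_drugs <- setdiff(drugs, hero)
  n_adr_pts <- min(2L * length(adr_drugs), length(pts))
  planted_adr <- data.frame(
    drug = rep(adr_drugs, each = 2L)[seq_len(n_adr_pts)],
    pt = pts[seq_len(n_adr_pts)],
    lambda = cfg$lambda
  )
  reports <- gen_reports(cfg$n_reports, drugs, other_drugs, drug_weights,
                         pt_baseline, planted_adr,
                         seed = stage_seed(cfg$seed, "reports"))
  list(
    descriptor_sets = sets, pathways = pathways, scores = scores,
    reports = reports, pt2hlt = pt2hlt,
    class_drugs = drugs, other_drugs = other_drugs,
    truth = ground_truth(planted_pw, planted_adr, fam, pt2hlt),
    hero_drug = hero
  )
}

#' Run the full analysis pipeline
#'
#' Executes every stage on synthetic inputs generated from `config` and
#' writes all artifacts (TSV tables, GMT, GML graphs, Newick dendrograms and
#' a JSON manifest with config echo and per-file MD5 checksums) to `outdir`.
#' Reruns with the same config and seed produce byte-identical files.
#'
#' @param config A `pipeline_config`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results: `inputs`,
#'   `structural_similarity`, `perturbation_similarity`, `consensus`,
#'   `enrichments`, `g_drug_pathway`, `signals`, `hlt_edges`, `g_drug_adr`,
#'   `g_pathway_adr`, `summaries`, `quadrants`, `manifest`.
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- config
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(outdir, f)
  inputs <- simulate_inputs(cfg)
  message("stage: simulate — ", length(inputs$class_drugs), " class drugs, ",
          nrow(inputs$reports), " reports")
  write_descriptor_sets(inputs$descriptor_sets, out("descriptor_sets.tsv"))
  write_gmt(inputs$pathways, out("pathways.gmt"))
  write_tsv(inputs$reports, out("reports.tsv"))
  write_pt_hlt_map(inputs$pt2hlt, out("pt2hlt.tsv"))

  sim_struct <- structural_similarity_matrix(inputs$descriptor_sets)
  write_matrix_tsv(sim_struct, out("structural_similarity.tsv"), key = "drug")
  write_dendrogram_newick(complete_linkage_clustering(sim_struct),
                          out("structural_dendrogram.nwk"))
  message("stage: chemsim — ", nrow(sim_struct), " x ", ncol(sim_struct),
          " similarity matrix")

  # replicate ranked profiles per drug, merged to a consensus
  consensus <- lapply(inputs$class_drugs, function(d) {
    reps <- lapply(seq_along(inputs$scores), function(r) {
      to_ranked_profile(inputs$scores[[r]][, d], drug_id = d)
    })
    names(reps) <- sprintf("%s_rep%d", d, seq_along(reps))
    kru_bor_merge(reps, drug_id = d)
  })
  names(consensus) <- inputs$class_drugs
  sim_pert <- perturbation_similarity_matrix(consensus)
  write_matrix_tsv(sim_pert, out("perturbation_similarity.tsv"), key = "drug")
  write_dendrogram_newick(complete_linkage_clustering(sim_pert),
                          out("perturbation_dendrogram.nwk"))
  rank_mat <- vapply(consensus, function(p) p$ranks,
                     numeric(consensus[[1]]$G))
  write_matrix_tsv(rank_mat, out("consensus_ranks.tsv"), key = "gene")
  message("stage: merge — ", length(consensus), " consensus profiles")

  enrichments <- do.call(rbind, lapply(inputs$class_drugs, function(d) {
    gsea_run(consensus[[d]], inputs$pathways, w = cfg$w, n_perm = cfg$n_perm,
             alpha = cfg$alpha, min_size = cfg$min_size,
             max_size = cfg$max_size,
             seed = stage_seed(cfg$seed, paste0("gsea_", d)))
  }))
  write_tsv(enrichments, out("enrichments.tsv"))
  message("stage: gsea — ", sum(enrichments$significant),
          " significant drug-pathway calls")

  g_dp <- build_drug_pathway(enrichments, inputs$class_drugs,
                             alpha = cfg$alpha)
  write_gml(g_dp, out("drug_pathway.gml"))

  retained <- stage1_class_signals(inputs$reports, inputs$class_drugs,
                                   c(inputs$class_drugs, inputs$other_drugs))
  signals <- stage2_drug_signals(inputs$reports, inputs$class_drugs, retained)
  write_tsv(signals, out("signals.tsv"))
  hlt_edges <- aggregate_to_hlt(signals, inputs$pt2hlt)
  write_tsv(hlt_edges, out("hlt_edges.tsv"))
  message("stage: signals — ", length(retained), " stage-1 PTs, ",
          nrow(signals), " stage-2 signals")

  g_da <- build_drug_adr(hlt_edges)
  write_gml(g_da, out("drug_adr.gml"))
  g_pa <- project_shared_drugs(g_dp, g_da)
  write_gml(g_pa, out("pathway_adr.gml"))

  graphs <- list(drug_pathway = g_dp, drug_adr = g_da, pathway_adr = g_pa)
  summaries <- do.call(rbind, lapply(names(graphs), function(nm) {
    cbind(network = nm, graph_summary(graphs[[nm]]))
  }))
  write_tsv(summaries, out("network_summaries.tsv"))
  metrics <- do.call(rbind, lapply(names(graphs), function(nm) {
    cbind(network = nm, node_metrics(graphs[[nm]]))
  }))
  write_tsv(metrics, out("node_metrics.tsv"))
  message("stage: metrics — ", nrow(metrics), " node-metric rows")

  degrees <- stats::setNames(
    vapply(inputs$class_drugs, function(d) node_degree(g_dp, d), integer(1)),
    inputs$class_drugs)
  strengths <- stats::setNames(
    vapply(inputs$class_drugs, function(d) {
      if (d %in% g_da$part_one) node_strength(g_da, d) else 0
    }, numeric(1)),
    inputs$class_drugs)
  quadrants <- quadrant_classification(degrees, strengths)
  write_tsv(quadrants, out("quadrants.tsv"))
  message("stage: repurpose — ", sum(quadrants$candidate), " candidates")

  files <- sort(list.files(outdir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    config = unclass(cfg),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("dpanet")),
    stage_rows = list(
      reports = nrow(inputs$reports),
      enrichments = nrow(enrichments),
      significant_enrichments = sum(enrichments$significant),
      stage1_pts = length(retained),
      stage2_signals = nrow(signals),
      hlt_edges = nrow(hlt_edges),
      node_metrics = nrow(metrics),
      candidates = sum(quadrants$candidate)
    ),
    checksums = as.list(tools::md5sum(file.path(outdir, files)))
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(
    inputs = inputs, structural_similarity = sim_struct,
    perturbation_similarity = sim_pert, consensus = consensus,
    enrichments = enrichments, g_drug_pathway = g_dp,
    retained_pts = retained, signals = signals, hlt_edges = hlt_edges,
    g_drug_adr = g_da, g_pathway_adr = g_pa, summaries = summaries,
    quadrants = quadrants, manifest = manifest
  ))
}
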