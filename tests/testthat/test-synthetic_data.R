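# Generators: bookkeeping, determinism, and the statistical structure the
# downstream analysis assumes.

test_that("descriptor sets respect family layout and mutation rate", {
  sets0 <- gen_descriptor_sets(2, 3, 500, mutation_rate = 0, seed = 11)
  expect_length(sets0, 6L)
  fam <- attr(sets0, "family_assignment")
  expect_setequal(unname(fam), rep(1:2, each = 3))
  # no mutation: family members identical, within-family Tanimoto exactly 1
  for (f in 1:2) {
    ids <- names(fam)[fam == f]
    expect_equal(tanimoto_similarity(sets0[[ids[1]]], sets0[[ids[2]]]), 1)
    expect_identical(sets0[[ids[1]]], sets0[[ids[3]]])
  }
  expect_error(gen_descriptor_sets(0, 3, 500, 0.1), class = "invalid_parameter")
  expect_error(gen_descriptor_sets(2, 3, 50, 0.1, set_size = 30),
               class = "invalid_parameter")
})

test_that("within-family Tanimoto exceeds between-family under mutation", {
  withr::with_seed(5, {
    within <- numeric(0); between <- numeric(0)
    for (s in 1:25) {
      sets <- gen_descriptor_sets(3, 2, 500, mutation_rate = 0.1, seed = s)
      fam <- attr(sets, "family_assignment")
      ids <- names(sets)
      for (i in seq_along(ids)[-length(ids)]) {
        for (j in seq.int(i + 1, length(ids))) {
          t <- tanimoto_similarity(sets[[i]], sets[[j]])
          if (fam[ids[i]] == fam[ids[j]]) within <- c(within, t)
          else between <- c(between, t)
        }
      }
    }
    expect_gt(mean(within), mean(between))
    expect_gt(mean(within), 0.5)  # ~ (1-2*0.1) overlap expectation
  })
})

test_that("pathway collection sizes, names and determinism", {
  genes <- sprintf("g%03d", 1:200)
  expect_identical(gen_pathway_collection(0, 5, 10, genes),
                   setNames(list(), character(0)))
  pw <- gen_pathway_collection(15, 5, 5, genes, seed = 3)
  expect_true(all(lengths(pw) == 5))
  expect_false(anyDuplicated(names(pw)) > 0)
  expect_true(all(unlist(pw) %in% genes))
  expect_identical(pw, gen_pathway_collection(15, 5, 5, genes, seed = 3))
  expect_error(gen_pathway_collection(5, 10, 5, genes),
               class = "invalid_parameter")
  expect_error(gen_pathway_collection(5, 10, 300, genes),
               class = "invalid_parameter")
})

test_that("perturbation scores carry family structure and planted shifts", {
  genes <- sprintf("g%04d", 1:1000)
  drugs <- c("d1", "d2")
  # pure noise: ranked profiles essentially uncorrelated
  s0 <- gen_perturbation_scores(drugs, genes, c(d1 = 1L, d2 = 2L),
                                family_signal = 0, noise_sd = 1, seed = 21)
  rho0 <- spearman_similarity(to_ranked_profile(s0[, 1]),
                              to_ranked_profile(s0[, 2]))
  expect_lt(abs(rho0), 0.1)
  # shared family, dominant family signal: near-identical rankings
  s1 <- gen_perturbation_scores(drugs, genes, c(d1 = 1L, d2 = 1L),
                                family_signal = 10, noise_sd = 0.1, seed = 22)
  rho1 <- spearman_similarity(to_ranked_profile(s1[, 1]),
                              to_ranked_profile(s1[, 2]))
  expect_gt(rho1, 0.9)
  # zero shift is identity with the no-planted-effects run
  pw <- list(pA = genes[1:30])
  s2 <- gen_perturbation_scores(drugs, genes, c(d1 = 1L, d2 = 2L), 1, 1,
                                planted_effects = data.frame(
                                  drug = "d1", pathway = "pA", delta = 0),
                                pathways = pw, seed = 23)
  s3 <- gen_perturbation_scores(drugs, genes, c(d1 = 1L, d2 = 2L), 1, 1,
                                seed = 23)
  expect_equal(s2, s3)
  expect_error(
    gen_perturbation_scores(drugs, genes, c(d1 = 1L, d2 = 2L), 1, 1,
                            planted_effects = data.frame(
                              drug = "d1", pathway = "nope", delta = 1),
                            pathways = pw, seed = 1),
    class = "unknown_identifier")
})

test_that("report generator respects counts, weights and planted structure", {
  base <- setNames(rep(0.02, 50), sprintf("pt_%03d", 1:50))
  empty <- gen_reports(0, "c1", "o1", c(0.5, 0.5), base)
  expect_identical(nrow(empty), 0L)
  expect_named(empty, c("report_id", "drug", "preferred_term"))
  one <- gen_reports(5, "c1", character(0), 1, c(only_pt = 1), seed = 2)
  expect_true(all(one$drug == "c1" & one$preferred_term == "only_pt"))
  expect_error(
    gen_reports(10, "c1", "o1", c(0.5, 0.5), base,
                planted_adr_signals = data.frame(drug = "c1", pt = "pt_001",
                                                 lambda = 0.5)),
    class = "invalid_parameter")
  expect_error(gen_reports(10, "c1", "o1", c(0.6, 0.6), base),
               class = "invalid_parameter")
  # determinism
  r1 <- gen_reports(1000, c("c1", "c2"), "o1", c(0.3, 0.3, 0.4), base, seed = 9)
  r2 <- gen_reports(1000, c("c1", "c2"), "o1", c(0.3, 0.3, 0.4), base, seed = 9)
  expect_identical(r1, r2)
})

test_that("report drug marginals match drug_weights (chi-square over seeds)", {
  base <- setNames(rep(0.01, 100), sprintf("pt_%03d", 1:100))
  w <- c(0.05, 0.1, 0.15, 0.2, 0.1, 0.1, 0.1, 0.08, 0.07, 0.05)
  drugs <- sprintf("d%02d", 1:10)
  passes <- 0
  for (s in 1:20) {
    r <- gen_reports(1e5, drugs[1:4], drugs[5:10], w, base, seed = s)
    obs <- table(factor(r$drug, levels = drugs))
    pv <- suppressWarnings(stats::chisq.test(obs, p = w)$p.value)
    if (pv > 0.01) passes <- passes + 1
  }
  expect_gte(passes, 18)
})

test_that("planted reporting elevation yields PRR consistent with lambda", {
  base <- setNames(rep(0.01, 100), sprintf("pt_%03d", 1:100))
  planted <- data.frame(drug = "class_1", pt = "pt_001", lambda = 10)
  r <- gen_reports(2e5, c("class_1", "class_2"), c("other_1", "other_2"),
                   rep(0.25, 4), base, planted, seed = 41)
  cts <- contingency(r, "class_1", "pt_001",
                     c("class_1", "class_2", "other_1", "other_2"))
  est <- prr(cts)
  expect_gt(est, 5); expect_lt(est, 20)
})

test_that("PT to HLT map is a surjective single-valued partition", {
  pts <- sprintf("pt_%03d", 1:30)
  m1 <- gen_pt_hlt_map(pts, 1, seed = 4)
  expect_length(unique(m1), 1L)
  mb <- gen_pt_hlt_map(pts, 30, seed = 4)
  expect_length(unique(mb), 30L)
  m <- gen_pt_hlt_map(pts, 7, seed = 4)
  expect_named(m, pts)
  expect_length(unique(m), 7L)           # surjective
  expect_identical(m, gen_pt_hlt_map(pts, 7, seed = 4))
  expect_error(gen_pt_hlt_map(pts, 0), class = "invalid_parameter")
  expect_error(gen_pt_hlt_map(pts, 31), class = "invalid_parameter")
})
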