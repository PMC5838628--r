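# Bipartite container, network construction and topology metrics against
# brute-force oracles.

k22 <- function() {
  bipartite_graph(c("d1", "d2"), c("p1", "p2"),
                  data.frame(u = c("d1", "d1", "d2", "d2"),
                             v = c("p1", "p2", "p1", "p2")))
}

test_that("constructor enforces the bipartite contract", {
  g <- k22()
  expect_s3_class(g, "bipartite_graph")
  expect_error(bipartite_graph(c("a"), c("a")), class = "invalid_parameter")
  expect_error(
    bipartite_graph("d1", "p1", data.frame(u = c("d1", "d1"),
                                           v = c("p1", "p1"))),
    class = "duplicate_edge")
  expect_error(
    bipartite_graph("d1", "p1", data.frame(u = "p1", v = "d1")),
    class = "invalid_parameter")
})

test_that("drug-pathway network keeps degree-0 drugs, drops silent pathways", {
  enr <- data.frame(
    drug = c("d1", "d1", "d2", "d3"),
    pathway = c("pw1", "pw2", "pw1", "pw3"),
    p_adj = c(0.01, 0.5, 0.05, 0.2)
  )
  g <- build_drug_pathway(enr, drugs = c("d1", "d2", "d3", "d4"), alpha = 0.1)
  expect_setequal(g$part_one, c("d1", "d2", "d3", "d4"))
  expect_setequal(g$part_two, c("pw1"))       # only pathways with an edge
  expect_equal(nrow(g$edges), 2L)
  expect_false(g$weighted)
  none <- build_drug_pathway(enr[enr$p_adj > 0.9, ], drugs = c("d1", "d2"))
  expect_equal(length(none$part_two), 0L)
  expect_equal(nrow(none$edges), 0L)
  expect_error(build_drug_pathway(enr, c("d1"), alpha = 2),
               class = "invalid_parameter")
})

test_that("drug-ADR network carries weights and strength sums them", {
  he <- data.frame(drug = c("d1", "d1", "d2"),
                   hlt = c("H1", "H2", "H1"),
                   weight = c(2.5, 3.5, 1.5))
  g <- build_drug_adr(he)
  expect_true(g$weighted)
  expect_equal(node_strength(g, "d1"), 6.0)
  expect_equal(node_strength(g, "H1"), 4.0)
  expect_error(build_drug_adr(rbind(he, he[1, ])), class = "duplicate_edge")
})

test_that("density follows the printed-count identity", {
  expect_equal(bipartite_density(k22()), 1)
  g <- bipartite_graph(c("d1", "d2", "d3"), c("p1", "p2"),
                       data.frame(u = "d1", v = "p1"))
  expect_equal(bipartite_density(g), 1 / 6)
  expect_error(bipartite_density(bipartite_graph("d1", character(0))),
               class = "undefined_density")
})

test_that("pairwise and node clustering coefficients on hand cases", {
  g <- k22()
  expect_equal(pairwise_cc(g, "d1", "d2"), 1)
  expect_equal(node_cc(g, "d1"), 1)
  expect_equal(node_cc(g, "p1"), 1)
  star <- bipartite_graph("d1", c("p1", "p2", "p3"),
                          data.frame(u = "d1", v = c("p1", "p2", "p3")))
  expect_equal(node_cc(star, "d1"), 0)   # empty second neighbourhood
  expect_equal(node_cc(star, "p1"), 1)   # p2, p3 have identical neighbourhood
  tri <- bipartite_graph(c("d1", "d2"), c("pa", "pb", "pc"),
                         data.frame(u = c("d1", "d1", "d2", "d2"),
                                    v = c("pa", "pb", "pb", "pc")))
  expect_equal(pairwise_cc(tri, "d1", "d2"), 1 / 3)
  expect_error(pairwise_cc(tri, "d1", "pa"), class = "incompatible_nodes")
  expect_error(node_cc(tri, "nope"), class = "unknown_node")
})

test_that("redundancy on hand cases", {
  expect_equal(redundancy(k22(), "d1"), 1)
  path <- bipartite_graph(c("d1", "d2"), "hA",
                          data.frame(u = c("d1", "d2"), v = c("hA", "hA")))
  expect_equal(redundancy(path, "hA"), 0)
  expect_true(is.na(redundancy(path, "d1")))  # degree 1 -> undefined
})

test_that("components: sizes, order and singletons", {
  g <- bipartite_graph(c("d1", "d2", "d3"), c("p1", "p2"),
                       data.frame(u = c("d1", "d1", "d2", "d2"),
                                  v = c("p1", "p2", "p1", "p2")))
  comps <- connected_components(g)
  expect_length(comps, 2L)
  expect_equal(lengths(comps), c(4L, 1L))
  expect_equal(comps[[2]], "d3")
  empty_edges <- bipartite_graph(c("d1", "d2"), c("p1", "p2"))
  expect_length(connected_components(empty_edges), 4L)
})

test_that("metrics match brute-force oracles on random graphs", {
  skip_if_not_installed("igraph")
  withr::with_seed(53, {
    for (i in 1:40) {
      g <- random_bipartite(sample(3:6, 1), sample(3:6, 1), runif(1, 0.2, 0.7))
      nodes <- c(g$part_one, g$part_two)
      for (v in nodes) {
        expect_equal(node_cc(g, v), oracle_node_cc(g, v))
        expect_equal(redundancy(g, v), oracle_redundancy(g, v))
      }
      expect_identical(connected_components(g), oracle_components_igraph(g))
      # degree-sum identity
      deg1 <- sum(vapply(g$part_one, function(v) node_degree(g, v), integer(1)))
      deg2 <- sum(vapply(g$part_two, function(v) node_degree(g, v), integer(1)))
      expect_equal(deg1, nrow(g$edges))
      expect_equal(deg2, nrow(g$edges))
    }
  })
})

test_that("projection counts shared drugs and matches the triple loop", {
  g_dp <- bipartite_graph(c("d1", "d2"), "pw1",
                          data.frame(u = c("d1", "d2"), v = c("pw1", "pw1")))
  g_da <- bipartite_graph(c("d1", "d2"), "hA",
                          data.frame(u = c("d1", "d2"), v = c("hA", "hA")))
  proj <- project_shared_drugs(g_dp, g_da)
  expect_equal(proj$edges$weight, 2)
  one <- project_shared_drugs(
    bipartite_graph("d1", "pw1", data.frame(u = "d1", v = "pw1")), g_da)
  expect_equal(one$edges$weight, 1)
  withr::with_seed(59, {
    for (i in 1:25) {
      drugs <- sprintf("d%02d", 1:5)
      gp <- bipartite_graph(drugs, sprintf("pw%d", 1:4),
                            expand.grid(u = drugs, v = sprintf("pw%d", 1:4),
                                        stringsAsFactors = FALSE)[
                              runif(20) < 0.4, ])
      ga <- bipartite_graph(drugs, sprintf("h%d", 1:4),
                            expand.grid(u = drugs, v = sprintf("h%d", 1:4),
                                        stringsAsFactors = FALSE)[
                              runif(20) < 0.4, ])
      proj <- project_shared_drugs(gp, ga)
      oracle <- oracle_projection(gp, ga)
      got <- proj$edges[order(proj$edges$u, proj$edges$v), ]
      rownames(got) <- rownames(oracle) <- NULL
      expect_equal(got, oracle)
      # weight bound by the two degrees
      for (k in seq_len(nrow(got))) {
        expect_lte(got$weight[k],
                   min(node_degree(gp, got$u[k]), node_degree(ga, got$v[k])))
      }
    }
  })
})

test_that("graph summary ties the pieces together", {
  s <- graph_summary(k22())
  expect_equal(unname(unlist(s)), c(2, 2, 4, 1, 1, 1))
  withr::with_seed(61, {
    g <- random_bipartite(5, 6, 0.3)
    s <- graph_summary(g)
    expect_equal(s$density, bipartite_density(g))
    nm <- node_metrics(g)
    expect_equal(s$mean_cc_part_one, mean(nm$cc[nm$part == "one"]))
  })
})

test_that("degree CCDF starts at 1 and is non-increasing", {
  withr::with_seed(67, {
    g <- random_bipartite(6, 5, 0.4)
    cc <- degree_ccdf(g, "one")
    expect_equal(cc$ccdf[1], 1)
    expect_true(all(diff(cc$ccdf) <= 0))
  })
})
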