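Package: dpanet
Title: Drug-Pathway-ADR Bipartite Network Pharmacology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Network-pharmacology analysis of a drug class through tripartite
    drug-pathway-adverse-reaction relationships. Builds structural (Tanimoto on
    atom-pair descriptor sets) and gene-perturbation (Spearman on ranked
    profiles) drug-drug similarity matrices with complete-linkage clustering;
    merges replicate perturbation profiles into consensus rankings with the
    Kruskal-Borda algorithm; links drugs to pathways by preranked permutation
    gene set enrichment analysis with Benjamini-Hochberg adjustment; links
    drugs to adverse-event terms by two-stage proportional reporting ratio
    (PRR) signal detection over spontaneous-report tables, aggregated from
    preferred terms to higher-level terms; projects the two bipartite networks
    onto a weighted pathway-ADR network; computes bipartite topology metrics
    (degree, density, Latapy clustering coefficient, redundancy coefficient,
    node strength, connected components); and classifies drugs into
    median-split quadrants of pathway degree versus ADR node strength to
    prioritise repurposing candidates. Ships a synthetic-data generator with
    planted ground truth for recovery testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    fgsea,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
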