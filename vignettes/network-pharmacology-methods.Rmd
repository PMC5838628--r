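---
title: "Methods: drug-pathway-ADR network construction and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-pathway-ADR network construction and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`dpanet` models a drug class as three coupled bipartite networks —
drug-pathway, drug-ADR, and their pathway-ADR projection — and derives a
repurposing prioritisation from their topology. This vignette documents the
statistical procedures, the tunable parameters and their defaults, the
synthetic-data model used to validate the pipeline, and the numerical and
design choices a maintainer should know about.

# Similarity and consensus profiles

Structural similarity between two drugs is the set Tanimoto coefficient on
atom-pair descriptor codes, treated as presence/absence sets rather than
counted multisets. The counted variant weights repeated substructures more
heavily; the set form keeps the core free of any chemistry toolkit and is
the natural match for a Jaccard-style coefficient. An optional upstream
adapter can supply descriptor sets from SMILES, but the package consumes
precomputed descriptor TSVs.

Perturbation similarity is Spearman's rho between ranked genome-wide
profiles. Rank 1 is the most up-regulated gene throughout the package; the
GSEA gene-level statistic depends on this convention, so it is fixed
globally. Ties receive average ranks, and every profile is stored sorted by
gene identifier so that serialisation is reproducible.

When a drug has replicate profiles (cell lines, doses, batches), they are
merged into one consensus by Kruskal-Borda aggregation: repeatedly find the
pair of profiles with the smallest Spearman footrule distance
(sum of absolute rank differences) and replace it by its Borda merge — the
ranking of summed ranks, ties averaged — until one profile remains. Ties in
the footrule distance are broken by the lexicographically smallest pair of
profile labels, and a merged profile is labelled by joining its
constituents' labels in sorted order, which makes the whole merge tree
deterministic. Distinct datasets (CMap-style and LINCS-style) are processed
independently end to end: profiles from different gene universes never mix,
and the operations refuse profiles whose universes differ.

Hierarchical clustering of either similarity matrix uses complete linkage
on the dissimilarity 1 - similarity, the simplest order-preserving
monotone transform. Items are sorted lexicographically before clustering so
leaf order does not depend on input order.

# Drug-pathway network: preranked permutation GSEA

Each drug's consensus profile is linked to pathways by preranked GSEA. The
gene-level statistic is the centred negated rank
s(g) = (G+1)/2 - r(g), symmetric about zero; the enrichment score of a
gene set is the maximal signed deviation of the running sum that increments
by |s|^w / N_R at in-set genes and decrements by 1/(G - N_H) otherwise.
Parameters and defaults:

* **w = 1** (classic GSEA weighting). With w = 0 every hit counts equally.
* **Null distribution**: gene permutation — random same-size gene subsets —
  because ranked consensus profiles have no sample-level replicates to
  permute. The p-value is one-sided on the observed sign with an add-one
  estimator, p = (1 + k)/(1 + m), where m counts same-sign null scores and
  k the same-sign scores at least as extreme; this floors p at
  1/(1 + n_perm) and avoids zero p-values. If no null draw shares the
  observed sign, p is reported at the floor with a degenerate-null flag.
* **n_perm**: 50,000 for a full-fidelity analysis; the test and example
  configurations use 2,000, which keeps the p floor (5e-4) well below the
  significance threshold after adjustment across typical collection sizes.
* **Set-size bounds**: gene sets are intersected with the profile's
  universe and retained when the effective size is in [5, 500] — the usual
  convention that prevents degenerate enrichment scores.
* **Multiplicity**: Benjamini-Hochberg within each drug's run (one analysis
  per drug), not pooled across drugs. An edge requires adjusted p < 0.1.

Two numerical details matter. First, when the maximal positive and negative
deviations of the running sum tie in magnitude, the positive one is
returned; the comparison carries a 1e-12 cushion so the choice cannot flip
on floating-point jitter between the two internal ES code paths (a full
cumulative sum for observed scores, an O(N_H) hit-position walk for the
permutation null). Second, the comparison "at least as extreme" in the
p-value uses the same cushion, so a null score numerically equal to the
observed one always counts.

The drug-pathway graph keeps every analysed drug as a node even with no
significant pathway (degree 0), while pathways appear only when significant
for at least one drug. The density denominator therefore includes
disconnected drugs — this is the convention under which the published
node/edge counts reproduce their printed densities exactly.

# Drug-ADR network: two-stage PRR

The proportional reporting ratio of an event given an exposure is
PRR = (a/(a+b)) / (c/(c+d)) on report-level 2x2 counts. Stage 1 computes,
for every preferred term, the PRR of the drug class against the comparator
drugs in scope and keeps terms with a defined PRR strictly greater than 1.
Stage 2 recomputes the PRR for each (class drug, retained PT) pair using
the other class drugs as the comparator and again keeps strict PRR > 1.
Choices:

* Strict inequality, no confidence-interval or chi-square criterion and no
  continuity correction: PRR undefined (no exposed reports, or event absent
  in the comparator) is excluded and logged rather than patched.
* No multiplicity control at stage 2.
* Each report carries one drug and one PT (multi-PT tables are accepted;
  report identity then defines the exposure denominators).
* The stage-1 scope is an explicit parameter (class plus whichever
  comparator drugs the analyst includes).

Signals are grouped by the HLT of their PT; a drug-HLT edge exists when at
least one contributing PT has PRR > 1 and its weight is the sum of the
contributing PRRs. Only supra-threshold PTs contribute to the weight, which
keeps the weight a sum of signals consistent with the edge-existence rule.
Note that a PRR threshold of 1 is a disproportionality direction, not an
error-control boundary: with no true signal, roughly half of all tested
pairs fall above 1, so the drug-ADR network is expected to be dense with
weak noise edges, and downstream interpretation rests on the weights.

# Topology metrics and projection

For bipartite graphs the clustering coefficient of a node u is the mean
Jaccard overlap between N(u) and N(v) over all nodes v at distance 2 (the
Latapy bipartite coefficient); nodes with an empty second neighbourhood get
0 rather than NA so that part-level means are defined over all nodes
(including degree-0 drugs — the alternative, excluding them, is documented
but not used). The redundancy coefficient of v is the fraction of its
neighbour pairs that remain connected through some other node if v is
removed; it requires degree >= 2 and is NA (excluded from averages)
otherwise. Strength is the sum of adjacent edge weights, equalling degree
on unweighted graphs. Components are reported sorted by size, ties by
smallest label. Degree distributions are exported as complementary
cumulative frequencies.

The pathway-ADR projection connects a pathway and an HLT when at least one
drug links to both; the weight is the number of such shared drugs, bounded
above by the smaller of the two degrees.

# Repurposing quadrants

Drugs present in both the drug-pathway and drug-ADR networks are placed on
(ADR strength, pathway degree) axes split at their medians over that
intersection. Candidates are strictly above the degree median and strictly
below the strength median; drugs exactly on either median are labelled
`boundary` and never candidates, since the quadrant scheme defines no tie
rule and a strict rule is invariant under monotone transforms of either
axis. The classification depends only on ranks relative to the medians.

# The synthetic-data model

The generators produce inputs with exactly the structure the analysis
assumes, plus planted ground truth:

* **Descriptor sets**: families share a lead set of 30 codes from a
  universe of >= 10x the set size; members independently replace each code
  with probability `mutation_rate` (default 0.1), giving within-family
  Tanimoto well above between-family values for rates below 0.5.
* **Perturbation scores**: gene score = family latent component (s.d.
  `family_signal`) + independent gaussian noise (s.d. `noise_sd`) + a shift
  `delta` on every gene of each planted (drug, pathway) pair. Scores are
  continuous and ranked downstream. The planted shift of 3 noise s.d. on a
  30-gene pathway in a 1000-gene universe is the recovery condition used
  throughout the tests.
* **Reports**: multinomial — each report draws one drug from `drug_weights`
  and one PT from the baseline PT distribution, with planted (drug, PT)
  pairs multiplying that PT's probability by `lambda >= 1` and
  renormalising. The multiplicative-with-renormalisation form maps directly
  onto the relative reporting rate that the PRR estimates when baseline PT
  probabilities are small; with `lambda = 10` on a 0.005-baseline PT the
  downstream PRR estimate concentrates near 10. One drug per report
  (multi-ingredient products excluded from scope).
* **PT-to-HLT map**: a surjective random partition; one PT is pinned to
  each HLT before the rest are assigned uniformly.

All generators are deterministic given (parameters, seed); seeding is local
to each call and never leaks into the caller's RNG stream.

The default end-to-end configuration (`pipeline_config()`) describes a
compact study: 20 drugs in 5 structural families, 500 genes, 40 pathways of
10-50 genes, 50 PTs under 10 HLTs, 50,000 reports with the class holding
40% of reporting volume, 3 replicate profiles per drug. One drug — the
first drug of family 1 — is constructed as the planted best repurposing
candidate: it carries the most planted pathway effects (5 pathways) and is
the only class drug with no planted ADR elevation, while every other class
drug carries two drug-specific planted elevations at `lambda = 10`. That
contrast is what makes ADR node strength separate the constructed candidate
from the rest; without it, a no-toxicity drug would be statistically
exchangeable with its neighbours under reporting noise. Test and example
runs scale this configuration down (12 drugs, 300 genes, 20 pathways,
20,000 reports, 300-2,000 permutations) to keep the suite fast; the
vignette states these sizes as the package's validation choices.

What the synthetic model deliberately does not emulate: real chemistry (no
SMILES), the real MedDRA vocabulary, reporting biases
(under/stimulated reporting, duplicates), report time stamps, multi-drug
reports, and batch or cell-line structure in expression. Passing recovery
tests therefore demonstrates the pipeline's statistical machinery under its
own assumptions, not robustness to the messiness of FAERS or CMap/LINCS
data.

# Degenerate inputs and error behaviour

Empty descriptor sets, profiles over mismatched universes, gene sets empty
after intersection (or covering the whole universe), all-zero in-set
statistics at w > 0, undefined PRRs, unmapped PTs, duplicate edges and
empty node parts all raise classed errors (`dpa_error` conditions) rather
than propagating NaNs; undefined redundancy (degree < 2) is NA and excluded
from summaries. Pathway collections may legitimately be empty only at
generation time (`n_pathways = 0`).

# Known limitations

* The permutation GSEA is the plain estimator, not an adaptive multilevel
  scheme, so very small p-values cost O(n_perm) work per set.
* Kruskal-Borda merging is O(k^2) in the number of replicate profiles per
  drug — fine for the handfuls of replicates it is meant for.
* The two-stage PRR procedure inherits the PRR's lack of error control;
  the package reports weights, not calibrated probabilities.
* The quadrant scheme is an illustration-grade prioritisation: it ranks
  nothing within the candidate quadrant.
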