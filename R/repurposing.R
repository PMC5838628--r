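# Median-quadrant drug prioritisation: pathway degree (therapeutic
# potential, y axis) against ADR node strength (toxicity risk, x axis),
# each axis split at its median over the drugs present in both networks.

#' Classify drugs into median quadrants of pathway degree versus ADR strength
#'
#' Only drugs present in both maps are classified; the medians are computed
#' over that intersection. Quadrants use strict inequalities, so a drug
#' sitting exactly on either median is labelled `boundary` and is never a
#' candidate. Repurposing candidates are the `upper_left` drugs: pathway
#' degree above the median (many alternative therapeutic targets) and ADR
#' strength below it (low overall side-effect risk).
#'
#' @param degrees Named numeric vector drug -> degree in the drug-pathway
#'   network.
#' @param strengths Named numeric vector drug -> node strength in the
#'   drug-ADR network.
#' @return Data frame `drug`, `pathway_degree`, `adr_strength`, `quadrant`
#'   (one of upper_left, upper_right, lower_left, lower_right, boundary) and
#'   `candidate`; medians in attributes `median_degree`, `median_strength`.
#' @export
quadrant_classification <- function(degrees, strengths) {
  common <- intersect(names(degrees), names(strengths))
  if (!length(common)) {
    dpa_error("no_common_drugs", "no drug present in both networks")
  }
  common <- sort(common)
  k <- as.numeric(degrees[common])
  s <- as.numeric(strengths[common])
  med_k <- stats::median(k)
  med_s <- stats::median(s)
  quadrant <- ifelse(
    k == med_k | s == med_s, "boundary",
    ifelse(k > med_k,
           ifelse(s < med_s, "upper_left", "upper_right"),
           ifelse(s < med_s, "lower_left", "lower_right"))
  )
  out <- data.frame(
    drug = common,
    pathway_degree = k,
    adr_strength = s,
    quadrant = quadrant,
    candidate = quadrant == "upper_left"
  )
  attr(out, "median_degree") <- med_k
  attr(out, "median_strength") <- med_s
  out
}
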