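# Two-stage proportional reporting ratio (PRR) signal detection over
# spontaneous-report tables, and aggregation of preferred-term (PT) signals
# into weighted drug-HLT associations.

check_reports <- function(reports) {
  need <- c("report_id", "drug", "preferred_term")
  if (!all(need %in% names(reports))) {
    dpa_error("invalid_parameter", sprintf(
      "report table must have columns %s", paste(need, collapse = ", ")))
  }
  reports
}

#' 2x2 contingency counts for one event against an exposure set
#'
#' Report-level counting within a scope of drugs: `a` = reports of an exposed
#' drug mentioning the event, `b` = exposed without the event, `c` =
#' non-exposed with the event, `d` = non-exposed without. Each in-scope
#' report contributes to exactly one cell.
#'
#' @param reports Report table (`report_id`, `drug`, `preferred_term`).
#' @param exposure Character vector of exposed drug ids.
#' @param event A single preferred-term id.
#' @param scope Character vector of drug ids defining the comparison universe
#'   (reports outside it are ignored).
#' @return Named integer vector `c(a, b, c, d)`.
#' @export
contingency <- function(reports, exposure, event, scope) {
  check_reports(reports)
  if (!all(exposure %in% scope)) {
    dpa_error("invalid_scope", "exposure drugs must be contained in scope")
  }
  r <- reports[reports$drug %in% scope, , drop = FALSE]
  exposed <- r$drug %in% exposure
  has_event <- r$preferred_term == event
  c(a = sum(exposed & has_event), b = sum(exposed & !has_event),
    c = sum(!exposed & has_event), d = sum(!exposed & !has_event))
}

#' Proportional reporting ratio
#'
#' `PRR = (a / (a + b)) / (c / (c + d))`: the event's reporting proportion
#' among exposed reports relative to non-exposed reports. Undefined (NA,
#' with attribute `undefined_reason`) when `a + b = 0` (no exposed reports)
#' or `c = 0` (event never reported in the comparator); no continuity
#' correction is applied.
#'
#' @param counts Named vector with elements `a`, `b`, `c`, `d`.
#' @return PRR (non-negative), or `NA` when undefined.
#' @export
prr <- function(counts) {
  a <- counts[["a"]]; b <- counts[["b"]]
  cc <- counts[["c"]]; d <- counts[["d"]]
  if (any(c(a, b, cc, d) < 0)) {
    dpa_error("invalid_parameter", "contingency counts must be non-negative")
  }
  if (a + b == 0) {
    return(structure(NA_real_, undefined_reason = "no exposed reports"))
  }
  if (cc == 0) {
    return(structure(NA_real_, undefined_reason = "event absent in comparator"))
  }
  (a / (a + b)) / (cc / (cc + d))
}

# Vectorised PRR over all PTs for a fixed exposure/scope split; used by both
# stages so the per-PT arithmetic is identical to contingency() + prr().
prr_all_pts <- function(reports, exposure, scope) {
  r <- reports[reports$drug %in% scope, , drop = FALSE]
  exposed <- r$drug %in% exposure
  pts <- sort(unique(r$preferred_term))
  a <- table(factor(r$preferred_term[exposed], levels = pts))
  c_ <- table(factor(r$preferred_term[!exposed], levels = pts))
  n_exp <- sum(exposed); n_non <- sum(!exposed)
  data.frame(
    pt = pts,
    a = as.integer(a), b = n_exp - as.integer(a),
    c = as.integer(c_), d = n_non - as.integer(c_),
    PRR = ifelse(n_exp == 0 | as.integer(c_) == 0, NA_real_,
                 (as.integer(a) / n_exp) / (as.integer(c_) / n_non))
  )
}

#' Stage 1: class-level ADR screen
#'
#' PRR of every preferred term for the drug class against the remaining
#' drugs in scope; terms with a defined PRR strictly greater than 1 — events
#' reported disproportionately often under the class — are retained for the
#' drug-level stage.
#'
#' @param reports Report table.
#' @param class_drugs Drugs of the class under study.
#' @param all_drugs Full drug scope (must strictly contain `class_drugs`).
#' @return Character vector of retained PT ids, with the full per-PT table in
#'   attribute `screen`.
#' @export
stage1_class_signals <- function(reports, class_drugs, all_drugs) {
  check_reports(reports)
  if (!length(class_drugs) || !length(all_drugs)) {
    dpa_error("invalid_parameter", "drug lists must be non-empty")
  }
  if (!all(class_drugs %in% all_drugs) ||
      length(setdiff(all_drugs, class_drugs)) == 0L) {
    dpa_error("no_comparator",
              "class_drugs must be a strict subset of all_drugs")
  }
  tab <- prr_all_pts(reports, class_drugs, all_drugs)
  keep <- !is.na(tab$PRR) & tab$PRR > 1
  structure(tab$pt[keep], screen = tab)
}

#' Stage 2: drug-level ADR signals within the class
#'
#' For every (class drug, retained PT) pair, the PRR of the PT for that drug
#' against the other class drugs only; pairs with a defined PRR strictly
#' greater than 1 become signal records. Undefined PRRs are excluded and
#' reported in attribute `excluded`.
#'
#' @param reports Report table.
#' @param class_drugs At least two class drugs (the within-class comparator).
#' @param retained_pts Non-empty PT ids from [stage1_class_signals()].
#' @return Data frame `drug`, `pt`, `a`, `b`, `c`, `d`, `PRR` (all PRR > 1).
#' @export
stage2_drug_signals <- function(reports, class_drugs, retained_pts) {
  check_reports(reports)
  if (length(class_drugs) < 2L) {
    dpa_error("no_comparator", "need at least two class drugs for stage 2")
  }
  if (!length(retained_pts)) {
    dpa_error("invalid_parameter", "retained_pts must be non-empty")
  }
  rows <- list()
  excluded <- list()
  for (d in sort(unique(class_drugs))) {
    tab <- prr_all_pts(reports, d, class_drugs)
    tab <- tab[tab$pt %in% retained_pts, , drop = FALSE]
    if (!nrow(tab)) next
    tab <- cbind(drug = d, tab)
    ok <- !is.na(tab$PRR) & tab$PRR > 1
    rows[[d]] <- tab[ok, , drop = FALSE]
    excluded[[d]] <- tab[is.na(tab$PRR), c("drug", "pt"), drop = FALSE]
  }
  if (length(rows)) {
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    out <- data.frame(drug = character(0), pt = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), PRR = numeric(0))
  }
  if (length(excluded)) {
    attr(out, "excluded") <-
      do.call(rbind, c(excluded, list(make.row.names = FALSE)))
  }
  out
}

#' Aggregate drug-PT signals into weighted drug-HLT edges
#'
#' Signals are grouped by (drug, HLT of the PT); an edge's weight is the sum
#' of the PRRs of its contributing PTs (all above 1 by construction), and the
#' contributing PTs are carried along.
#'
#' @param signals Output of [stage2_drug_signals()].
#' @param pt2hlt Named character vector PT -> HLT; every signal PT must map.
#' @return Data frame `drug`, `hlt`, `weight`, `n_pts`, `pts`
#'   (comma-separated contributing PTs).
#' @export
aggregate_to_hlt <- function(signals, pt2hlt) {
  if (!nrow(signals)) {
    return(data.frame(drug = character(0), hlt = character(0),
                      weight = numeric(0), n_pts = integer(0),
                      pts = character(0)))
  }
  unmapped <- setdiff(signals$pt, names(pt2hlt))
  if (length(unmapped)) {
    dpa_error("unmapped_term", sprintf(
      "PTs without an HLT mapping: %s", paste(unmapped, collapse = ", ")))
  }
  hlt <- pt2hlt[signals$pt]
  key <- paste(signals$drug, hlt, sep = "\r")
  split_idx <- split(seq_len(nrow(signals)), key)
  out <- do.call(rbind, lapply(split_idx, function(ix) {
    data.frame(drug = signals$drug[ix[1]], hlt = unname(hlt[ix[1]]),
               weight = sum(signals$PRR[ix]), n_pts = length(ix),
               pts = paste(sort(signals$pt[ix]), collapse = ","))
  }))
  out <- out[order(out$drug, out$hlt), , drop = FALSE]
  rownames(out) <- NULL
  out
}
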