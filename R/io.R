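# Readers and writers for the interchange formats: TSV tables, descriptor
# sets, score matrices, GMT gene-set collections, GML graphs, Newick
# dendrograms. All tabular output is tab-separated UTF-8 with a header row;
# all writers are deterministic (sorted records) so reruns are
# byte-identical.

#' Write / read a generic TSV table
#'
#' @param x Data frame.
#' @param path File path.
#' @return `path` (writer, invisibly) or a data frame (reader).
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) {
    dpa_error("io_error", sprintf("file not found: %s", path))
  }
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "")
}

#' Write / read descriptor sets
#'
#' One line per drug: `drug_id TAB comma-separated descriptor codes`.
#'
#' @param sets Named list of descriptor-code vectors.
#' @param path File path.
#' @return `path` (writer) or a named list (reader).
#' @export
write_descriptor_sets <- function(sets, path) {
  df <- data.frame(
    drug_id = names(sets),
    codes = vapply(sets, function(s) paste(sort(unique(s)), collapse = ","),
                   character(1))
  )
  write_tsv(df[order(df$drug_id), ], path)
}

#' @rdname write_descriptor_sets
#' @export
read_descriptor_sets <- function(path) {
  df <- read_tsv(path)
  stats::setNames(strsplit(df$codes, ",", fixed = TRUE), df$drug_id)
}

#' Write / read a numeric matrix (scores, ranks or similarities)
#'
#' Genes-by-drugs (or ids-by-ids) matrix with row names in the first column.
#'
#' @param m Numeric matrix with dimnames.
#' @param path File path.
#' @param key Name of the first (row-name) column.
#' @return `path` (writer) or a matrix (reader).
#' @export
write_matrix_tsv <- function(m, path, key = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- key
  write_tsv(df, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read / write a GMT gene-set collection
#'
#' One set per line: `name TAB description TAB gene1 TAB gene2 ...`.
#' Duplicate genes within a line are collapsed; empty lines are skipped.
#'
#' @param path File path.
#' @param collection Named list of gene-id vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @return Named list of gene sets with a `descriptions` attribute (reader),
#'   or `path` (writer).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    dpa_error("io_error", sprintf("file not found: %s", path))
  }
  lines <- readLines(path, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    dpa_error("format_error", sprintf(
      "GMT line %d has fewer than 3 fields", which(keep)[short[1]]))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(fields, `[`, character(1), 2L), names(sets))
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(collection, "descriptions")
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("na", length(collection)),
                                    names(collection))
  }
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, descriptions[[nm]], unique(collection[[nm]])),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write / read a bipartite graph in GML
#'
#' Nodes carry `label` and `part` ("one"/"two") attributes; edges carry
#' `weight`. Node and edge records are emitted in sorted label order so the
#' file is byte-identical across runs.
#'
#' @param g A `bipartite_graph`.
#' @param path File path.
#' @return `path` (writer) or a `bipartite_graph` (reader).
#' @export
write_gml <- function(g, path) {
  labels <- c(g$part_one, g$part_two)
  parts <- c(rep("one", length(g$part_one)), rep("two", length(g$part_two)))
  id_of <- stats::setNames(seq_along(labels) - 1L, labels)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("graph [", "  directed 0",
               sprintf("  name \"%s\"", g$name)), con)
  for (i in seq_along(labels)) {
    writeLines(sprintf(
      "  node [\n    id %d\n    label \"%s\"\n    part \"%s\"\n  ]",
      id_of[[labels[i]]], labels[i], parts[i]), con)
  }
  e <- g$edges
  if (nrow(e)) {
    for (i in seq_len(nrow(e))) {
      writeLines(sprintf(
        "  edge [\n    source %d\n    target %d\n    weight %s\n  ]",
        id_of[[e$u[i]]], id_of[[e$v[i]]],
        format(e$weight[i], digits = 15)), con)
    }
  }
  writeLines("]", con)
  invisible(path)
}

#' @rdname write_gml
#' @export
read_gml <- function(path) {
  if (!file.exists(path)) {
    dpa_error("io_error", sprintf("file not found: %s", path))
  }
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  grab <- function(block, key) {
    hit <- grep(paste0("^", key, " "), block, value = TRUE)[1]
    sub("^\"(.*)\"$", "\\1", sub(paste0("^", key, " "), "", hit))
  }
  blocks <- function(kind) {
    starts <- which(lines == paste(kind, "["))
    lapply(starts, function(s) {
      e <- s
      while (lines[e] != "]") e <- e + 1L
      lines[(s + 1L):(e - 1L)]
    })
  }
  nodes <- blocks("node")
  ids <- vapply(nodes, grab, character(1), "id")
  labels <- vapply(nodes, grab, character(1), "label")
  parts <- vapply(nodes, grab, character(1), "part")
  label_of <- stats::setNames(labels, ids)
  edges_raw <- blocks("edge")
  edges <- if (length(edges_raw)) {
    data.frame(
      u = label_of[vapply(edges_raw, grab, character(1), "source")],
      v = label_of[vapply(edges_raw, grab, character(1), "target")],
      weight = as.numeric(vapply(edges_raw, grab, character(1), "weight"))
    )
  } else {
    data.frame(u = character(0), v = character(0), weight = numeric(0))
  }
  g_name <- grab(lines, "name")
  bipartite_graph(labels[parts == "one"], labels[parts == "two"],
                  edges, name = if (is.na(g_name)) "bipartite" else g_name)
}

#' Write / read a PT-to-HLT mapping
#'
#' @param pt2hlt Named character vector PT -> HLT.
#' @param path File path.
#' @return `path` (writer) or a named character vector (reader).
#' @export
write_pt_hlt_map <- function(pt2hlt, path) {
  df <- data.frame(preferred_term = names(pt2hlt), hlt = unname(pt2hlt))
  write_tsv(df[order(df$preferred_term), ], path)
}

#' @rdname write_pt_hlt_map
#' @export
read_pt_hlt_map <- function(path) {
  df <- read_tsv(path)
  stats::setNames(df$hlt, df$preferred_term)
}
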