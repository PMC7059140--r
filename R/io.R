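#' Read gene-term annotation pairs from a two-column TSV
#'
#' Accepts a plain two-column file (`gene<TAB>term`), with or without a header
#' row; a header is detected when the second field of the first line does not
#' look like a term identifier and the line repeats no data row.
#'
#' @param path Path to the TSV file.
#' @param release_tag Optional release label stored on the result.
#' @return Annotation set tibble (`gene`, `term`).
#' @export
read_annotation_pairs <- function(path, release_tag = NULL) {
  tab <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(tab) < 2) abort("read_annotation_pairs: expected two columns")
  header_words <- c("gene", "gene_id", "symbol", "term", "term_id", "go_id")
  if (tolower(tab[[1]][1]) %in% header_words ||
      tolower(tab[[2]][1]) %in% header_words) {
    tab <- tab[-1, ]
  }
  annotation_set(tab[[1]], tab[[2]], release_tag = release_tag)
}

#' Read annotations from a GAF 2.x file
#'
#' Uses column 2 (DB Object ID) or column 3 (symbol) as the gene identifier
#' and column 5 as the term; rows whose qualifier (column 4) contains `NOT`
#' are ignored, as are comment lines.
#'
#' @param path Path to the GAF file.
#' @param use_symbol If `TRUE`, take gene ids from the symbol column (3)
#'   instead of the DB Object ID column (2).
#' @param release_tag Optional release label.
#' @return Annotation set tibble.
#' @export
read_gaf <- function(path, use_symbol = FALSE, release_tag = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) {
    length(f) >= 5 && !grepl("\\bNOT\\b", f[4])
  }, logical(1))
  fields <- fields[keep]
  gene_col <- if (use_symbol) 3L else 2L
  annotation_set(
    gene = vapply(fields, `[[`, character(1), gene_col),
    term = vapply(fields, `[[`, character(1), 5L),
    release_tag = release_tag)
}

#' Read an ontology from an OBO 1.2 file (subset)
#'
#' Parses `[Term]` stanzas for `id:`, `name:`, `namespace:`, `is_a:` and
#' `relationship: part_of`; obsolete terms are skipped. All other tags and
#' relationship types are ignored.
#'
#' @param path Path to the OBO file.
#' @param part_of If `TRUE` (default), `relationship: part_of` edges are kept
#'   alongside `is_a` edges; set `FALSE` for is_a-only propagation.
#' @return A `kcml_ontology`.
#' @export
read_obo <- function(path, part_of = TRUE) {
  lines <- readr::read_lines(path, progress = FALSE)
  term_starts <- which(lines == "[Term]")
  stanza_ends <- c(term_starts[-1] - 1L, length(lines))
  terms <- list(); edges <- list()
  for (s in seq_along(term_starts)) {
    chunk <- lines[term_starts[s]:stanza_ends[s]]
    # a stanza of another type ends the [Term] block
    other <- grep("^\\[", chunk[-1])
    if (length(other) > 0) chunk <- chunk[seq_len(other[1])]
    tag <- function(t) sub(paste0("^", t, ":\\s*"), "",
                           grep(paste0("^", t, ":"), chunk, value = TRUE))
    if (any(grepl("^is_obsolete:\\s*true", chunk))) next
    id <- tag("id")[1]
    if (is.na(id) || !nzchar(id)) next
    nm <- tag("name")
    ns <- tag("namespace")
    terms[[length(terms) + 1L]] <- tibble(
      id = id,
      name = if (length(nm)) nm[1] else id,
      namespace = if (length(ns)) ns[1] else NA_character_)
    isa <- sub("\\s*!.*$", "", tag("is_a"))
    isa <- isa[nzchar(isa)]
    if (length(isa) > 0) {
      edges[[length(edges) + 1L]] <- tibble(child = id, parent = isa,
                                            relation = "is_a")
    }
    if (part_of) {
      rel <- grep("^relationship:\\s*part_of\\s", chunk, value = TRUE)
      po <- sub("\\s*!.*$", "", sub("^relationship:\\s*part_of\\s+", "", rel))
      po <- po[nzchar(po)]
      if (length(po) > 0) {
        edges[[length(edges) + 1L]] <- tibble(child = id, parent = po,
                                              relation = "part_of")
      }
    }
  }
  terms <- distinct(bind_rows(terms))
  edges <- if (length(edges)) distinct(bind_rows(edges)) else
    tibble(child = character(0), parent = character(0), relation = character(0))
  # tolerate dangling parents (declare them as bare terms)
  missing <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(missing) > 0) {
    terms <- bind_rows(terms, tibble(id = missing, name = missing,
                                     namespace = NA_character_))
  }
  ontology_dag(terms, edges)
}

#' Write a term catalog to TSV (with a JSON parameter sidecar)
#'
#' @param cat A `kcml_catalog`.
#' @param path Output TSV path; a `<path>.json` sidecar records the filter and
#'   merge parameters.
#' @return `path`, invisibly.
#' @export
write_term_catalog <- function(cat, path) {
  tab <- tibble(
    term_id = cat$term,
    n_genes = cat$n_genes,
    merged_from = vapply(cat$merged_from, paste, character(1), collapse = ";"))
  readr::write_tsv(tab, path, progress = FALSE)
  jsonlite::write_json(
    list(min_genes = attr(cat, "min_genes"), max_genes = attr(cat, "max_genes"),
         n_terms = nrow(cat)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read / write a profile matrix TSV
#'
#' Profile tables are TSV with a header; the reserved metadata columns
#' (`gene`, `well_id`, `plate_id`, `tcn`) come first when present and every
#' other column is a numeric feature.
#'
#' @param path File path.
#' @return `read_profile_matrix()` returns a profile tibble.
#' @export
read_profile_matrix <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  for (mc in intersect(c("gene", "well_id", "plate_id"), names(tab))) {
    tab[[mc]] <- as.character(tab[[mc]])
  }
  as_tibble(tab)
}

#' @rdname read_profile_matrix
#' @param m Profile tibble to write.
#' @export
write_profile_matrix <- function(m, path) {
  meta <- intersect(kcml_meta_cols, names(m))
  readr::write_tsv(m[, c(meta, feature_cols(m))], path, progress = FALSE)
  invisible(path)
}

#' Read a siRNA seed map
#'
#' Accepts either `(gene, sirna_sequence)` rows, from which the 6-mer seed
#' (guide positions 2-7) is derived, or `(gene, seed)` rows directly. Multiple
#' rows per gene are allowed (pooled siRNAs).
#'
#' @param path TSV path with a header naming either `sirna_sequence` or
#'   `seed` as the second column.
#' @return Tibble `(gene, seed)`.
#' @export
read_seed_map <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  names(tab)[1] <- "gene"
  if ("sirna_sequence" %in% names(tab)) {
    tibble(gene = tab$gene,
           seed = vapply(tab$sirna_sequence, extract_seed, character(1),
                         USE.NAMES = FALSE))
  } else {
    names(tab)[2] <- "seed"
    tibble(gene = tab$gene, seed = toupper(chartr("T", "U", tab$seed)))
  }
}

#' Read an interaction network edge list
#'
#' @param path TSV with 2 or 3 columns (`gene_a`, `gene_b`[, `source`]);
#'   header optional. Self-loops are dropped; edges are undirected.
#' @return An igraph object with a `source` edge attribute.
#' @export
read_interaction_network <- function(path) {
  tab <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (tolower(tab[[1]][1]) %in% c("gene_a", "from", "gene1")) tab <- tab[-1, ]
  names(tab)[1:2] <- c("gene_a", "gene_b")
  if (ncol(tab) < 3) tab$source <- "combined" else names(tab)[3] <- "source"
  tab <- filter(tab, .data$gene_a != .data$gene_b)
  g <- igraph::graph_from_data_frame(tab, directed = FALSE)
  igraph::simplify(g, edge.attr.comb = "first")
}

#' Export a term network
#'
#' @param net A `kcml_term_network` (see [build_term_network()]).
#' @param path Output path; format chosen by extension (`.graphml` or `.sif`).
#' @return `path`, invisibly.
#' @export
write_term_network <- function(net, path) {
  if (grepl("\\.graphml$", path)) {
    igraph::write_graph(net$graph, path, format = "graphml")
  } else if (grepl("\\.sif$", path)) {
    ed <- net$edges
    readr::write_lines(
      sprintf("%s overlap %s", ed$term_a, ed$term_b), path)
  } else {
    abort("write_term_network: use a .graphml or .sif extension")
  }
  invisible(path)
}

#' Write a prediction table TSV
#'
#' @param pred Prediction tibble (`gene`, `term`, `decision_score`,
#'   `predicted`, `rank`, and optionally `zscored_rank`, `off_target`).
#' @param path Output TSV path.
#' @export
write_predictions <- function(pred, path) {
  readr::write_tsv(pred, path, progress = FALSE)
  invisible(path)
}
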