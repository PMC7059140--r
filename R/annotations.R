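#' Annotation sets and the term catalog
#'
#' An annotation set is a two-column tibble of `(gene, term)` pairs, one row
#' per pair, with no duplicates. A term catalog is the filtered (and possibly
#' merged) list of candidate terms for classification, stored as a tibble with
#' a list-column of positive gene sets.
#'
#' @name annotations
NULL

#' Build an annotation set from gene/term vectors
#'
#' @param gene,term Character vectors of equal length.
#' @param release_tag Optional free-text release label (e.g. `"2018-03"`).
#' @return A tibble with columns `gene`, `term` (deduplicated, sorted) and
#'   attribute `release_tag`.
#' @export
annotation_set <- function(gene, term, release_tag = NULL) {
  stopifnot(length(gene) == length(term))
  out <- distinct(tibble(gene = as.character(gene), term = as.character(term)))
  out <- arrange(out, .data$gene, .data$term)
  attr(out, "release_tag") <- release_tag
  out
}

#' Escalate annotations to ancestor terms
#'
#' Every gene annotated to a term becomes annotated to all ancestors of that
#' term reachable through the ontology's parent links. No annotation is
#' removed, and the operation is idempotent. Terms absent from the ontology
#' pass through unchanged (with a message).
#'
#' @param ann Annotation set tibble (`gene`, `term`).
#' @param dag Ontology as returned by [read_obo()] or [ontology_dag()].
#' @return Propagated annotation set tibble.
#' @export
propagate_annotations <- function(ann, dag) {
  anc <- ontology_ancestors(dag)
  unknown <- setdiff(unique(ann$term), c(names(anc), dag$terms$id))
  if (length(unknown) > 0) {
    inform(sprintf(
      "propagate_annotations: %d annotated term(s) not in ontology, passed through unchanged",
      length(unknown)))
  }
  extra <- ann |>
    mutate(.anc = unname(anc[.data$term])) |>
    filter(!vapply(.data$.anc, is.null, logical(1))) |>
    select("gene", ".anc") |>
    tidyr::unnest_longer(".anc", values_to = "term")
  out <- distinct(bind_rows(ann, select(extra, "gene", "term")))
  arrange(out, .data$gene, .data$term)
}

#' Construct an ontology DAG from explicit parent links
#'
#' @param terms Tibble with columns `id`, and optionally `name`, `namespace`.
#' @param edges Tibble with columns `child`, `parent` and optionally
#'   `relation` (`"is_a"` or `"part_of"`).
#' @return An object of class `kcml_ontology`.
#' @export
ontology_dag <- function(terms, edges) {
  terms <- as_tibble(terms)
  if (!"name" %in% names(terms)) terms$name <- terms$id
  if (!"namespace" %in% names(terms)) terms$namespace <- NA_character_
  edges <- as_tibble(edges)
  if (!"relation" %in% names(edges)) edges$relation <- "is_a"
  bad <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(bad) > 0) {
    abort(sprintf("ontology edge endpoint(s) not declared as terms: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  dag <- structure(list(terms = terms, edges = edges), class = "kcml_ontology")
  cyc <- find_cycle_edge(dag)
  if (!is.null(cyc)) {
    abort(sprintf("ontology graph contains a cycle through edge %s -> %s",
                  cyc[1], cyc[2]))
  }
  dag
}

#' @export
print.kcml_ontology <- function(x, ...) {
  cat(sprintf("<kcml_ontology> %d terms, %d parent links\n",
              nrow(x$terms), nrow(x$edges)))
  invisible(x)
}

# Returns c(child, parent) of one edge on a cycle, or NULL if acyclic.
find_cycle_edge <- function(dag) {
  g <- igraph::graph_from_data_frame(
    dag$edges[, c("child", "parent")], directed = TRUE,
    vertices = dag$terms["id"])
  if (igraph::is_dag(g)) return(NULL)
  # locate a back edge by DFS over the subgraph restricted to cycles
  comp <- igraph::components(g, mode = "strong")
  bad <- which(comp$csize > 1)[1]
  verts <- names(comp$membership)[comp$membership == bad]
  sub <- dag$edges[dag$edges$child %in% verts & dag$edges$parent %in% verts, ]
  c(sub$child[1], sub$parent[1])
}

# term -> character vector of all ancestors (memoised transitive closure)
ontology_ancestors <- function(dag) {
  parents <- split(dag$edges$parent, dag$edges$child)
  anc <- new.env(parent = emptyenv())
  get_anc <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    ps <- parents[[t]]
    if (is.null(ps)) {
      res <- character(0)
    } else {
      res <- unique(c(ps, unlist(lapply(ps, get_anc), use.names = FALSE)))
    }
    anc[[t]] <- res
    res
  }
  out <- lapply(unique(dag$edges$child), get_anc)
  names(out) <- unique(dag$edges$child)
  # terms with no parents map to empty sets
  roots <- setdiff(dag$terms$id, names(out))
  out[roots] <- list(character(0))
  out
}

#' Filter terms by positive-set size
#'
#' Keeps exactly the terms whose annotated gene set has size within
#' `[min_genes, max_genes]` (both bounds inclusive); the bounds follow the
#' usual 100-500 window used for training-set construction.
#'
#' @param ann Propagated annotation set tibble.
#' @param min_genes,max_genes Inclusive size bounds (defaults 100 and 500).
#' @return A term catalog: tibble with columns `term`, `genes` (list-column),
#'   `n_genes`, `merged_from` (list-column, empty before merging); class
#'   `kcml_catalog`.
#' @export
filter_terms <- function(ann, min_genes = 100, max_genes = 500) {
  if (nrow(ann) == 0) {
    warn("filter_terms: empty annotation set; returning empty catalog")
    return(new_catalog(tibble(term = character(0), genes = list(),
                              n_genes = integer(0), merged_from = list()),
                       min_genes, max_genes))
  }
  by_term <- ann |>
    group_by(.data$term) |>
    summarise(genes = list(sort(unique(.data$gene))), .groups = "drop") |>
    mutate(n_genes = lengths(.data$genes)) |>
    filter(.data$n_genes >= min_genes, .data$n_genes <= max_genes) |>
    arrange(.data$term)
  by_term$merged_from <- rep(list(character(0)), nrow(by_term))
  new_catalog(by_term, min_genes, max_genes)
}

new_catalog <- function(tbl, min_genes, max_genes) {
  structure(tbl, class = c("kcml_catalog", class(tbl)),
            min_genes = min_genes, max_genes = max_genes)
}

#' Jaccard index of two gene sets
#'
#' `|a intersect b| / |a union b|`; returns 0 for two empty sets (logged).
#'
#' @param a,b Character vectors (treated as sets).
#' @return A fraction in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) {
    inform("jaccard: both sets empty; returning 0 by convention")
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Merge highly redundant terms
#'
#' Greedy agglomeration: while any retained pair of terms has Jaccard index
#' above `threshold`, the most redundant pair is merged (gene sets unioned);
#' the surviving identifier is that of the larger set (ties: lexicographically
#' smaller id) and absorbed ids are recorded in `merged_from`. Merged sets may
#' exceed the catalog's original `max_genes`; they are kept.
#'
#' @param cat A `kcml_catalog`.
#' @param threshold Jaccard threshold above which a pair is merged (0.70).
#' @return A `kcml_catalog` in which no retained pair has Jaccard > threshold.
#' @export
merge_redundant_terms <- function(cat, threshold = 0.70) {
  entries <- lapply(seq_len(nrow(cat)), function(i) {
    list(term = cat$term[i], genes = cat$genes[[i]],
         merged_from = cat$merged_from[[i]])
  })
  repeat {
    k <- length(entries)
    if (k < 2) break
    best <- c(NA_integer_, NA_integer_); best_j <- threshold
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        jc <- jaccard(entries[[i]]$genes, entries[[j]]$genes)
        if (jc > best_j) { best_j <- jc; best <- c(i, j) }
      }
    }
    if (is.na(best[1])) break
    ei <- entries[[best[1]]]; ej <- entries[[best[2]]]
    keep_i <- length(ei$genes) > length(ej$genes) ||
      (length(ei$genes) == length(ej$genes) && ei$term <= ej$term)
    keep <- if (keep_i) ei else ej
    drop <- if (keep_i) ej else ei
    keep$genes <- sort(union(ei$genes, ej$genes))
    keep$merged_from <- sort(unique(c(keep$merged_from, drop$merged_from,
                                      drop$term)))
    entries[[best[1]]] <- keep
    entries[[best[2]]] <- NULL
  }
  out <- tibble(
    term = vapply(entries, `[[`, character(1), "term"),
    genes = lapply(entries, `[[`, "genes"),
    merged_from = lapply(entries, `[[`, "merged_from"))
  out$n_genes <- lengths(out$genes)
  out <- arrange(out[, c("term", "genes", "n_genes", "merged_from")], .data$term)
  new_catalog(out, attr(cat, "min_genes"), attr(cat, "max_genes"))
}

#' Annotations present in a newer release but not an older one
#'
#' @param old,new Annotation set tibbles.
#' @return Tibble of `(gene, term)` pairs in `new` and absent from `old`.
#' @export
new_annotation_diff <- function(old, new) {
  arrange(anti_join(distinct(new[, c("gene", "term")]),
                    distinct(old[, c("gene", "term")]),
                    by = c("gene", "term")),
          .data$gene, .data$term)
}
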