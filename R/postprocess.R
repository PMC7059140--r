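#' Extract the siRNA seed from a guide-strand sequence
#'
#' The seed is positions 2-7 (1-based, inclusive) of the siRNA guide strand;
#' DNA input is normalised to RNA (T -> U).
#'
#' @param sequence A single siRNA sequence (length >= 7, alphabet ACGUT,
#'   case-insensitive).
#' @return The 6-mer seed as an RNA string.
#' @export
extract_seed <- function(sequence) {
  stopifnot(length(sequence) == 1)
  s <- toupper(sequence)
  if (nchar(s) < 7) abort(sprintf("extract_seed: sequence '%s' shorter than 7", s))
  if (grepl("[^ACGUT]", s)) abort(sprintf("extract_seed: invalid characters in '%s'", s))
  chartr("T", "U", substr(s, 2, 7))
}

#' Flag predictions driven by shared siRNA seeds
#'
#' For every term with predictions and every eligible seed (carried by at
#' least `min_carriers` genes of the universe), a 2x2 table over the gene
#' universe ({predicted for the term, not} x {carries the seed, not}) is
#' tested with a right-tail Fisher exact test; when `p < alpha`, all of that
#' term's predictions for the seed's carrier genes are flagged as off-target.
#' Flagged rows are retained (set `remove = TRUE` to drop them).
#'
#' @param pred Prediction tibble (possibly multiple terms).
#' @param seeds Tibble `(gene, seed)`, one row per pooled siRNA.
#' @param alpha Significance level on the raw p-value (0.01, no correction).
#' @param min_carriers Seeds carried by fewer genes are not tested (4).
#' @param remove Drop flagged predictions instead of flagging them.
#' @return The prediction tibble with `off_target` set; attribute
#'   `seed_tests` holds the per-(term, seed) test table.
#' @export
seed_enrichment_filter <- function(pred, seeds, alpha = 0.01,
                                   min_carriers = 4, remove = FALSE) {
  universe <- unique(pred$gene)
  no_seed <- setdiff(universe, seeds$gene)
  if (length(no_seed) > 0) {
    inform(sprintf("seed_enrichment_filter: %d gene(s) without seed records",
                   length(no_seed)))
  }
  seeds <- distinct(seeds[seeds$gene %in% universe, c("gene", "seed")])
  carriers <- split(seeds$gene, seeds$seed)
  carriers <- carriers[lengths(carriers) >= min_carriers]
  pred$off_target <- pred$off_target %||% FALSE
  tests <- list()
  N <- length(universe)
  for (tid in unique(pred$term)) {
    sel <- pred$term == tid & pred$predicted
    pred_genes <- unique(pred$gene[sel])
    n <- length(pred_genes)
    if (n == 0) next
    for (sd_ in names(carriers)) {
      carr <- carriers[[sd_]]
      k <- length(intersect(pred_genes, carr))
      if (k == 0) next
      p <- fisher_right_tail(k, length(carr), n, N)
      tests[[length(tests) + 1L]] <- tibble(
        term = tid, seed = sd_, n_carriers = length(carr),
        n_predicted = n, n_overlap = k, p_value = p,
        flagged = p < alpha)
      if (p < alpha) {
        pred$off_target[pred$term == tid & pred$gene %in% carr] <- TRUE
      }
    }
  }
  if (remove) pred <- pred[!pred$off_target, ]
  attr(pred, "seed_tests") <- bind_rows(tests)
  pred
}

#' Build the term-overlap network
#'
#' Terms whose predicted gene lists overlap by more than `threshold` are
#' joined by an edge; any term left without an edge is then attached to its
#' highest-overlap partner, iterating until no term is isolated. Overlap is
#' the Jaccard index by default (`measure = "overlap_coef"` uses the overlap
#' coefficient `|A&B| / min(|A|,|B|)` instead). Ties attach to the
#' lexicographically smallest partner.
#'
#' @param pred_sets Named list of per-term predicted gene sets, or a combined
#'   prediction tibble (its `predicted` rows are used).
#' @param threshold Overlap threshold for direct edges (0.70, strict).
#' @param measure `"jaccard"` (default) or `"overlap_coef"`.
#' @return A `kcml_term_network`: list with `graph` (igraph), `edges` tibble
#'   (`term_a`, `term_b`, `weight`, `origin`).
#' @export
build_term_network <- function(pred_sets, threshold = 0.70,
                               measure = c("jaccard", "overlap_coef")) {
  measure <- match.arg(measure)
  if (is.data.frame(pred_sets)) {
    pred_sets <- split(pred_sets$gene[pred_sets$predicted],
                       pred_sets$term[pred_sets$predicted])
  }
  terms <- sort(names(pred_sets))
  if (length(terms) < 2) abort("build_term_network: need at least two terms")
  empty <- terms[lengths(pred_sets[terms]) == 0]
  if (length(empty) > 0) {
    warn(sprintf("build_term_network: empty prediction set(s): %s",
                 paste(empty, collapse = ", ")))
  }
  ov <- function(a, b) {
    A <- unique(pred_sets[[a]]); B <- unique(pred_sets[[b]])
    if (length(A) == 0 || length(B) == 0) return(0)
    i <- length(intersect(A, B))
    if (measure == "jaccard") i / length(union(A, B))
    else i / min(length(A), length(B))
  }
  k <- length(terms)
  W <- matrix(0, k, k, dimnames = list(terms, terms))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) W[i, j] <- W[j, i] <- ov(terms[i], terms[j])
  }
  edges <- list()
  has_edge <- function() {
    if (length(edges) == 0) return(character(0))
    e <- bind_rows(edges)
    unique(c(e$term_a, e$term_b))
  }
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (W[i, j] > threshold) {
        edges[[length(edges) + 1L]] <- tibble(
          term_a = terms[i], term_b = terms[j], weight = W[i, j],
          origin = "threshold")
      }
    }
  }
  repeat {
    isolated <- setdiff(terms, has_edge())
    if (length(isolated) == 0) break
    t0 <- isolated[1]
    cand <- setdiff(terms, t0)
    w <- W[t0, cand]
    best <- cand[w == max(w)]
    partner <- sort(best)[1]
    pair <- sort(c(t0, partner))
    edges[[length(edges) + 1L]] <- tibble(
      term_a = pair[1], term_b = pair[2], weight = W[t0, partner],
      origin = "attachment")
  }
  etab <- distinct(bind_rows(edges))
  g <- igraph::graph_from_data_frame(
    etab[, c("term_a", "term_b")], directed = FALSE,
    vertices = data.frame(name = terms))
  igraph::E(g)$weight <- etab$weight
  igraph::E(g)$origin <- etab$origin
  structure(list(graph = g, edges = etab), class = "kcml_term_network")
}

#' @export
print.kcml_term_network <- function(x, ...) {
  cat(sprintf("<kcml_term_network> %d terms, %d edges (%d by threshold)\n",
              igraph::vcount(x$graph), nrow(x$edges),
              sum(x$edges$origin == "threshold")))
  invisible(x)
}

#' Enrichment of predictions among interaction-network first neighbours
#'
#' First neighbours are the genes adjacent to at least one of the term's
#' annotated genes in the interaction network, excluding the annotated genes
#' themselves (set `include_annotated = TRUE` to keep them). The overlap of
#' the predicted set with the neighbour set is scored with an upper-tail
#' hypergeometric test over the gene universe.
#'
#' @param predicted Predicted genes for one term.
#' @param annotated The term's annotated genes (subset of `universe`).
#' @param net An igraph interaction network (undirected, no self-loops).
#' @param universe The gene universe (matrix rows).
#' @param include_annotated Count annotated genes as their own neighbours.
#' @return List: `n_neighbours`, `n_predicted`, `n_overlap`, `p_value`.
#' @export
ppi_first_neighbor_enrichment <- function(predicted, annotated, net, universe,
                                          include_annotated = FALSE) {
  stopifnot(all(annotated %in% universe))
  present <- intersect(annotated, igraph::V(net)$name)
  nb <- character(0)
  if (length(present) > 0) {
    nb <- unique(unlist(lapply(
      igraph::adjacent_vertices(net, present),
      function(v) igraph::V(net)$name[as.integer(v)])))
  }
  nb <- intersect(nb, universe)
  if (!include_annotated) nb <- setdiff(nb, annotated)
  predicted <- intersect(predicted, universe)
  if (length(nb) == 0) {
    inform("ppi_first_neighbor_enrichment: empty neighbour set; p = 1")
    return(list(n_neighbours = 0L, n_predicted = length(predicted),
                n_overlap = 0L, p_value = 1))
  }
  k <- length(intersect(predicted, nb))
  list(n_neighbours = length(nb), n_predicted = length(predicted),
       n_overlap = k,
       p_value = fisher_right_tail(k, length(nb), length(predicted),
                                   length(universe)))
}

#' Embed a term's subphenotypic space
#'
#' Fits a logistic regression reproducing the classifier's predicted labels
#' from its selected features, then embeds the genes in 2-D with t-SNE on the
#' selected feature columns scaled by the absolute logistic weights. A
#' (near-)separated logistic fit falls back to a ridge-regularised fit via
#' iterated least squares (logged).
#'
#' @param clf A classifiable `kcml_classifier`.
#' @param pred Prediction tibble of `clf` over the matrix (see
#'   [predict_genome()]).
#' @param m Profile tibble.
#' @param seed Integer seed for the embedding.
#' @param perplexity t-SNE perplexity (30).
#' @return List: `coords` tibble (`gene`, `dim1`, `dim2`, `predicted`),
#'   `weights` (named vector over selected features), `agreement` (fraction
#'   of labels the logistic model reproduces).
#' @export
subphenotypic_embedding <- function(clf, pred, m, seed = 1L,
                                    perplexity = 30) {
  if (!clf$classifiable) warn("subphenotypic_embedding: classifier not classifiable")
  x <- feature_matrix(m)[, clf$features, drop = FALSE]
  lab <- pred$predicted[match(m$gene, pred$gene)]
  if (anyNA(lab)) abort("subphenotypic_embedding: predictions do not cover the matrix")
  fit <- tryCatch({
    withCallingHandlers(
      glm(lab ~ ., data = as.data.frame(x), family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          inform("subphenotypic_embedding: separation detected; ridge fallback")
          invokeRestart("muffleWarning")
        }
      })
  }, error = function(e) NULL)
  w <- if (!is.null(fit)) coef(fit)[-1] else NULL
  if (is.null(w) || anyNA(w)) {
    w <- ridge_logistic(x, lab)
  }
  names(w) <- clf$features
  aw <- abs(w)
  if (all(aw == 0)) abort("subphenotypic_embedding: all feature weights are zero")
  agreement <- agreement_rate(x, lab, w)
  xs <- sweep(x, 2, aw, "*")
  Y <- tsne_embed(xs, perplexity = perplexity, seed = seed)
  list(coords = tibble(gene = m$gene, dim1 = Y[, 1], dim2 = Y[, 2],
                       predicted = lab),
       weights = w, agreement = agreement)
}

# Logistic fit with a small L2 penalty via Newton iterations; guards against
# perfect separation.
ridge_logistic <- function(x, lab, lambda = 1e-2, iter = 50) {
  X <- cbind(1, x)
  y <- as.numeric(lab)
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0
  for (it in seq_len(iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    Wd <- pmax(p * (1 - p), 1e-6)
    H <- crossprod(X, X * Wd) + pen
    g <- crossprod(X, y - p) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  drop(beta[-1])
}

agreement_rate <- function(x, lab, w) {
  # refit intercept for the given weights, then compare hard labels
  eta0 <- drop(x %*% w)
  b <- tryCatch(
    suppressWarnings(coef(glm(lab ~ 1, offset = eta0,
                              family = binomial()))[1]),
    error = function(e) 0)
  mean((eta0 + b > 0) == lab)
}

#' Signed, scaled counts of selected features per category
#'
#' Counts, for each classifier and feature category, how many of its selected
#' features sit above (+1) or below (-1) the control mean among the
#' predicted-positive genes; per-term net counts are scaled to maximum
#' absolute value 1.
#'
#' @param fit A `kcml_fit` (or list of classifiers).
#' @param categories Tibble mapping `feature` to `category` (unmapped
#'   features fall into `"other"`, with a warning).
#' @param m Profile tibble.
#' @param pred Combined prediction tibble over `m` for the same classifiers.
#' @param control_genes Genes constituting the control reference (e.g.
#'   scrambled wells or the whole screen).
#' @return Tibble (`term`, `category`, `n_features`, `signed_count`,
#'   `scaled`).
#' @export
feature_category_summary <- function(fit, categories, m, pred,
                                     control_genes) {
  ctrl_idx <- match(intersect(control_genes, m$gene), m$gene)
  if (length(ctrl_idx) == 0) abort("feature_category_summary: no control genes in matrix")
  x <- feature_matrix(m)
  rows <- list()
  for (clf in fit) {
    cat_map <- categories$category[match(clf$features, categories$feature)]
    if (anyNA(cat_map)) {
      warn(sprintf("feature_category_summary: %d unmapped feature(s) -> 'other'",
                   sum(is.na(cat_map))))
      cat_map[is.na(cat_map)] <- "other"
    }
    pos_genes <- pred$gene[pred$term == clf$term & pred$predicted]
    pos_idx <- match(intersect(pos_genes, m$gene), m$gene)
    if (length(pos_idx) == 0) next
    sgn <- vapply(clf$features, function(f) {
      d <- mean(x[pos_idx, f]) - mean(x[ctrl_idx, f])
      if (d > 0) 1 else -1
    }, numeric(1))
    tab <- tibble(term = clf$term, category = cat_map, sign = sgn) |>
      group_by(.data$term, .data$category) |>
      summarise(n_features = n(), signed_count = sum(.data$sign),
                .groups = "drop")
    rows[[length(rows) + 1L]] <- tab
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out |>
    group_by(.data$term) |>
    mutate(scaled = if (max(abs(.data$signed_count)) > 0) {
      .data$signed_count / max(abs(.data$signed_count))
    } else 0) |>
    ungroup()
}
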