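#' Clustering-based gene-function baseline
#'
#' The comparison pipeline: reduce profiles to the top principal components,
#' cluster the genes (k-means, or a one-dimensional self-organising map so
#' the unit count is comparable to k), and score each gene for each term by
#' the fraction of the rest of its cluster annotated to the term. Recall
#' counts a gene as predicted when it co-clusters with at least one annotated
#' gene; AUROC ranks annotated vs non-annotated genes by the cluster-overlap
#' score.
#'
#' @param m Profile tibble.
#' @param catalog A `kcml_catalog` (or tibble with `term`, `genes`).
#' @param method `"kmeans"` or `"som"`.
#' @param k_values Cluster counts to evaluate (default `c(10, 50, 100, 150,
#'   200)`); values exceeding the row count are skipped with a message.
#' @param n_pcs Principal components used (default 100, clipped).
#' @param seed Integer seed (k-means initialisation / SOM sampling).
#' @return Tibble (`method`, `k`, `term`, `recall`, `auroc`) plus attribute
#'   `summary` (mean AUROC per k).
#' @export
cluster_baseline <- function(m, catalog, method = c("kmeans", "som"),
                             k_values = c(10, 50, 100, 150, 200),
                             n_pcs = 100, seed = 1L) {
  method <- match.arg(method)
  red <- suppressWarnings(reduce_pca(m, n_pcs, zscore = FALSE))
  x <- feature_matrix(red)
  rows <- list()
  for (k in k_values) {
    if (k > nrow(x)) {
      inform(sprintf("cluster_baseline: k=%d exceeds %d rows; skipped",
                     k, nrow(x)))
      next
    }
    set.seed(seed)
    cl <- if (method == "kmeans") {
      kmeans(x, centers = k, nstart = 5, iter.max = 50)$cluster
    } else {
      som_chain(x, k)
    }
    for (i in seq_len(nrow(catalog))) {
      tid <- catalog$term[i]
      pos <- intersect(catalog$genes[[i]], m$gene)
      if (length(pos) == 0) next
      is_pos <- m$gene %in% pos
      # per cluster: number of annotated members
      npos_cl <- tapply(is_pos, cl, sum)
      size_cl <- tapply(rep(1L, length(cl)), cl, sum)
      others_pos <- npos_cl[as.character(cl)] - is_pos
      others_n <- size_cl[as.character(cl)] - 1L
      score <- ifelse(others_n > 0, others_pos / others_n, 0)
      predicted <- others_pos >= 1
      rows[[length(rows) + 1L]] <- tibble(
        method = method, k = k, term = tid,
        recall = mean(predicted[is_pos]),
        auroc = auroc(score[is_pos], score[!is_pos]))
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(method = character(0), k = numeric(0), term = character(0),
                  recall = numeric(0), auroc = numeric(0)))
  }
  attr(out, "summary") <- out |>
    group_by(.data$method, .data$k) |>
    summarise(mean_auroc = mean(.data$auroc, na.rm = TRUE), .groups = "drop")
  out
}

# Minimal 1-D (chain topology) self-organising map returning cluster ids;
# online training with a shrinking neighbourhood, deterministic given the
# RNG state.
som_chain <- function(x, k, epochs = 5, alpha0 = 0.5) {
  n <- nrow(x)
  units <- x[sample(n, k), , drop = FALSE]
  radius0 <- max(k / 2, 1)
  total <- epochs * n
  t <- 0
  for (e in seq_len(epochs)) {
    for (i in sample(n)) {
      t <- t + 1
      frac <- t / total
      alpha <- alpha0 * (1 - frac)
      radius <- max(radius0 * (1 - frac), 0.5)
      d2 <- rowSums(sweep(units, 2, x[i, ])^2)
      win <- which.min(d2)
      nb <- which(abs(seq_len(k) - win) <= radius)
      h <- exp(-((nb - win)^2) / (2 * max(radius, 1e-9)^2))
      units[nb, ] <- units[nb, , drop = FALSE] +
        alpha * h * (matrix(x[i, ], length(nb), ncol(x), byrow = TRUE) -
                       units[nb, , drop = FALSE])
    }
  }
  d2 <- cross_sqdist(x, units)
  max.col(-d2, ties.method = "first")
}

#' Correlation-based gene-function baseline
#'
#' A gene is predicted for a term when its Pearson correlation with any other
#' gene annotated to that term exceeds `r_threshold`; it counts as a true
#' positive if annotated itself and as a false positive otherwise.
#'
#' @param m Profile tibble.
#' @param catalog A `kcml_catalog`.
#' @param r_threshold Correlation threshold (default 0.9, strict).
#' @return Tibble (`term`, `tp`, `fp`, `recall`, `precision`).
#' @export
correlation_baseline <- function(m, catalog, r_threshold = 0.9) {
  x <- t(feature_matrix(m))           # features x genes: cor() over columns
  keep_var <- apply(x, 2, function(v) isTRUE(sd(v) > 0))
  cc <- suppressWarnings(cor(x))
  cc[!keep_var, ] <- NA
  cc[, !keep_var] <- NA
  diag(cc) <- NA
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    tid <- catalog$term[i]
    pos <- intersect(catalog$genes[[i]], m$gene)
    if (length(pos) < 2) {
      inform(sprintf("correlation_baseline: term %s has <2 genes in matrix; skipped",
                     tid))
      next
    }
    pos_idx <- match(pos, m$gene)
    best <- apply(cc[, pos_idx, drop = FALSE], 1, function(v) {
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    })
    predicted <- !is.na(best) & best > r_threshold
    is_pos <- m$gene %in% pos
    tp <- sum(predicted & is_pos)
    fp <- sum(predicted & !is_pos)
    rows[[length(rows) + 1L]] <- tibble(
      term = tid, tp = tp, fp = fp,
      recall = tp / length(pos),
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  }
  bind_rows(rows)
}
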