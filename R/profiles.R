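#' Population-comparison statistics
#'
#' Distribution-distance statistics comparing a perturbed cell population to a
#' control (scrambled/empty) population. Both the rank-sum statistic
#' \eqn{U = R - n_1(n_1+1)/2} (with \eqn{R} the pooled-rank sum of the
#' perturbed sample and midrank tie handling) and the two-sample
#' Kolmogorov-Smirnov distance \eqn{D} are multiplied by a scaling factor
#' \eqn{sf = n_1 n_2 / (n_1 + n_2)} to account for sample-size differences.
#' `sf = "sqrt"` substitutes the classical \eqn{\sqrt{n_1 n_2/(n_1+n_2)}}.
#'
#' @param perturbed,control Numeric vectors of single-cell feature values.
#' @param sf Scaling-factor form: `"linear"` (default, as applied to both
#'   statistics) or `"sqrt"`.
#' @return A scalar; `NA` when either sample is empty.
#' @name population_stats
NULL

scale_factor <- function(n1, n2, sf = c("linear", "sqrt")) {
  sf <- match.arg(sf)
  v <- n1 * n2 / (n1 + n2)
  if (sf == "sqrt") sqrt(v) else v
}

#' @rdname population_stats
#' @export
rank_sum_scaled <- function(perturbed, control, sf = c("linear", "sqrt")) {
  perturbed <- perturbed[is.finite(perturbed)]
  control <- control[is.finite(control)]
  n1 <- length(perturbed); n2 <- length(control)
  if (n1 == 0 || n2 == 0) {
    inform("rank_sum_scaled: empty sample; returning NA")
    return(NA_real_)
  }
  r <- rank(c(perturbed, control), ties.method = "average")
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U * scale_factor(n1, n2, sf)
}

#' @rdname population_stats
#' @export
ks_distance_scaled <- function(perturbed, control, sf = c("linear", "sqrt")) {
  perturbed <- perturbed[is.finite(perturbed)]
  control <- control[is.finite(control)]
  n1 <- length(perturbed); n2 <- length(control)
  if (n1 == 0 || n2 == 0) {
    inform("ks_distance_scaled: empty sample; returning NA")
    return(NA_real_)
  }
  ks_statistic(perturbed, control) * scale_factor(n1, n2, sf)
}

# Two-sample KS statistic: max ECDF gap over the pooled sample points.
ks_statistic <- function(x, y) {
  pooled <- sort(unique(c(x, y)))
  Fx <- ecdf(x)(pooled)
  Fy <- ecdf(y)(pooled)
  max(abs(Fx - Fy))
}

# Asymptotic two-sided two-sample KS p-value (Kolmogorov distribution),
# used only to order features; exactness is not needed.
ks_pvalue <- function(d, n1, n2) {
  ne <- n1 * n2 / (n1 + n2)
  t <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * d
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}

#' Sarle's bimodality coefficient
#'
#' \eqn{b = (g_1^2 + 1) / (g_2 + 3(n-1)^2/((n-2)(n-3)))} with sample skewness
#' \eqn{g_1} and excess kurtosis \eqn{g_2}. Approaches 1/3 for a normal
#' sample and 5/9 for a uniform sample; larger values suggest bimodality.
#'
#' @param values Numeric vector; needs `n >= 4` and nonzero variance,
#'   otherwise `NA` is returned.
#' @return Scalar coefficient.
#' @export
bimodality_coefficient <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4) return(NA_real_)
  m <- mean(values)
  s2 <- mean((values - m)^2)
  if (s2 <= 0) return(NA_real_)
  g1 <- mean((values - m)^3) / s2^1.5
  g2 <- mean((values - m)^4) / s2^2 - 3
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 <= 0 || length(x) < 3) return(NA_real_)
  mean((x - m)^3) / s2^1.5
}

sample_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 <= 0 || length(x) < 4) return(NA_real_)
  mean((x - m)^4) / s2^2 - 3
}

#' Aggregation specification for single-cell features
#'
#' Chooses which per-well statistics are computed for every raw feature:
#' location/spread summaries, quantiles, distribution-shape measures and the
#' control-dependent distribution-distance statistics (scaled rank-sum and KS
#' distance).
#'
#' @param stats Character vector out of `mean`, `sd`, `quantiles`, `iqr`,
#'   `range`, `skewness`, `kurtosis`, `bimodality`, `ks`, `ranksum`.
#' @param quantiles Quantile probabilities used when `"quantiles"` is enabled.
#' @param sf Scaling-factor form for the distance statistics.
#' @return An object of class `kcml_aggspec`.
#' @export
aggregation_spec <- function(stats = c("mean", "sd", "quantiles", "iqr",
                                       "range", "skewness", "kurtosis",
                                       "bimodality", "ks", "ranksum"),
                             quantiles = c(0.01, 0.05, 0.25, 0.50, 0.75,
                                           0.95, 0.99),
                             sf = c("linear", "sqrt")) {
  stats <- match.arg(stats, several.ok = TRUE)
  if (length(stats) == 0) abort("aggregation_spec: enable at least one statistic")
  structure(list(stats = stats, quantiles = quantiles, sf = match.arg(sf)),
            class = "kcml_aggspec")
}

agg_one_feature <- function(x, ctrl, spec) {
  out <- list()
  x_ok <- x[is.finite(x)]
  for (st in spec$stats) {
    out <- c(out, switch(
      st,
      mean = list(mean = if (length(x_ok)) mean(x_ok) else NA_real_),
      sd = list(sd = if (length(x_ok) > 1) sd(x_ok) else NA_real_),
      quantiles = as.list(setNames(
        if (length(x_ok)) quantile(x_ok, spec$quantiles, names = FALSE, type = 7)
        else rep(NA_real_, length(spec$quantiles)),
        paste0("q", formatC(100 * spec$quantiles, format = "fg")))),
      iqr = list(iqr = if (length(x_ok))
        diff(quantile(x_ok, c(0.25, 0.75), names = FALSE)) else NA_real_),
      range = list(range = if (length(x_ok)) diff(range(x_ok)) else NA_real_),
      skewness = list(skewness = sample_skewness(x)),
      kurtosis = list(kurtosis = sample_kurtosis(x)),
      bimodality = list(bimodality = bimodality_coefficient(x)),
      ks = list(ks = if (is.null(ctrl)) NA_real_ else
        suppressMessages(ks_distance_scaled(x, ctrl, sf = spec$sf))),
      ranksum = list(ranksum = if (is.null(ctrl)) NA_real_ else
        suppressMessages(rank_sum_scaled(x, ctrl, sf = spec$sf)))))
  }
  out
}

#' Aggregate a single-cell table into per-well profiles
#'
#' For every well, each raw numeric feature is summarised by the statistics in
#' `spec` (one output column per feature x statistic); per-state cell
#' fractions and the total cell number (`tcn`) are appended. Distance
#' statistics compare each well's cells against the pooled control cells.
#'
#' @param cells Single-cell tibble with columns `well_id`, `gene`, optional
#'   `plate_id`, optional logical state columns (names starting `state_`),
#'   and numeric features.
#' @param controls Gene labels identifying control wells (default
#'   `c("scrambled", "empty")`).
#' @param spec An [aggregation_spec()].
#' @return Per-well profile tibble (`well_id`, `gene`, `plate_id`, `tcn`,
#'   features named `<feature>_<stat>` and `frac_<state>`).
#' @export
aggregate_wells <- function(cells, controls = c("scrambled", "empty"),
                            spec = aggregation_spec()) {
  stopifnot(all(c("well_id", "gene") %in% names(cells)))
  state_cols <- grep("^state_", names(cells), value = TRUE)
  feats <- setdiff(names(cells)[vapply(cells, is.numeric, logical(1))],
                   c(state_cols, "tcn"))
  needs_ctrl <- any(c("ks", "ranksum") %in% spec$stats)
  ctrl_cells <- cells[cells$gene %in% controls, , drop = FALSE]
  if (needs_ctrl && nrow(ctrl_cells) == 0) {
    abort("aggregate_wells: distance statistics need control cells")
  }
  wells <- distinct(cells[, intersect(c("well_id", "gene", "plate_id"),
                                      names(cells))])
  rows <- lapply(seq_len(nrow(wells)), function(i) {
    w <- cells[cells$well_id == wells$well_id[i], , drop = FALSE]
    vals <- list()
    for (f in feats) {
      ctrl <- if (needs_ctrl) ctrl_cells[[f]] else NULL
      one <- agg_one_feature(w[[f]], ctrl, spec)
      names(one) <- paste0(f, "_", names(one))
      vals <- c(vals, one)
    }
    fr <- state_fractions(w, state_cols)
    c(vals, as.list(fr), list(tcn = nrow(w)))
  })
  bind_cols(wells, bind_rows(lapply(rows, as_tibble)))
}

#' Per-state cell fractions of a well
#'
#' Each state label (a logical column) is normalised independently by the
#' well's total cell number, so fractions of non-exclusive labels need not
#' sum to one.
#'
#' @param well_cells Tibble of one well's cells.
#' @param state_cols State column names (default: all columns starting
#'   `state_`).
#' @return Named numeric vector `frac_<state>`; `NA`s when the well is empty.
#' @export
state_fractions <- function(well_cells,
                            state_cols = grep("^state_", names(well_cells),
                                              value = TRUE)) {
  n <- nrow(well_cells)
  out <- vapply(state_cols, function(sc) {
    if (n == 0) return(NA_real_)
    sum(well_cells[[sc]], na.rm = TRUE) / n
  }, numeric(1))
  names(out) <- sub("^state_", "frac_", state_cols)
  out
}

#' Remove rows and features with excessive missingness
#'
#' Rows (samples) whose feature missing fraction exceeds `max_missing` are
#' dropped first; features are then re-checked on the surviving rows and
#' dropped by the same rule.
#'
#' @param m Profile tibble.
#' @param max_missing Maximum tolerated missing fraction (default 0.30).
#' @return Cleaned profile tibble with attribute `drop_log` (list with
#'   `rows`, `cols`).
#' @export
clean_profiles <- function(m, max_missing = 0.30) {
  feats <- feature_cols(m)
  x <- feature_matrix(m)
  row_frac <- rowMeans(is.na(x))
  keep_rows <- row_frac <= max_missing
  x2 <- x[keep_rows, , drop = FALSE]
  col_frac <- colMeans(is.na(x2))
  keep_cols <- col_frac <= max_missing
  if (!any(keep_rows) || !any(keep_cols)) {
    abort("clean_profiles: all rows or all features exceeded the missingness threshold")
  }
  out <- m[keep_rows, c(intersect(kcml_meta_cols, names(m)),
                        feats[keep_cols])]
  attr(out, "drop_log") <- list(
    rows = which(!keep_rows), cols = feats[!keep_cols])
  out
}

#' Impute missing values from nearest neighbouring features
#'
#' Each missing cell is replaced by the inverse-distance-weighted mean of the
#' values, in that row, of the `k` nearest other features; feature-feature
#' distance is the root-mean-square difference over rows where both features
#' are observed. A feature with no overlap with any other feature falls back
#' to its column mean (logged).
#'
#' @param m Cleaned profile tibble (every feature has at least one observed
#'   value).
#' @param k Number of neighbouring features (default 10).
#' @return Fully observed profile tibble.
#' @export
impute_knn_features <- function(m, k = 10) {
  feats <- feature_cols(m)
  x <- feature_matrix(m)
  p <- ncol(x)
  if (p < 2) abort("impute_knn_features: need at least two features")
  if (any(colSums(!is.na(x)) == 0)) {
    abort("impute_knn_features: feature with no observed values; clean first")
  }
  # feature-feature RMS distances on mutually observed rows
  d <- matrix(Inf, p, p)
  obs <- !is.na(x)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      both <- obs[, i] & obs[, j]
      if (any(both)) {
        d[i, j] <- d[j, i] <- sqrt(mean((x[both, i] - x[both, j])^2))
      }
    }
  }
  col_means <- colMeans(x, na.rm = TRUE)
  kk <- min(k, p - 1)
  for (j in seq_len(p)) {
    miss <- which(is.na(x[, j]))
    if (length(miss) == 0) next
    if (all(!is.finite(d[, j]))) {
      inform(sprintf(
        "impute_knn_features: feature '%s' has no overlap; column-mean fallback",
        feats[j]))
      x[miss, j] <- col_means[j]
      next
    }
    ord <- order(d[, j])
    ord <- ord[ord != j & is.finite(d[ord, j])]
    for (i in miss) {
      nb <- ord[obs[i, ord]][seq_len(kk)]
      nb <- nb[!is.na(nb)]
      if (length(nb) == 0) { x[i, j] <- col_means[j]; next }
      w <- 1 / (d[nb, j] + 1e-12)
      x[i, j] <- sum(w * x[i, nb]) / sum(w)
    }
  }
  rebuild_profiles(m, x, feats)
}

rebuild_profiles <- function(m, x, feats) {
  out <- m
  for (j in seq_along(feats)) out[[feats[j]]] <- unname(x[, j])
  out
}

#' Z-score features within plates
#'
#' Subtracts the plate mean and divides by the plate standard deviation, per
#' feature. Zero-variance plate/feature combinations become 0 (logged);
#' without a `plate_id` column the whole table is one plate.
#'
#' @param m Profile tibble.
#' @return Normalised profile tibble.
#' @export
plate_zscore <- function(m) {
  feats <- feature_cols(m)
  plate <- if ("plate_id" %in% names(m)) m$plate_id else rep("all", nrow(m))
  x <- feature_matrix(m)
  for (pl in unique(plate)) {
    idx <- which(plate == pl)
    if (length(idx) == 1) {
      warn(sprintf("plate_zscore: plate '%s' has a single row; set to 0", pl))
      x[idx, ] <- 0
      next
    }
    mu <- colMeans(x[idx, , drop = FALSE], na.rm = TRUE)
    sdv <- apply(x[idx, , drop = FALSE], 2, sd, na.rm = TRUE)
    zero <- !is.finite(sdv) | sdv == 0
    sdv[zero] <- 1
    x[idx, ] <- sweep(sweep(x[idx, , drop = FALSE], 2, mu), 2, sdv, "/")
    if (any(zero)) x[idx, zero] <- 0
  }
  rebuild_profiles(m, x, feats)
}

#' Average replicate wells per gene
#'
#' One output row per gene: the arithmetic mean of its wells' features (and
#' of `tcn`). `well_id` is dropped; `plate_id` keeps the first value per gene.
#'
#' @param m Per-well profile tibble with a `gene` column.
#' @return Per-gene profile tibble.
#' @export
average_replicates <- function(m) {
  stopifnot("gene" %in% names(m))
  feats <- feature_cols(m)
  num_cols <- c(feats, intersect("tcn", names(m)))
  out <- m |>
    group_by(.data$gene) |>
    summarise(across(dplyr::all_of(num_cols), ~ mean(.x, na.rm = TRUE)),
              .groups = "drop")
  if ("plate_id" %in% names(m)) {
    plates <- m |>
      group_by(.data$gene) |>
      summarise(plate_id = dplyr::first(.data$plate_id), .groups = "drop")
    out <- left_join(out, plates, by = "gene")
  }
  meta <- intersect(kcml_meta_cols, names(out))
  out[, c(meta, setdiff(names(out), meta))]
}

#' Filter perturbations that kill too many cells
#'
#' Removes rows whose total cell number is below `min_cells` (strictly), to
#' avoid classifiers that latch onto viability phenotypes.
#'
#' @param m Profile tibble with a `tcn` column.
#' @param min_cells Minimum total cell number (default 625; `tcn < 625` is
#'   removed, `tcn = 625` kept).
#' @return Filtered profile tibble with attribute `drop_log`.
#' @export
viability_filter <- function(m, min_cells = 625) {
  stopifnot("tcn" %in% names(m))
  keep <- m$tcn >= min_cells
  out <- m[keep, ]
  attr(out, "drop_log") <- m$gene[!keep] %||% which(!keep)
  out
}

#' Correct the cell-number confound by binned z-scoring
#'
#' Total cell number is cut into `n_bins` equal-frequency bins; bins with
#' fewer than `min_per_bin` rows are merged rightward (towards higher cell
#' numbers) until every bin is large enough; features are then z-scored
#' within each bin.
#'
#' @param m Profile tibble with `tcn`.
#' @param n_bins Initial number of equal-frequency bins (default 32).
#' @param min_per_bin Minimum rows per bin after merging (default 100).
#' @return Corrected profile tibble with attribute `tcn_bin` (integer bin
#'   assignment per row).
#' @export
correct_cell_number <- function(m, n_bins = 32, min_per_bin = 100) {
  stopifnot("tcn" %in% names(m))
  n <- nrow(m)
  if (n < min_per_bin) {
    warn("correct_cell_number: fewer rows than min_per_bin; single global bin")
    bins <- rep(1L, n)
  } else {
    brk <- unique(quantile(m$tcn, probs = seq(0, 1, length.out = n_bins + 1),
                           type = 7))
    bins <- as.integer(cut(m$tcn, breaks = brk, include.lowest = TRUE))
    # merge small bins rightward
    repeat {
      tab <- table(factor(bins, levels = sort(unique(bins))))
      small <- which(tab < min_per_bin)
      if (length(small) == 0) break
      lv <- as.integer(names(tab))
      s <- lv[small[1]]
      target <- if (s == max(lv)) lv[which(lv == s) - 1] else
        lv[which(lv == s) + 1]
      bins[bins == s] <- target
    }
    bins <- as.integer(factor(bins))
  }
  feats <- feature_cols(m)
  x <- feature_matrix(m)
  for (b in unique(bins)) {
    idx <- which(bins == b)
    mu <- colMeans(x[idx, , drop = FALSE])
    sdv <- apply(x[idx, , drop = FALSE], 2, sd)
    zero <- !is.finite(sdv) | sdv == 0
    sdv[zero] <- 1
    x[idx, ] <- sweep(sweep(x[idx, , drop = FALSE], 2, mu), 2, sdv, "/")
    if (any(zero)) x[idx, zero] <- 0
  }
  out <- rebuild_profiles(m, x, feats)
  attr(out, "tcn_bin") <- bins
  out
}

#' Reduce a profile matrix to principal-component scores
#'
#' Centres the features, projects onto the top `n_components` principal
#' components, fixes each component's sign so its largest-magnitude loading
#' is positive, and z-scores the score columns.
#'
#' @param m Profile tibble.
#' @param n_components Number of components (clipped to `min(n-1, p)` with a
#'   warning).
#' @param zscore Z-score the component scores (default `TRUE`).
#' @return Profile tibble with metadata columns and features `PC1..PCk`;
#'   attribute `explained_variance` holds per-component variance fractions.
#' @export
reduce_pca <- function(m, n_components, zscore = TRUE) {
  x <- feature_matrix(m)
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (n_components > kmax) {
    warn(sprintf("reduce_pca: n_components clipped from %d to %d",
                 n_components, kmax))
    n_components <- kmax
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2, flip, "*")
  if (zscore) {
    sdv <- apply(scores, 2, sd)
    sdv[sdv == 0] <- 1
    scores <- sweep(sweep(scores, 2, colMeans(scores)), 2, sdv, "/")
  }
  meta <- intersect(kcml_meta_cols, names(m))
  out <- bind_cols(m[, meta, drop = FALSE],
                   as_tibble(as.data.frame(scores)))
  attr(out, "explained_variance") <-
    (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
  out
}
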