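#' Training configuration for per-term classifiers
#'
#' Collects every tunable of the per-term training pipeline. Defaults follow
#' the framework's published procedure: a 70/30 train/test split of the
#' annotated genes, class-balanced negative sampling, 30-fold cross-validation
#' of the F-score, a brute-force kernel-width search, forward feature
#' selection capped at 100 features, and selection thresholds
#' FPR < 0.20, test recall > 0.30, train recall > 0.40.
#'
#' @param train_fraction Fraction of positives used for training (0.70).
#' @param cv_folds Cross-validation folds for F-score estimates (30; clipped
#'   to the per-class training count for small terms).
#' @param sigma_factors Kernel-width grid as multipliers of the median
#'   pairwise training distance (default `2^(-3:3)`; wider multiples give
#'   nearly constant or nearly delta kernels whose F-score is unstable).
#' @param max_features Cap on selected features (100).
#' @param max_candidates Cap on how many KS-ranked features are tried during
#'   forward selection (`Inf`: all).
#' @param fpr_max,test_recall_min,train_recall_min Classifiability thresholds
#'   (strict inequalities).
#' @param C SVM soft-margin cost (1).
#' @param improve_tol Minimum CV F-score improvement to accept a feature
#'   (1e-4).
#' @param sigma_top_features Features (in KS order) used for the coarse
#'   kernel-width search before feature selection (20).
#' @param consensus_folds,consensus_required Consensus retraining: number of
#'   refits and the number that must agree (10 and 7).
#' @param rng_seed Base seed; all sampling in training derives from it.
#' @return An object of class `kcml_config`.
#' @export
kcml_config <- function(train_fraction = 0.70, cv_folds = 30,
                        sigma_factors = 2^(-3:3), max_features = 100,
                        max_candidates = Inf, fpr_max = 0.20,
                        test_recall_min = 0.30, train_recall_min = 0.40,
                        C = 1, improve_tol = 1e-4, sigma_top_features = 20,
                        consensus_folds = 10, consensus_required = 7,
                        rng_seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            all(c(fpr_max, test_recall_min, train_recall_min) >= 0),
            all(c(fpr_max, test_recall_min, train_recall_min) <= 1),
            consensus_required <= consensus_folds, all(sigma_factors > 0))
  structure(list(train_fraction = train_fraction, cv_folds = cv_folds,
                 sigma_factors = sigma_factors, max_features = max_features,
                 max_candidates = max_candidates, fpr_max = fpr_max,
                 test_recall_min = test_recall_min,
                 train_recall_min = train_recall_min, C = C,
                 improve_tol = improve_tol,
                 sigma_top_features = sigma_top_features,
                 consensus_folds = consensus_folds,
                 consensus_required = consensus_required,
                 rng_seed = as.integer(rng_seed)),
            class = "kcml_config")
}

# seed derived per term, kept under 2^31
derive_seed <- function(base, i) {
  as.integer((as.numeric(base) * 7919 + i * 104729) %% 2147483629)
}

#' Split a term's positives and sample balanced negatives
#'
#' Positives are split 70/30 into train and test (train share rounded up);
#' negatives are drawn uniformly without replacement from the universe minus
#' the term's positives, in equal number to the positives of each split.
#'
#' @param positives Character vector of annotated genes present in the
#'   profile matrix.
#' @param universe All genes available as rows of the profile matrix.
#' @param cfg A [kcml_config()]; uses `train_fraction`.
#' @return List with `train_pos`, `test_pos`, `train_neg`, `test_neg`.
#' @export
split_and_sample <- function(positives, universe, cfg = kcml_config()) {
  positives <- unique(positives)
  pool <- setdiff(universe, positives)
  if (length(pool) < length(positives)) {
    abort("split_and_sample: not enough non-annotated genes for balanced negatives")
  }
  n_pos <- length(positives)
  n_train <- ceiling(cfg$train_fraction * n_pos)
  perm <- sample(positives)
  train_pos <- perm[seq_len(n_train)]
  test_pos <- perm[-seq_len(n_train)]
  negs <- sample(pool, n_pos)
  list(train_pos = sort(train_pos), test_pos = sort(test_pos),
       train_neg = sort(negs[seq_len(n_train)]),
       test_neg = sort(negs[-seq_len(n_train)]))
}

#' Rank features by two-sample KS separation between classes
#'
#' Features are ordered by ascending two-sample KS p-value comparing the
#' positive-class rows against the negative-class rows; ties break by larger
#' KS statistic, then by column position.
#'
#' @param m Profile tibble.
#' @param pos,neg Gene identifiers of the two classes (matrix rows).
#' @return Tibble (`feature`, `statistic`, `p_value`) in rank order.
#' @export
ks_feature_ranking <- function(m, pos, neg) {
  x <- feature_matrix(m)
  ip <- match(pos, m$gene); ineg <- match(neg, m$gene)
  if (anyNA(ip) || anyNA(ineg)) abort("ks_feature_ranking: genes missing from matrix")
  feats <- feature_cols(m)
  d <- numeric(length(feats)); p <- numeric(length(feats))
  n1 <- length(ip); n2 <- length(ineg)
  for (j in seq_along(feats)) {
    d[j] <- ks_statistic(x[ip, j], x[ineg, j])
    p[j] <- ks_pvalue(d[j], n1, n2)
  }
  ord <- order(p, -d, seq_along(feats))
  tibble(feature = feats[ord], statistic = d[ord], p_value = p[ord])
}

median_pairwise_distance <- function(D2) {
  dv <- sqrt(D2[upper.tri(D2)])
  md <- median(dv[dv > 0])
  if (!is.finite(md) || md <= 0) 1 else md
}

#' Kernel-width search by cross-validated F-score
#'
#' Brute-force search over `cfg$sigma_factors` times the median pairwise
#' training distance; the width with the highest mean CV F-score wins, ties
#' going to the smallest width.
#'
#' @param x Training feature matrix.
#' @param y Training labels (logical or 0/1).
#' @param cfg A [kcml_config()].
#' @param fold Optional precomputed 0-based fold assignment.
#' @return List `sigma`, `fscore`, `grid` (tibble of widths and scores).
#' @export
optimize_sigma <- function(x, y, cfg = kcml_config(), fold = NULL) {
  x <- as.matrix(x)
  y <- as_pm1(y)
  D2 <- pairwise_sqdist(x)
  nfold <- min(cfg$cv_folds, min(table(y)))
  if (is.null(fold)) fold <- stratified_folds(y, nfold)
  grid <- sort(cfg$sigma_factors * median_pairwise_distance(D2))
  fs <- vapply(grid, function(s) {
    cv_fscore(D2, y, fold, nfold, s, C = cfg$C)
  }, numeric(1))
  if (all(!is.finite(fs))) abort("optimize_sigma: no usable width on the grid")
  best <- which(fs == max(fs))[1]  # grid sorted ascending: ties -> smallest
  list(sigma = grid[best], fscore = fs[best],
       grid = tibble(sigma = grid, cv_fscore = fs))
}

#' Forward feature selection by cross-validated F-score
#'
#' Candidates are visited in the given (KS-ranked) order and appended to the
#' model; a candidate is kept only when the mean CV F-score improves by more
#' than `cfg$improve_tol`. The accepted-feature score trace is therefore
#' non-decreasing. At most `cfg$max_features` features are kept; if no
#' candidate improves on the empty model, the top-ranked feature is retained
#' alone so every model has at least one feature.
#'
#' @param order Character vector of candidate features, best first.
#' @param x Training matrix containing at least those columns.
#' @param y Training labels.
#' @param sigma Kernel width to evaluate with.
#' @param cfg A [kcml_config()].
#' @param fold Optional fold assignment (0-based).
#' @return List `features` (selected, in acceptance order) and `trace`
#'   (tibble `feature`, `cv_fscore` for each accepted feature).
#' @export
forward_select <- function(order, x, y, sigma, cfg = kcml_config(),
                           fold = NULL) {
  if (length(order) == 0) abort("forward_select: empty candidate order")
  x <- as.matrix(x)
  y <- as_pm1(y)
  if (length(unique(y)) < 2) abort("forward_select: single-class training data")
  n <- nrow(x)
  nfold <- min(cfg$cv_folds, min(table(y)))
  if (is.null(fold)) fold <- stratified_folds(y, nfold)
  if (is.finite(cfg$max_candidates)) {
    order <- order[seq_len(min(length(order), cfg$max_candidates))]
  }
  D2 <- matrix(0, n, n)
  best <- 0
  selected <- character(0)
  trace <- list()
  first_f <- NA_real_
  for (f in order) {
    if (length(selected) >= cfg$max_features) break
    dv <- x[, f]
    D2c <- D2 + outer(dv, dv, "-")^2
    fc <- cv_fscore(D2c, y, fold, nfold, sigma, C = cfg$C)
    if (is.na(first_f)) first_f <- fc
    if (fc > best + cfg$improve_tol) {
      selected <- c(selected, f)
      D2 <- D2c
      best <- fc
      trace[[length(trace) + 1L]] <- tibble(feature = f, cv_fscore = fc)
    }
  }
  if (length(selected) == 0) {
    selected <- order[1]
    trace <- list(tibble(feature = order[1], cv_fscore = first_f))
  }
  list(features = selected, trace = bind_rows(trace))
}

#' Area under the ROC curve from two score samples
#'
#' Rank-statistic form: the fraction of (positive, negative) pairs ordered
#' correctly, ties counting one half.
#'
#' @param pos_scores,neg_scores Decision scores of the two classes.
#' @return AUROC in `[0, 1]`; `NA` if either class is empty.
#' @export
auroc <- function(pos_scores, neg_scores) {
  n1 <- length(pos_scores); n2 <- length(neg_scores)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

metrics_from_scores <- function(test_pos, test_neg, train_pos = NULL) {
  tp <- sum(test_pos > 0); fn <- sum(test_pos <= 0)
  fp <- sum(test_neg > 0); tn <- sum(test_neg <= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fscore <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, fscore = fscore,
       false_positive_rate = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       test_recall = recall,
       train_recall = if (is.null(train_pos)) NA_real_ else
         mean(train_pos > 0),
       auroc = auroc(test_pos, test_neg))
}

#' Evaluate a fitted classifier on held-out genes
#'
#' @param model A `kcml_svm` (or `kcml_classifier`, whose model and feature
#'   set are then used).
#' @param test_pos,test_neg Feature matrices of held-out positive / negative
#'   genes.
#' @param train_pos Optional feature matrix of training positives (for train
#'   recall).
#' @return Named list of metrics: precision, recall, F-score, false-positive
#'   rate, train/test recall, AUROC.
#' @export
evaluate_classifier <- function(model, test_pos, test_neg, train_pos = NULL) {
  if (inherits(model, "kcml_classifier")) model <- model$model
  if (nrow(test_pos) == 0 || nrow(test_neg) == 0) {
    warn("evaluate_classifier: empty test class; metrics missing")
    return(metrics_from_scores(numeric(0), numeric(0)))
  }
  metrics_from_scores(
    predict(model, test_pos), predict(model, test_neg),
    if (!is.null(train_pos)) predict(model, train_pos))
}

#' Train one term's classifier
#'
#' The full per-term pipeline: split annotated genes 70/30, sample balanced
#' negatives, rank features by KS separation, pick a coarse kernel width on
#' the top-ranked features, forward-select features by CV F-score, re-search
#' the width on the selected set, refit on the training split and evaluate on
#' the held-out split. Deterministic given `seed`.
#'
#' @param term Term identifier (bookkeeping only).
#' @param positives Genes annotated to the term.
#' @param m Profile tibble (one row per gene).
#' @param cfg A [kcml_config()].
#' @param seed Integer seed (default `cfg$rng_seed`).
#' @return A `kcml_classifier`: fields `term`, `features`, `sigma`, `model`,
#'   `metrics`, `classifiable`, `partition`, `trace`, `seed`; or `NULL` when
#'   fewer than 10 positives are present in the matrix (logged).
#' @export
train_term_classifier <- function(term, positives, m, cfg = kcml_config(),
                                  seed = cfg$rng_seed) {
  present <- intersect(positives, m$gene)
  if (length(present) < length(positives)) {
    inform(sprintf("train_term_classifier[%s]: %d positive(s) absent from matrix",
                   term, length(positives) - length(present)))
  }
  if (length(present) < 10) {
    inform(sprintf("train_term_classifier[%s]: <10 positives present; skipped",
                   term))
    return(NULL)
  }
  set.seed(seed)
  part <- split_and_sample(present, m$gene, cfg)
  x_all <- feature_matrix(m)
  tr_genes <- c(part$train_pos, part$train_neg)
  xtr <- x_all[match(tr_genes, m$gene), , drop = FALSE]
  ytr <- c(rep(1L, length(part$train_pos)), rep(-1L, length(part$train_neg)))
  stopifnot(sum(ytr == 1) == sum(ytr == -1))
  nfold <- min(cfg$cv_folds, length(part$train_pos))
  fold <- stratified_folds(ytr, nfold)

  ranking <- ks_feature_ranking(m[match(tr_genes, m$gene), ],
                                part$train_pos, part$train_neg)
  top <- head(ranking$feature, cfg$sigma_top_features)
  coarse <- optimize_sigma(xtr[, top, drop = FALSE], ytr, cfg, fold = fold)
  sel <- forward_select(ranking$feature, xtr, ytr, coarse$sigma, cfg,
                        fold = fold)
  final <- optimize_sigma(xtr[, sel$features, drop = FALSE], ytr, cfg,
                          fold = fold)
  model <- rbf_svm(xtr[, sel$features, drop = FALSE], ytr,
                   sigma = final$sigma, C = cfg$C)
  met <- metrics_from_scores(
    predict(model, x_all[match(part$test_pos, m$gene), sel$features,
                         drop = FALSE]),
    predict(model, x_all[match(part$test_neg, m$gene), sel$features,
                         drop = FALSE]),
    predict(model, x_all[match(part$train_pos, m$gene), sel$features,
                         drop = FALSE]))
  classifiable <- is_classifiable(met, cfg)
  structure(list(term = term, features = sel$features, sigma = final$sigma,
                 C = cfg$C, model = model, metrics = met,
                 classifiable = classifiable, partition = part,
                 trace = sel$trace, seed = seed),
            class = "kcml_classifier")
}

is_classifiable <- function(met, cfg) {
  isTRUE(met$false_positive_rate < cfg$fpr_max) &&
    isTRUE(met$test_recall > cfg$test_recall_min) &&
    isTRUE(met$train_recall > cfg$train_recall_min)
}

#' @export
print.kcml_classifier <- function(x, ...) {
  cat(sprintf(
    "<kcml_classifier> term %s: %d feature(s), sigma %.4g, %sclassifiable\n",
    x$term, length(x$features), x$sigma, if (x$classifiable) "" else "not "))
  cat(sprintf("  test recall %.3f | train recall %.3f | FPR %.3f | AUROC %.3f\n",
              x$metrics$test_recall, x$metrics$train_recall,
              x$metrics$false_positive_rate, x$metrics$auroc))
  invisible(x)
}

#' Train classifiers for every term of a catalog
#'
#' @param m Profile tibble.
#' @param catalog A `kcml_catalog` (see [filter_terms()]), or any tibble with
#'   `term` and a `genes` list-column.
#' @param cfg A [kcml_config()]; per-term seeds derive from `cfg$rng_seed`.
#' @param progress Emit a message per term.
#' @return A `kcml_fit`: list of `kcml_classifier`s (skipped terms omitted)
#'   with the config attached.
#' @export
train_kcml <- function(m, catalog, cfg = kcml_config(), progress = FALSE) {
  fits <- list()
  for (i in seq_len(nrow(catalog))) {
    tid <- catalog$term[i]
    if (progress) inform(sprintf("training %s (%d/%d)", tid, i, nrow(catalog)))
    clf <- train_term_classifier(tid, catalog$genes[[i]], m, cfg,
                                 seed = derive_seed(cfg$rng_seed, i))
    if (!is.null(clf)) fits[[tid]] <- clf
  }
  structure(fits, class = "kcml_fit", config = cfg)
}

#' @export
print.kcml_fit <- function(x, ...) {
  ncl <- sum(vapply(x, `[[`, logical(1), "classifiable"))
  cat(sprintf("<kcml_fit> %d term classifier(s), %d classifiable\n",
              length(x), ncl))
  invisible(x)
}

#' Keep only classifiers that pass the selection thresholds
#'
#' A classifier is kept when FPR < `fpr_max`, test recall >
#' `test_recall_min` and train recall > `train_recall_min`, all strict.
#'
#' @param fit A `kcml_fit` or list of `kcml_classifier`s.
#' @param cfg A [kcml_config()] supplying the thresholds.
#' @return The selected subset, same class as the input.
#' @export
select_classifiable <- function(fit, cfg = attr(fit, "config") %||% kcml_config()) {
  keep <- vapply(fit, function(clf) is_classifiable(clf$metrics, cfg),
                 logical(1))
  out <- fit[keep]
  if (inherits(fit, "kcml_fit")) {
    out <- structure(out, class = "kcml_fit", config = cfg)
  }
  out
}

#' Score every gene of a screen with one term classifier
#'
#' @param clf A `kcml_classifier`.
#' @param m Profile tibble containing the classifier's selected features.
#' @return Prediction tibble (`gene`, `term`, `decision_score`, `predicted`,
#'   `rank`, `off_target`); `rank` orders the predicted genes by decreasing
#'   decision score (NA for non-predicted genes).
#' @export
predict_genome <- function(clf, m) {
  missing <- setdiff(clf$features, feature_cols(m))
  if (length(missing) > 0) {
    abort(sprintf("predict_genome: matrix lacks selected feature(s): %s",
                  paste(missing, collapse = ", ")))
  }
  x <- feature_matrix(m)[, clf$features, drop = FALSE]
  s <- predict(clf$model, x)
  out <- tibble(gene = m$gene, term = clf$term, decision_score = s,
                predicted = s > 0)
  out$rank <- NA_integer_
  idx <- which(out$predicted)
  out$rank[idx] <- rank(-out$decision_score[idx], ties.method = "first")
  out$off_target <- FALSE
  arrange(out, dplyr::desc(.data$decision_score))
}

#' Predict with every classifier of a fit
#'
#' @param object A `kcml_fit`.
#' @param m Profile tibble.
#' @param classifiable_only Score only classifiers that passed selection
#'   (default `TRUE`).
#' @param ... Unused.
#' @return Combined prediction tibble with `zscored_rank` added (per gene,
#'   the z-score of its decision scores across terms; NA with fewer than two
#'   terms).
#' @export
predict.kcml_fit <- function(object, m, classifiable_only = TRUE, ...) {
  fits <- if (classifiable_only) select_classifiable(object) else object
  if (length(fits) == 0) {
    warn("predict.kcml_fit: no classifiable terms")
    return(tibble(gene = character(0), term = character(0),
                  decision_score = numeric(0), predicted = logical(0),
                  rank = integer(0), off_target = logical(0),
                  zscored_rank = numeric(0)))
  }
  pred <- bind_rows(lapply(fits, predict_genome, m = m))
  add_zscored_rank(pred)
}

#' Z-score each gene's decision scores across terms
#'
#' Expresses, per gene, how strongly one term's classifier scores it relative
#' to the gene's score distribution over all terms (used for cross-term
#' heatmaps of prediction strength).
#'
#' @param pred Combined prediction tibble (multiple terms).
#' @return The tibble with a `zscored_rank` column.
#' @export
add_zscored_rank <- function(pred) {
  pred |>
    group_by(.data$gene) |>
    mutate(zscored_rank = if (n() > 1 && sd(.data$decision_score) > 0) {
      (.data$decision_score - mean(.data$decision_score)) /
        sd(.data$decision_score)
    } else NA_real_) |>
    ungroup()
}

#' Consensus predictions from cross-validated refits
#'
#' With features and kernel width frozen, the model is refit on
#' `consensus_folds` leave-one-fold-out partitions of all annotated genes
#' (fresh balanced negatives per refit); a gene is a consensus prediction when
#' at least `consensus_required` of the refits score it positive.
#'
#' @param clf A classifiable `kcml_classifier`.
#' @param positives All genes annotated to the term.
#' @param m Profile tibble.
#' @param cfg A [kcml_config()].
#' @param seed Integer seed.
#' @return Prediction tibble with `n_votes` and consensus `predicted`.
#' @export
consensus_retrain <- function(clf, positives, m, cfg = kcml_config(),
                              seed = cfg$rng_seed) {
  if (!clf$classifiable) warn("consensus_retrain: classifier did not pass selection")
  set.seed(seed)
  present <- intersect(positives, m$gene)
  nf <- cfg$consensus_folds
  fold <- sample(rep_len(seq_len(nf), length(present)))
  x_all <- feature_matrix(m)[, clf$features, drop = FALSE]
  pool <- setdiff(m$gene, present)
  votes <- integer(nrow(m))
  for (f in seq_len(nf)) {
    tr_pos <- present[fold != f]
    tr_neg <- sample(pool, length(tr_pos))
    xtr <- x_all[match(c(tr_pos, tr_neg), m$gene), , drop = FALSE]
    ytr <- c(rep(1L, length(tr_pos)), rep(-1L, length(tr_neg)))
    mod <- rbf_svm(xtr, ytr, sigma = clf$sigma, C = clf$C)
    votes <- votes + as.integer(predict(mod, x_all) > 0)
  }
  out <- tibble(gene = m$gene, term = clf$term, n_votes = votes,
                predicted = votes >= cfg$consensus_required)
  arrange(out, dplyr::desc(.data$n_votes))
}

#' Null control: train classifiers on random gene sets
#'
#' Draws `n_sets` random gene sets of `set_size` genes and runs the full
#' training pipeline on each, as the empirical null against which the
#' selection thresholds are calibrated: on signal-free data essentially no
#' random set should yield a classifiable model.
#'
#' @param m Profile tibble.
#' @param cfg A [kcml_config()].
#' @param n_sets Number of random sets (100).
#' @param set_size Genes per set (200).
#' @return List with `metrics` (one row per set: test/train recall, FPR,
#'   AUROC, classifiable) and `pass_rate`.
#' @export
random_geneset_baseline <- function(m, cfg = kcml_config(), n_sets = 100,
                                    set_size = 200) {
  stopifnot(nrow(m) > 2 * set_size)
  rows <- list()
  for (i in seq_len(n_sets)) {
    set.seed(derive_seed(cfg$rng_seed, 100000 + i))
    genes <- sample(m$gene, set_size)
    clf <- train_term_classifier(paste0("random_", i), genes, m, cfg,
                                 seed = derive_seed(cfg$rng_seed, 200000 + i))
    rows[[i]] <- tibble(
      set = i, test_recall = clf$metrics$test_recall,
      train_recall = clf$metrics$train_recall,
      false_positive_rate = clf$metrics$false_positive_rate,
      auroc = clf$metrics$auroc, n_features = length(clf$features),
      classifiable = clf$classifiable)
  }
  metrics <- bind_rows(rows)
  list(metrics = metrics, pass_rate = mean(metrics$classifiable))
}

#' Right-tail Fisher / hypergeometric p-value of a 2x2 overlap
#'
#' Probability of observing `k` or more successes when drawing `n` items
#' from a universe of `N` containing `K` successes (the right-tail Fisher
#' exact test of the corresponding 2x2 table).
#'
#' @param k Observed overlap.
#' @param K Successes in the universe.
#' @param n Draws.
#' @param N Universe size.
#' @return Upper-tail p-value `P(X >= k)`.
#' @export
fisher_right_tail <- function(k, K, n, N) {
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Validate predictions against annotations accrued in a later release
#'
#' For every predicted term, genes not annotated in the old release form the
#' validation universe; the overlap between the classifier's predicted genes
#' and the newly annotated genes is scored by a right-tail Fisher exact test,
#' alongside the fraction of new annotations that were predicted.
#'
#' @param pred Combined prediction tibble.
#' @param old Annotation set at training time.
#' @param new_diff Newly accrued `(gene, term)` pairs (see
#'   [new_annotation_diff()]); must be disjoint from `old`.
#' @return Tibble (`term`, `n_new`, `n_predicted`, `n_overlap`,
#'   `fraction_predicted`, `p_value`).
#' @export
validate_new_annotations <- function(pred, old, new_diff) {
  if (nrow(dplyr::semi_join(new_diff, old, by = c("gene", "term"))) > 0) {
    abort("validate_new_annotations: new_diff overlaps the old annotation set")
  }
  rows <- list()
  for (tid in unique(pred$term)) {
    ptab <- pred[pred$term == tid, ]
    old_genes <- old$gene[old$term == tid]
    uni <- setdiff(unique(ptab$gene), old_genes)
    new_genes <- intersect(new_diff$gene[new_diff$term == tid], uni)
    if (length(new_genes) == 0) {
      inform(sprintf("validate_new_annotations: no new annotations for %s; skipped",
                     tid))
      next
    }
    pred_genes <- intersect(ptab$gene[ptab$predicted], uni)
    k <- length(intersect(pred_genes, new_genes))
    rows[[tid]] <- tibble(
      term = tid, n_new = length(new_genes),
      n_predicted = length(pred_genes), n_overlap = k,
      fraction_predicted = k / length(new_genes),
      p_value = fisher_right_tail(k, length(new_genes), length(pred_genes),
                                  length(uni)))
  }
  bind_rows(rows)
}
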