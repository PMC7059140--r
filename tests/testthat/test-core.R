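test_that("splitting is 70/30, balanced, seed-reproducible and disjoint", {
  universe <- sprintf("g%04d", 1:1000)
  pos <- universe[1:100]
  set.seed(1)
  part <- split_and_sample(pos, universe)
  expect_equal(length(part$train_pos), 70)
  expect_equal(length(part$test_pos), 30)
  expect_equal(length(part$train_neg), 70)
  expect_equal(length(part$test_neg), 30)
  set.seed(1)
  expect_identical(split_and_sample(pos, universe), part)
  for (i in 1:100) {
    set.seed(i)
    p <- split_and_sample(pos, universe)
    expect_length(intersect(c(p$train_neg, p$test_neg), pos), 0)
    expect_length(intersect(p$train_pos, p$test_pos), 0)
    expect_length(intersect(p$train_neg, p$test_neg), 0)
  }
  # odd count: ceil for training
  set.seed(2)
  p2 <- split_and_sample(universe[1:15], universe)
  expect_equal(length(p2$train_pos), 11)  # ceiling(0.7 * 15)
  expect_error(split_and_sample(universe[1:600], universe[1:1000]),
               "not enough")
})

test_that("KS feature ranking matches a per-feature sweep and finds signal", {
  set.seed(5)
  n <- 40
  m <- tibble::tibble(gene = sprintf("g%02d", 1:(2 * n)))
  for (j in 1:10) m[[sprintf("f%02d", j)]] <- rnorm(2 * n)
  m$f03 <- c(rnorm(n, 3), rnorm(n))  # planted separation
  pos <- m$gene[1:n]; neg <- m$gene[(n + 1):(2 * n)]
  rk <- ks_feature_ranking(m, pos, neg)
  expect_equal(rk$feature[1], "f03")
  # oracle sweep with stats::ks.test statistics
  for (f in rk$feature) {
    d_oracle <- unname(suppressWarnings(
      stats::ks.test(m[[f]][1:n], m[[f]][(n + 1):(2 * n)])$statistic))
    expect_equal(rk$statistic[rk$feature == f], d_oracle)
  }
  expect_true(!is.unsorted(rk$p_value))
})

test_that("forward selection has a monotone trace and respects the cap", {
  set.seed(6)
  n <- 30
  x <- matrix(rnorm(2 * n * 12), 2 * n, 12,
              dimnames = list(NULL, sprintf("f%02d", 1:12)))
  x[1:n, 1] <- x[1:n, 1] + 2   # informative feature f01
  y <- rep(c(1L, -1L), each = n)
  sel <- forward_select(colnames(x), x, y, sigma = 2,
                        cfg = kcml_config(cv_folds = 5, rng_seed = 1))
  expect_true("f01" %in% sel$features)
  expect_true(!is.unsorted(sel$trace$cv_fscore))
  expect_gte(length(sel$features), 1)

  capped <- forward_select(colnames(x), x, y, sigma = 2,
                           cfg = kcml_config(cv_folds = 5, max_features = 2))
  expect_lte(length(capped$features), 2)
  expect_error(forward_select(colnames(x), x, rep(1L, 2 * n), sigma = 2),
               "single-class")
  expect_error(forward_select(character(0), x, y, 2), "empty")
})

test_that("kernel-width search picks the CV-optimal grid point", {
  set.seed(7)
  n <- 30
  x <- rbind(matrix(rnorm(n * 2, 2), n, 2), matrix(rnorm(n * 2, -2), n, 2))
  y <- rep(c(1L, -1L), each = n)
  cfg1 <- kcml_config(sigma_factors = 1, cv_folds = 5)
  res1 <- optimize_sigma(x, y, cfg1)
  expect_equal(nrow(res1$grid), 1)
  expect_equal(res1$sigma, res1$grid$sigma[1])

  cfg <- kcml_config(sigma_factors = 2^(-2:2), cv_folds = 5, rng_seed = 3)
  set.seed(3)
  res <- optimize_sigma(x, y, cfg)
  # exhaustive re-evaluation: no grid point beats the winner
  expect_true(all(res$grid$cv_fscore <= res$fscore + 1e-12))
  set.seed(3)
  res2 <- optimize_sigma(x, y, cfg)
  expect_identical(res$sigma, res2$sigma)
})

test_that("metric formulas and AUROC match their oracles", {
  # precision 0.5, recall 1.0 -> F = 2/3
  met <- kcml:::metrics_from_scores(test_pos = c(1, 2),
                                    test_neg = c(1, 1, -1, -1))
  expect_equal(met$precision, 0.5)
  expect_equal(met$recall, 1.0)
  expect_equal(met$fscore, 2 / 3)
  expect_equal(met$false_positive_rate, 0.5)

  # perfect separation
  met2 <- kcml:::metrics_from_scores(c(1, 2, 3), c(-1, -2))
  expect_equal(met2$auroc, 1.0)
  expect_equal(met2$false_positive_rate, 0.0)

  # AUROC equals the all-pairs oracle, ties counting one half
  set.seed(8)
  for (i in 1:20) {
    p <- sample(0:5, 7, replace = TRUE)
    q <- sample(0:5, 9, replace = TRUE)
    oracle <- (sum(outer(p, q, ">")) + 0.5 * sum(outer(p, q, "=="))) /
      (length(p) * length(q))
    expect_equal(auroc(p, q), oracle)
  }
  expect_true(is.na(auroc(numeric(0), 1:3)))
})

test_that("classifiability thresholds are strict on all three metrics", {
  cfg <- kcml_config()
  fake <- function(fpr, test_r, train_r) {
    structure(list(term = "x", metrics = list(
      false_positive_rate = fpr, test_recall = test_r,
      train_recall = train_r)), class = "kcml_classifier")
  }
  sel <- function(...) length(select_classifiable(list(fake(...)), cfg))
  expect_equal(sel(0.19, 0.31, 0.41), 1)
  expect_equal(sel(0.20, 0.31, 0.41), 0)  # FPR not strictly below
  expect_equal(sel(0.19, 0.30, 0.41), 0)  # recall not strictly above
  expect_equal(sel(0.19, 0.31, 0.40), 0)
  expect_length(select_classifiable(list(), cfg), 0)
})

test_that("the planted-term classifier recovers signal and is deterministic", {
  sc <- small_screen()
  clf <- small_classifier()
  expect_true(clf$classifiable)
  truth <- sc$truth$terms$T1$informative_features
  expect_gte(mean(clf$features %in% truth), 0.5)
  # identical seed -> identical metrics and features
  clf2 <- train_term_classifier("T1", sc$truth$terms$T1$positives,
                                sc$profiles, kcml_config(rng_seed = 11))
  expect_identical(glance(clf), glance(clf2))
  expect_identical(clf$features, clf2$features)
  # balanced training enforced
  expect_equal(length(clf$partition$train_pos),
               length(clf$partition$train_neg))
})

test_that("terms with too few profiled positives are skipped", {
  sc <- small_screen()
  expect_message(
    out <- train_term_classifier("tiny", sc$profiles$gene[1:5], sc$profiles),
    "skipped")
  expect_null(out)
})

test_that("genome-wide prediction ranks by decision score", {
  sc <- small_screen()
  clf <- small_classifier()
  pred <- predict_genome(clf, sc$profiles)
  expect_setequal(pred$gene, sc$profiles$gene)
  expect_equal(pred$rank[1], 1)
  expect_equal(pred$decision_score[1], max(pred$decision_score))
  expect_true(all(pred$predicted == (pred$decision_score > 0)))
  # ranks are a permutation of 1..n_predicted
  expect_setequal(pred$rank[pred$predicted], seq_len(sum(pred$predicted)))
  # training positives mostly recovered
  expect_gt(mean(pred$predicted[pred$gene %in% clf$partition$train_pos]),
            0.5)
  # row-permutation invariance
  set.seed(9)
  perm <- sample(nrow(sc$profiles))
  pred2 <- predict_genome(clf, sc$profiles[perm, ])
  expect_equal(pred2$decision_score[match(pred$gene, pred2$gene)],
               pred$decision_score)
  bad <- dplyr::select(sc$profiles, -dplyr::all_of(clf$features[1]))
  expect_error(predict_genome(clf, bad), clf$features[1], fixed = TRUE)
})

test_that("consensus retraining intersects cross-validated refits", {
  sc <- small_screen()
  clf <- small_classifier()
  pos <- sc$truth$terms$T1$positives
  cons <- consensus_retrain(clf, pos, sc$profiles,
                            kcml_config(rng_seed = 13))
  single <- predict_genome(clf, sc$profiles)
  # consensus at 7/10 is more stringent than typical single-model calls
  expect_true(all(cons$n_votes >= 0 & cons$n_votes <= 10))
  expect_lte(sum(cons$predicted), sum(single$predicted) * 1.5)
  # required = folds means unanimity: consensus = intersection of refits
  cfg_all <- kcml_config(consensus_folds = 10, consensus_required = 10,
                         rng_seed = 13)
  cons_all <- consensus_retrain(clf, pos, sc$profiles, cfg_all)
  expect_true(all(cons_all$n_votes[cons_all$predicted] == 10))
  expect_true(all(cons_all$predicted == (cons_all$n_votes == 10)))
  # determinism
  cons2 <- consensus_retrain(clf, pos, sc$profiles,
                             kcml_config(rng_seed = 13))
  expect_identical(cons, cons2)
})

test_that("fit-level training, selection and tidiers work end to end", {
  sc <- generate_screen(screen_spec(
    n_genes = 300, n_features = 25, missing_rate = 0,
    terms = tibble::tibble(term = c("T1", "T2"), n_positive = c(60, 50),
                           n_informative = 5, effect_size = c(1.5, 0)),
    seed = 31))
  cat <- tibble::tibble(term = names(sc$truth$terms),
                        genes = lapply(sc$truth$terms, `[[`, "positives"))
  fit <- train_kcml(sc$profiles, cat, kcml_config(rng_seed = 17,
                                                  sigma_factors = 2^(-1:1)))
  expect_s3_class(fit, "kcml_fit")
  expect_length(fit, 2)
  g <- glance(fit)
  expect_equal(nrow(g), 2)
  expect_true(g$classifiable[g$term == "T1"])
  td <- tidy(fit)
  expect_true(all(td$feature[td$term == "T1"] %in%
                    feature_cols(sc$profiles)))
  sel <- select_classifiable(fit)
  expect_true(all(vapply(sel, `[[`, logical(1), "classifiable")))
  pred <- predict(fit, sc$profiles)
  expect_true(all(c("zscored_rank", "off_target") %in% names(pred)))
})

test_that("validation against later annotations matches enumeration", {
  # 20-gene universe: all newly annotated genes predicted, none else
  genes <- sprintf("g%02d", 1:20)
  pred <- tibble::tibble(gene = genes, term = "T1",
                         decision_score = c(rep(1, 5), rep(-1, 15)),
                         predicted = c(rep(TRUE, 5), rep(FALSE, 15)),
                         rank = NA_integer_, off_target = FALSE)
  old <- annotation_set(character(0), character(0))
  new <- annotation_set(genes[1:5], rep("T1", 5))
  v <- validate_new_annotations(pred, old, new)
  expect_equal(v$fraction_predicted, 1.0)
  expect_equal(v$p_value, hyper_tail_oracle(5, 5, 5, 20))

  # permutation null: p roughly uniform
  set.seed(10)
  pv <- replicate(200, {
    newp <- annotation_set(sample(genes, 5), rep("T1", 5))
    validate_new_annotations(pred, old, newp)$p_value
  })
  expect_gt(mean(pv > 0.5), 0.25)  # not concentrated at small p
  # empty diff: term skipped
  expect_message(
    v2 <- validate_new_annotations(pred, old,
                                   annotation_set("g01", "other")),
    "skipped")
  expect_equal(nrow(v2), 0)
  expect_error(validate_new_annotations(pred, new, new), "overlaps")
})

test_that("fisher right tail equals the enumeration oracle", {
  set.seed(11)
  for (i in 1:50) {
    N <- sample(5:30, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(fisher_right_tail(k, K, n, N),
                 hyper_tail_oracle(k, K, n, N), tolerance = 1e-12)
    # and agrees with stats::fisher.test
    tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2)
    if (all(tab >= 0)) {
      expect_equal(fisher_right_tail(k, K, n, N),
                   stats::fisher.test(tab, alternative = "greater")$p.value,
                   tolerance = 1e-9)
    }
  }
})
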