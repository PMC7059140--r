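test_that("scaled rank-sum matches the pair-counting oracle", {
  expect_equal(rank_sum_scaled(c(3, 4), c(1, 2)), 4.0)
  expect_equal(rank_sum_scaled(c(1, 2), c(3, 4)), 0.0)
  expect_equal(rank_sum_scaled(1, 1), 0.25)
  expect_message(expect_true(is.na(rank_sum_scaled(numeric(0), 1:3))),
                 "empty")

  set.seed(7)
  for (i in 1:100) {
    n1 <- sample(1:20, 1); n2 <- sample(1:20, 1)
    x <- sample(0:8, n1, replace = TRUE)  # integer values force ties
    y <- sample(0:8, n2, replace = TRUE)
    sf <- n1 * n2 / (n1 + n2)
    expect_equal(rank_sum_scaled(x, y), u_oracle(x, y) * sf)
    # swap symmetry: U -> n1 n2 - U
    expect_equal(rank_sum_scaled(y, x) / sf + rank_sum_scaled(x, y) / sf,
                 n1 * n2)
  }
  # sqrt variant
  expect_equal(rank_sum_scaled(c(3, 4), c(1, 2), sf = "sqrt"), 4 * sqrt(1))
})

test_that("scaled KS distance matches the brute-force ECDF-gap oracle", {
  expect_equal(ks_distance_scaled(c(1, 2, 3), c(1, 2, 3)), 0.0)
  expect_equal(ks_distance_scaled(c(10, 11), c(0, 1)), 1.0)
  expect_equal(ks_distance_scaled(c(1, 3), c(2, 4)), 0.5)

  set.seed(8)
  for (i in 1:100) {
    n1 <- sample(2:25, 1); n2 <- sample(2:25, 1)
    x <- rnorm(n1); y <- rnorm(n2, sd = 2)
    sf <- n1 * n2 / (n1 + n2)
    expect_equal(ks_distance_scaled(x, y), ks_oracle(x, y) * sf)
    expect_equal(ks_distance_scaled(x, y), ks_distance_scaled(y, x))
  }
})

test_that("bimodality coefficient hits its analytic anchors", {
  set.seed(1)
  expect_equal(bimodality_coefficient(rnorm(2e5)), 1 / 3, tolerance = 0.02)
  expect_equal(bimodality_coefficient(runif(2e5)), 1 / 1.8,
               tolerance = 0.02)
  expect_true(is.na(bimodality_coefficient(rep(2, 50))))
  expect_true(is.na(bimodality_coefficient(1:3)))
})

test_that("well aggregation produces one value per feature-statistic pair", {
  cells <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:9),
    well_id = rep(c("w1", "w2", "w3"), each = 3),
    gene = rep(c("scrambled", "gA", "gB"), each = 3),
    plate_id = "p1",
    f1 = c(1, 2, 3, 4, 5, 6, 5, 5, 5),
    f2 = c(0, 0, 1, 1, 1, 1, 0, 1, 0))
  spec <- aggregation_spec(stats = c("mean", "sd"))
  prof <- aggregate_wells(cells, spec = spec)
  expect_equal(nrow(prof), 3)
  expect_setequal(setdiff(feature_cols(prof), "tcn"),
                  c("f1_mean", "f1_sd", "f2_mean", "f2_sd"))
  expect_equal(prof$f1_mean[prof$gene == "gA"], 5)
  expect_equal(prof$f1_sd[prof$gene == "scrambled"], 1)
  expect_equal(prof$tcn, rep(3L, 3))

  # constant feature: skewness encoded missing, not zero
  spec2 <- aggregation_spec(stats = c("sd", "skewness"))
  prof2 <- aggregate_wells(cells, spec = spec2)
  expect_equal(prof2$f1_sd[prof2$gene == "gB"], 0)
  expect_true(is.na(prof2$f1_skewness[prof2$gene == "gB"]))

  # full default spec: column count |features| x |stats| (+tcn)
  full <- aggregate_wells(cells)
  n_stats <- 9 + 7  # mean sd iqr range skew kurt bimod ks ranksum + 7 quantiles
  expect_equal(length(setdiff(feature_cols(full), "tcn")), 2 * n_stats)
})

test_that("state fractions normalise each label by the well cell count", {
  w <- tibble::tibble(state_mitotic = c(rep(TRUE, 5), rep(FALSE, 45)),
                      state_infected = rep(FALSE, 50))
  fr <- state_fractions(w)
  expect_equal(unname(fr["frac_mitotic"]), 0.10)
  expect_equal(unname(fr["frac_infected"]), 0.0)
  set.seed(2)
  w2 <- tibble::tibble(state_a = runif(40) < 0.3, state_b = runif(40) < 0.6)
  fr2 <- state_fractions(w2)
  expect_equal(unname(fr2), c(sum(w2$state_a) / 40, sum(w2$state_b) / 40))
  expect_true(all(is.na(state_fractions(w2[0, ]))))
})

test_that("missingness cleaning drops rows first, then features", {
  set.seed(3)
  m <- tibble::tibble(gene = sprintf("g%02d", 1:10))
  for (j in 1:10) m[[sprintf("f%02d", j)]] <- rnorm(10)
  m_bad <- m
  m_bad[1, 2:5] <- NA            # row 1: 40% missing -> dropped
  cleaned <- clean_profiles(m_bad)
  expect_equal(nrow(cleaned), 9)
  expect_false("g01" %in% cleaned$gene)
  expect_equal(clean_profiles(m), m, ignore_attr = TRUE)

  # crafted: feature missing in 4/10 rows, but only 3/9 once row 1 is gone
  m2 <- m
  m2[1, 2:8] <- NA               # row 1 dropped (70%)
  m2[2:4, "f09"] <- NA           # f09: 4/10 = 40%, after row drop 3/9 = 33% > 30%
  cleaned2 <- clean_profiles(m2)
  expect_false("f09" %in% names(cleaned2))
  # oracle re-check on the survivors
  x <- feature_matrix(cleaned2)
  expect_true(all(rowMeans(is.na(x)) <= 0.30))
  expect_true(all(colMeans(is.na(x)) <= 0.30))

  m3 <- m
  m3[, -1] <- NA
  expect_error(clean_profiles(m3), "missingness")
})

test_that("feature k-NN imputation matches the by-column oracle", {
  # all other columns identical to the missing one
  m <- tibble::tibble(gene = sprintf("g%d", 1:5),
                      a = c(1, 2, 3, 4, NA), b = c(1, 2, 3, 4, 5),
                      c = c(1, 2, 3, 4, 5))
  out <- impute_knn_features(m, k = 10)
  expect_equal(out$a[5], 5)

  # k = 1: exactly the nearest column's value
  m2 <- tibble::tibble(gene = sprintf("g%d", 1:4),
                       a = c(0, 1, 2, NA), b = c(0, 1, 2, 10),
                       c = c(5, 8, 9, 20))
  out2 <- impute_knn_features(m2, k = 1)
  expect_equal(out2$a[4], 10)

  # random matrix vs brute-force oracle
  set.seed(11)
  x <- matrix(rnorm(30 * 15), 30, 15)
  miss <- matrix(runif(30 * 15) < 0.05, 30, 15)
  x[miss] <- NA
  m3 <- dplyr::bind_cols(tibble::tibble(gene = sprintf("g%02d", 1:30)),
                         tibble::as_tibble(as.data.frame(x)))
  out3 <- impute_knn_features(m3, k = 10)
  # oracle
  d <- matrix(Inf, 15, 15)
  for (i in 1:14) for (j in (i + 1):15) {
    both <- !is.na(x[, i]) & !is.na(x[, j])
    if (any(both)) d[i, j] <- d[j, i] <- sqrt(mean((x[both, i] - x[both, j])^2))
  }
  for (j in 1:15) for (i in which(miss[, j])) {
    ord <- order(d[, j]); ord <- ord[ord != j]
    nb <- ord[!is.na(x[i, ord])][1:10]
    nb <- nb[!is.na(nb)]
    w <- 1 / (d[nb, j] + 1e-12)
    expect_equal(out3[[sprintf("V%d", j)]][i], sum(w * x[i, nb]) / sum(w))
  }
  expect_true(all(is.finite(feature_matrix(out3))))
})

test_that("plate z-scoring centres and scales per plate", {
  set.seed(4)
  m <- tibble::tibble(gene = sprintf("g%02d", 1:20),
                      plate_id = rep(c("p1", "p2"), each = 10),
                      f1 = c(rnorm(10, 5), rnorm(10, -5)),
                      f2 = rep(3, 20))
  z <- plate_zscore(m)
  for (pl in c("p1", "p2")) {
    v <- z$f1[z$plate_id == pl]
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
  expect_true(all(z$f2 == 0))
  # single plate = global z-score
  m1 <- m |> dplyr::mutate(plate_id = "p1")
  z1 <- plate_zscore(m1)
  expect_equal(z1$f1, as.numeric(scale(m$f1)), tolerance = 1e-12)
})

test_that("replicate averaging equals the group-by-mean oracle", {
  m <- tibble::tibble(gene = c("a", "a", "b"), well_id = c("w1", "w2", "w3"),
                      tcn = c(100, 200, 50), f1 = c(0, 2, 7))
  avg <- average_replicates(m)
  expect_equal(avg$f1[avg$gene == "a"], 1)
  expect_equal(avg$tcn[avg$gene == "a"], 150)
  expect_equal(avg$f1[avg$gene == "b"], 7)

  set.seed(5)
  m2 <- tibble::tibble(gene = sample(letters[1:5], 40, replace = TRUE),
                       f1 = rnorm(40), f2 = rnorm(40))
  avg2 <- average_replicates(m2)
  oracle <- aggregate(cbind(f1, f2) ~ gene, data = m2, FUN = mean)
  expect_equal(avg2$f1, oracle$f1[match(avg2$gene, oracle$gene)])
})

test_that("viability filtering is strict at the cell-count threshold", {
  m <- tibble::tibble(gene = c("a", "b", "c"), tcn = c(624, 625, 5000),
                      f1 = 1:3)
  out <- viability_filter(m)
  expect_setequal(out$gene, c("b", "c"))
  set.seed(6)
  m2 <- tibble::tibble(gene = sprintf("g%02d", 1:50),
                       tcn = sample(100:2000, 50), f1 = rnorm(50))
  out2 <- viability_filter(m2, min_cells = 625)
  expect_setequal(out2$gene, m2$gene[m2$tcn >= 625])
})

test_that("cell-number correction removes the TCN confound", {
  # all TCN equal: one bin, equals global z-score
  set.seed(12)
  m <- tibble::tibble(gene = sprintf("g%03d", 1:300), tcn = 1000,
                      f1 = rnorm(300))
  out <- correct_cell_number(m, n_bins = 32, min_per_bin = 100)
  expect_equal(out$f1, as.numeric(scale(m$f1)), tolerance = 1e-12)
  expect_equal(length(unique(attr(out, "tcn_bin"))), 1)

  # confounded feature: r > 0.9 before, < 0.1 after
  set.seed(13)
  n <- 4000
  tcn <- round(rlnorm(n, log(3000), 0.4))
  tz <- (tcn - mean(tcn)) / sd(tcn)
  m2 <- tibble::tibble(gene = sprintf("g%04d", 1:n), tcn = tcn,
                       f1 = 2 * tz + rnorm(n, sd = 0.2), f2 = rnorm(n))
  expect_gt(abs(cor(m2$f1, m2$tcn)), 0.9)
  out2 <- correct_cell_number(m2, n_bins = 32, min_per_bin = 100)
  expect_lt(abs(cor(out2$f1, out2$tcn)), 0.1)
  # every bin is large enough and internally standardised
  bins <- attr(out2, "tcn_bin")
  expect_true(all(table(bins) >= 100))
  for (b in unique(bins)) {
    v <- out2$f2[bins == b]
    expect_equal(mean(v), 0, tolerance = 1e-9)
    expect_equal(sd(v), 1, tolerance = 1e-9)
  }
})

test_that("PCA reduction is sign-fixed and matches the eigendecomposition", {
  # rank-1 matrix: first component explains ~everything
  set.seed(14)
  u <- rnorm(20); v <- rnorm(3)
  m <- dplyr::bind_cols(tibble::tibble(gene = sprintf("g%02d", 1:20)),
                        tibble::as_tibble(as.data.frame(outer(u, v))))
  red <- reduce_pca(m, 2, zscore = FALSE)
  ev <- attr(red, "explained_variance")
  expect_gt(ev[1], 0.999)

  # scores match direct eigendecomposition of the covariance (up to sign)
  x <- matrix(rnorm(200), 20, 10)
  m2 <- dplyr::bind_cols(tibble::tibble(gene = sprintf("g%02d", 1:20)),
                         tibble::as_tibble(as.data.frame(x)))
  red2 <- reduce_pca(m2, 4, zscore = FALSE)
  xc <- scale(x, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(xc) / (nrow(x) - 1))
  sc_oracle <- xc %*% eig$vectors[, 1:4]
  for (j in 1:4) {
    got <- feature_matrix(red2)[, j]
    expect_true(max(abs(got - sc_oracle[, j])) < 1e-8 ||
                  max(abs(got + sc_oracle[, j])) < 1e-8)
  }
  # deterministic sign: largest-magnitude loading positive
  red2b <- reduce_pca(m2, 4, zscore = FALSE)
  expect_identical(feature_matrix(red2), feature_matrix(red2b))
  expect_warning(reduce_pca(m2, 50), "clipped")
})

test_that("clean-impute-zscore pipeline yields a finite matrix", {
  sc <- generate_screen(screen_spec(
    n_genes = 80, n_features = 15, missing_rate = 0.08,
    terms = tibble::tibble(term = "T1", n_positive = 20,
                           n_informative = 3, effect_size = 1),
    seed = 21))
  out <- plate_zscore(impute_knn_features(clean_profiles(sc$profiles)))
  expect_true(all(is.finite(feature_matrix(out))))
  # deterministic
  out2 <- plate_zscore(impute_knn_features(clean_profiles(sc$profiles)))
  expect_identical(out, out2)
})
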