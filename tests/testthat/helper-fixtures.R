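# Shared fixtures, built once per test run. Everything is generated in code;
# sizes are kept small so the whole suite stays fast.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# a small planted-signal screen used across core/postprocess tests
small_screen <- function() {
  fixture("small_screen", function() {
    generate_screen(screen_spec(
      n_genes = 400, n_features = 40, missing_rate = 0,
      terms = tibble::tibble(term = "T1", n_positive = 80,
                             n_informative = 6, effect_size = 1.5),
      seed = 101))
  })
}

small_classifier <- function() {
  fixture("small_classifier", function() {
    sc <- small_screen()
    train_term_classifier("T1", sc$truth$terms$T1$positives, sc$profiles,
                          kcml_config(rng_seed = 11))
  })
}

# pure-noise screen (no terms)
noise_screen <- function(n_genes = 300, n_features = 25, seed = 77) {
  generate_screen(screen_spec(
    n_genes = n_genes, n_features = n_features, missing_rate = 0,
    terms = tibble::tibble(term = character(0), n_positive = integer(0),
                           n_informative = integer(0),
                           effect_size = numeric(0)),
    seed = seed))
}

# random annotation set over a gene universe
random_annotations <- function(n_genes = 50, n_terms = 8, rate = 0.2,
                               seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  pairs <- expand.grid(gene = genes, term = terms,
                       stringsAsFactors = FALSE)
  pairs <- pairs[runif(nrow(pairs)) < rate, ]
  annotation_set(pairs$gene, pairs$term)
}

# independent transitive-closure oracle by exhaustive path enumeration
ancestors_oracle <- function(term, edges) {
  out <- character(0)
  frontier <- term
  repeat {
    parents <- unique(edges$parent[edges$child %in% frontier])
    new <- setdiff(parents, out)
    if (length(new) == 0) break
    out <- c(out, new)
    frontier <- new
  }
  sort(out)
}

# pair-counting oracle for the rank-sum statistic (ties count one half)
u_oracle <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# brute-force max ECDF gap over all pooled points
ks_oracle <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, numeric(1)))
}

# choose()-based enumeration oracle for the hypergeometric upper tail
hyper_tail_oracle <- function(k, K, n, N) {
  ks <- k:min(K, n)
  ks <- ks[ks >= max(0, n - (N - K))]
  if (length(ks) == 0) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
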