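#' Specification of a synthetic perturbation screen
#'
#' Describes the stated world the generator emits: a gene x feature matrix of
#' Gaussian (optionally heavy-tailed) background noise, a set of planted
#' terms whose annotated genes are shifted on a term-specific subset of
#' informative features, completely-at-random missingness, and a total cell
#' number (TCN) drawn per gene which may confound chosen features.
#'
#' @param n_genes Number of perturbed genes (default 2,000).
#' @param n_features Number of aggregated features (default 200).
#' @param terms Tibble (or data frame) with columns `term`, `n_positive`,
#'   `n_informative`, `effect_size`; defaults to 5 terms of 100-200 genes,
#'   10 informative features each, effect 1.0 SD.
#' @param noise_sd Background standard deviation (1).
#' @param missing_rate Missing-completely-at-random rate (0.02).
#' @param tcn_meanlog,tcn_sdlog Log-normal TCN model (defaults centred near
#'   3,000 cells per perturbation).
#' @param confound_features Number of features made linearly dependent on TCN
#'   (0 by default).
#' @param confound_coef Slope of the TCN confound (2).
#' @param heavy_tailed Use a t(3) background instead of Gaussian.
#' @param seed Integer seed.
#' @return An object of class `kcml_screen_spec`.
#' @export
screen_spec <- function(n_genes = 2000, n_features = 200,
                        terms = default_term_specs(),
                        noise_sd = 1, missing_rate = 0.02,
                        tcn_meanlog = log(3000), tcn_sdlog = 0.4,
                        confound_features = 0, confound_coef = 2,
                        heavy_tailed = FALSE, seed = 1L) {
  terms <- as_tibble(terms)
  stopifnot(all(terms$n_informative <= n_features),
            all(terms$n_positive <= n_genes),
            all(terms$effect_size >= 0),
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_genes = n_genes, n_features = n_features, terms = terms,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 tcn_meanlog = tcn_meanlog, tcn_sdlog = tcn_sdlog,
                 confound_features = confound_features,
                 confound_coef = confound_coef,
                 heavy_tailed = heavy_tailed, seed = as.integer(seed)),
            class = "kcml_screen_spec")
}

default_term_specs <- function() {
  tibble(term = sprintf("T%04d", 1:5),
         n_positive = c(150, 100, 200, 120, 180),
         n_informative = 10,
         effect_size = 1.0)
}

#' Generate a synthetic screen with planted ground truth
#'
#' @param spec A [screen_spec()].
#' @return List: `profiles` (profile tibble with `gene`, `plate_id`, `tcn`
#'   and features `f001...`), `annotations` (annotation set tibble), `truth`
#'   (per-term positive genes and informative features, confounded features).
#' @export
generate_screen <- function(spec = screen_spec()) {
  set.seed(spec$seed)
  n <- spec$n_genes; p <- spec$n_features
  genes <- sprintf("g%04d", seq_len(n))
  feats <- sprintf("f%03d", seq_len(p))
  x <- if (spec$heavy_tailed) {
    matrix(stats::rt(n * p, df = 3) * spec$noise_sd / sqrt(3), n, p)
  } else {
    matrix(rnorm(n * p, sd = spec$noise_sd), n, p)
  }
  truth <- list(terms = list(), confounded_features = character(0))
  ann <- list()
  for (i in seq_len(nrow(spec$terms))) {
    tid <- spec$terms$term[i]
    pos <- sample(genes, spec$terms$n_positive[i])
    inf <- sample(feats, spec$terms$n_informative[i])
    x[match(pos, genes), match(inf, feats)] <-
      x[match(pos, genes), match(inf, feats)] +
      spec$terms$effect_size[i] * spec$noise_sd
    truth$terms[[tid]] <- list(positives = sort(pos),
                               informative_features = sort(inf))
    ann[[i]] <- tibble(gene = pos, term = tid)
  }
  tcn <- round(rlnorm(n, spec$tcn_meanlog, spec$tcn_sdlog))
  if (spec$confound_features > 0) {
    cf <- sample(feats, spec$confound_features)
    tz <- (tcn - mean(tcn)) / sd(tcn)
    for (f in cf) {
      x[, match(f, feats)] <- spec$confound_coef * tz +
        rnorm(n, sd = 0.2 * spec$noise_sd)
    }
    truth$confounded_features <- sort(cf)
  }
  if (spec$missing_rate > 0) {
    x[runif(n * p) < spec$missing_rate] <- NA
  }
  profiles <- bind_cols(
    tibble(gene = genes,
           plate_id = sprintf("p%02d", ((seq_len(n) - 1) %/% 384) + 1),
           tcn = tcn),
    as_tibble(as.data.frame(x) |> setNames(feats)))
  annotations <- if (length(ann) > 0) {
    annotation_set(bind_rows(ann)$gene, bind_rows(ann)$term,
                   release_tag = "synthetic")
  } else {
    annotation_set(character(0), character(0), release_tag = "synthetic")
  }
  list(profiles = profiles, annotations = annotations, truth = truth)
}

#' Generate a synthetic single-cell table
#'
#' Emulates a per-cell feature table from an imaging screen: control wells
#' draw from a reference distribution per feature; perturbed wells may shift
#' the location, inflate the spread, or draw from a bimodal mixture. State
#' labels (mitotic/apoptotic/infected) are Bernoulli per cell.
#'
#' @param wells Tibble with columns `well_id`, `gene`, optional `plate_id`,
#'   and optionally `shift`, `spread`, `bimodal` (per-well effect knobs;
#'   missing columns default to no effect).
#' @param n_features Number of raw features (default 3).
#' @param cells_per_well Mean of the Poisson cell count per well (default
#'   200; at least 1 cell is drawn).
#' @param state_rates Named Bernoulli rates for state labels.
#' @param seed Integer seed.
#' @return Single-cell tibble (`cell_id`, `well_id`, `gene`, `plate_id`,
#'   `state_*` logicals, features `f1..`).
#' @export
generate_single_cell <- function(wells, n_features = 3,
                                 cells_per_well = 200,
                                 state_rates = c(mitotic = 0.03,
                                                 apoptotic = 0.02,
                                                 infected = 0.10),
                                 seed = 1L) {
  set.seed(seed)
  wells <- as_tibble(wells)
  stopifnot(nrow(wells) >= 1)
  for (col in c("shift", "spread", "bimodal")) {
    if (!col %in% names(wells)) {
      wells[[col]] <- if (col == "spread") 1 else 0
    }
  }
  if (!"plate_id" %in% names(wells)) wells$plate_id <- "p01"
  out <- list()
  for (i in seq_len(nrow(wells))) {
    nc <- max(1L, stats::rpois(1, cells_per_well))
    if (cells_per_well <= 0) abort("generate_single_cell: cells_per_well must be positive")
    x <- matrix(rnorm(nc * n_features), nc, n_features)
    x <- x * wells$spread[i] + wells$shift[i]
    if (wells$bimodal[i] > 0) {
      comp <- runif(nc) < 0.5
      x[comp, ] <- x[comp, ] + wells$bimodal[i]
    }
    states <- lapply(state_rates, function(r) runif(nc) < r)
    names(states) <- paste0("state_", names(state_rates))
    out[[i]] <- bind_cols(
      tibble(cell_id = sprintf("%s_c%04d", wells$well_id[i], seq_len(nc)),
             well_id = wells$well_id[i], gene = wells$gene[i],
             plate_id = wells$plate_id[i]),
      as_tibble(states),
      as_tibble(as.data.frame(x) |> setNames(paste0("f", seq_len(n_features)))))
  }
  bind_rows(out)
}

#' Generate a siRNA seed map with a planted off-target seed
#'
#' Background seeds are drawn near-uniformly from a small alphabet of 6-mers
#' (`n_seeds` of them, `sirnas_per_gene` per gene); the planted seed is
#' assigned to the given carrier genes.
#'
#' @param genes Gene identifiers.
#' @param n_seeds Size of the background seed alphabet (default 200).
#' @param carriers Genes that share the planted seed.
#' @param planted_seed The planted 6-mer (RNA alphabet).
#' @param sirnas_per_gene Pool size per gene (4).
#' @param seed Integer seed.
#' @return List: `seeds` tibble (`gene`, `seed`), `truth` (planted seed and
#'   carriers).
#' @export
generate_seed_map <- function(genes, n_seeds = 200, carriers = character(0),
                              planted_seed = "ACGUAC", sirnas_per_gene = 4,
                              seed = 1L) {
  stopifnot(all(carriers %in% genes))
  set.seed(seed)
  alphabet <- unique(replicate(n_seeds * 2, paste(
    sample(c("A", "C", "G", "U"), 6, replace = TRUE), collapse = "")))
  alphabet <- setdiff(alphabet, planted_seed)[seq_len(n_seeds)]
  tab <- tibble(
    gene = rep(genes, each = sirnas_per_gene),
    seed = sample(alphabet, length(genes) * sirnas_per_gene, replace = TRUE))
  if (length(carriers) > 0) {
    # replace one pool member of each carrier with the planted seed
    first_row <- match(carriers, tab$gene)
    tab$seed[first_row] <- planted_seed
  }
  list(seeds = tab,
       truth = list(planted_seed = planted_seed, carriers = sort(carriers)))
}

#' Generate a modular interaction network (stochastic block model)
#'
#' @param genes Gene identifiers.
#' @param modules Named list of gene modules (e.g. term positive sets).
#' @param p_within Edge probability within a module.
#' @param p_background Edge probability elsewhere.
#' @param seed Integer seed.
#' @return An undirected igraph with no self-loops, `source = "synthetic"`.
#' @export
generate_ppi <- function(genes, modules = list(), p_within = 0.2,
                         p_background = 0.005, seed = 1L) {
  stopifnot(p_within >= 0, p_within <= 1, p_background >= 0,
            p_background <= 1)
  set.seed(seed)
  n <- length(genes)
  module_id <- rep(0L, n)
  names(module_id) <- genes
  for (mi in seq_along(modules)) {
    module_id[intersect(modules[[mi]], genes)] <- mi
  }
  edges <- list()
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    same <- module_id[i] != 0L & module_id[js] == module_id[i]
    pr <- ifelse(same, p_within, p_background)
    hit <- runif(length(js)) < pr
    if (any(hit)) {
      edges[[length(edges) + 1L]] <- tibble(gene_a = genes[i],
                                            gene_b = genes[js[hit]])
    }
  }
  etab <- if (length(edges)) bind_rows(edges) else
    tibble(gene_a = character(0), gene_b = character(0))
  g <- igraph::graph_from_data_frame(etab, directed = FALSE,
                                     vertices = data.frame(name = genes))
  igraph::E(g)$source <- "synthetic"
  g
}
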