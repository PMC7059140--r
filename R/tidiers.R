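#' Tidy a term classifier
#'
#' One row per selected feature, in acceptance order, with the cross-validated
#' F-score after each acceptance.
#'
#' @param x A `kcml_classifier`.
#' @param ... Unused.
#' @return Tibble (`term`, `step`, `feature`, `cv_fscore`).
#' @export
tidy.kcml_classifier <- function(x, ...) {
  mutate(x$trace, term = x$term, step = row_number(),
         .before = 1)[, c("term", "step", "feature", "cv_fscore")]
}

#' @rdname tidy.kcml_classifier
#' @return `glance()` returns a one-row tibble of the held-out metrics and
#'   the classifiability flag.
#' @export
glance.kcml_classifier <- function(x, ...) {
  m <- x$metrics
  tibble(term = x$term, n_features = length(x$features), sigma = x$sigma,
         precision = m$precision, recall = m$recall, fscore = m$fscore,
         false_positive_rate = m$false_positive_rate,
         train_recall = m$train_recall, test_recall = m$test_recall,
         auroc = m$auroc, classifiable = x$classifiable, seed = x$seed)
}

#' Tidy all classifiers of a fit
#'
#' @param x A `kcml_fit`.
#' @param ... Unused.
#' @return `tidy()` row-binds [tidy.kcml_classifier()] over terms;
#'   `glance()` row-binds [glance.kcml_classifier()].
#' @export
tidy.kcml_fit <- function(x, ...) {
  bind_rows(lapply(unclass(x), tidy))
}

#' @rdname tidy.kcml_fit
#' @export
glance.kcml_fit <- function(x, ...) {
  bind_rows(lapply(unclass(x), glance))
}

#' @export
tidy.kcml_term_network <- function(x, ...) x$edges
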