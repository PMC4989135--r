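#' Fitness weights for accuracy vs subset size
#'
#' The fitness of a subset X is `w1 * A(X) + w2 * (n - D(X)) / n`, where
#' `A` is cross-validated accuracy in \[0, 1\], `D` the number of selected
#' genes and `n` the total gene count. `w2 = 1 - w1` is enforced, and `w1`
#' should dominate so accuracy outranks parsimony.
#'
#' @param w1 weight on classification accuracy, in \[0, 1\]. Default 0.8
#'   (hence `w2 = 0.2`).
#' @return An object of class `fitness_weights` with fields `w1` and `w2`.
#' @export
fitness_weights <- function(w1 = 0.8) {
  if (!is.numeric(w1) || length(w1) != 1L || w1 < 0 || w1 > 1)
    stop("w1 must be a single number in [0, 1]")
  structure(list(w1 = w1, w2 = 1 - w1), class = "fitness_weights")
}

# classifier backends: fit on (xtr, ytr), predict labels for xte.
# xtr/xte are standardized numeric matrices; ytr a factor (training levels).
classify <- function(classifier, xtr, ytr, xte) {
  ytr <- droplevels(ytr)
  if (nlevels(ytr) == 1L)
    return(rep(levels(ytr), nrow(xte)))
  switch(classifier,
    svm = {
      m <- e1071::svm(xtr, ytr, kernel = "linear", scale = FALSE,
                      fitted = FALSE)
      as.character(stats::predict(m, xte))
    },
    knn = {
      if (!requireNamespace("class", quietly = TRUE))
        stop("the 'class' package is required for classifier = 'knn'")
      k <- min(3L, nrow(xtr))
      as.character(class::knn(xtr, xte, ytr, k = k))
    },
    centroid = {
      cents <- vapply(levels(ytr),
                      function(l) colMeans(xtr[ytr == l, , drop = FALSE]),
                      numeric(ncol(xtr)))
      cents <- matrix(cents, ncol = nlevels(ytr),
                      dimnames = list(NULL, levels(ytr)))
      d2 <- outer(rowSums(xte^2), rep(1, ncol(cents))) -
        2 * xte %*% cents + outer(rep(1, nrow(xte)), colSums(cents^2))
      colnames(cents)[max.col(-d2, ties.method = "first")]
    },
    stop("unknown classifier: ", classifier)
  )
}

# cross-validated accuracy over the given fold assignment.
# standardization (center/scale) is fit on each training fold only and
# applied to the held-out samples, so no information leaks across folds.
cv_accuracy_folds <- function(x, y, fold_id, classifier) {
  correct <- 0L
  for (f in unique(fold_id)) {
    te <- fold_id == f
    xtr <- x[!te, , drop = FALSE]
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
    xte <- sweep(sweep(x[te, , drop = FALSE], 2, mu), 2, sdv, "/")
    pred <- classify(classifier, xtr, y[!te], xte)
    correct <- correct + sum(pred == as.character(y[te]))
  }
  correct / length(y)
}

# stratified k-fold assignment: within each class, samples are shuffled and
# dealt round-robin, so fold class proportions match the data.
stratified_folds <- function(labels, folds) {
  fold_id <- integer(length(labels))
  for (l in levels(labels)) {
    idx <- which(labels == l)
    idx <- sample_vec(idx, length(idx))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' Leave-one-out cross-validated accuracy of a gene subset
#'
#' Each sample is held out once; the classifier is trained on the remaining
#' samples restricted to the subset's columns (standardized on the training
#' fold only) and predicts the held-out sample.
#'
#' @param dataset a [gene_dataset()].
#' @param subset 1-based gene positions (non-empty, within `1..n`).
#' @param classifier `"svm"` (linear kernel, the default), `"knn"` or
#'   `"centroid"`.
#' @return Fraction of samples predicted correctly, in \[0, 1\].
#' @export
loocv_accuracy <- function(dataset, subset, classifier = "svm") {
  stopifnot(inherits(dataset, "gene_dataset"))
  subset <- as.integer(subset)
  if (length(subset) == 0L) stop("subset must be non-empty")
  if (any(subset < 1L | subset > dataset$n))
    stop("subset positions out of range 1..", dataset$n)
  x <- dataset$matrix[, subset, drop = FALSE]
  cv_accuracy_folds(x, dataset$labels, seq_len(nrow(x)), classifier)
}

#' Build a memoizing subset evaluator
#'
#' Maps a gene subset to cross-validated accuracy, caching results per exact
#' bit pattern: identical subsets are never re-evaluated within a run. The
#' k-fold assignment is drawn once at construction (from the current RNG
#' state), so a subset's accuracy is a constant for the evaluator's lifetime.
#'
#' @param dataset a [gene_dataset()].
#' @param classifier `"svm"`, `"knn"` or `"centroid"`.
#' @param cv `"loocv"` (each sample held out once; the reference scheme) or
#'   `"kfold"` (stratified, faster; for the search's inner loop).
#' @param folds number of folds for `cv = "kfold"`.
#' @return An environment of class `subset_evaluator` with fields
#'   `accuracy(subset)`, `n_genes`, `n_evals` (distinct subsets evaluated,
#'   i.e. classifier-fit passes) and `n_hits` (cache hits).
#' @export
make_evaluator <- function(dataset, classifier = c("svm", "knn", "centroid"),
                           cv = c("loocv", "kfold"), folds = 5L) {
  stopifnot(inherits(dataset, "gene_dataset"))
  classifier <- match.arg(classifier)
  cv <- match.arg(cv)
  n_samples <- nrow(dataset$matrix)
  if (cv == "kfold" && folds > n_samples)
    stop("more folds than samples; use cv = 'loocv' or fewer folds")
  fold_id <- if (cv == "loocv") seq_len(n_samples)
             else stratified_folds(dataset$labels, folds)
  ev <- new.env(parent = emptyenv())
  ev$n_genes <- dataset$n
  ev$classifier <- classifier
  ev$cv <- cv
  ev$n_evals <- 0L
  ev$n_hits <- 0L
  ev$cache <- new.env(parent = emptyenv())
  ev$accuracy <- function(subset) {
    key <- paste(subset, collapse = ",")
    hit <- ev$cache[[key]]
    if (!is.null(hit)) {
      ev$n_hits <- ev$n_hits + 1L
      return(hit)
    }
    a <- cv_accuracy_folds(dataset$matrix[, subset, drop = FALSE],
                           dataset$labels, fold_id, classifier)
    ev$cache[[key]] <- a
    ev$n_evals <- ev$n_evals + 1L
    a
  }
  class(ev) <- "subset_evaluator"
  ev
}

#' Build an evaluator from a bare accuracy function
#'
#' Advanced/testing hook: wraps an arbitrary function from subset positions
#' to an accuracy in \[0, 1\] in the evaluator interface (with the same
#' memoization), e.g. to run the search on a known fitness landscape.
#'
#' @param accuracy_fn function(subset positions) -> accuracy in \[0, 1\].
#' @param n_genes total gene count the landscape is defined over.
#' @return A `subset_evaluator`.
#' @export
evaluator_from_function <- function(accuracy_fn, n_genes) {
  ev <- new.env(parent = emptyenv())
  ev$n_genes <- as.integer(n_genes)
  ev$classifier <- "custom"
  ev$cv <- "none"
  ev$n_evals <- 0L
  ev$n_hits <- 0L
  ev$cache <- new.env(parent = emptyenv())
  ev$accuracy <- function(subset) {
    key <- paste(subset, collapse = ",")
    hit <- ev$cache[[key]]
    if (!is.null(hit)) {
      ev$n_hits <- ev$n_hits + 1L
      return(hit)
    }
    a <- accuracy_fn(subset)
    ev$cache[[key]] <- a
    ev$n_evals <- ev$n_evals + 1L
    a
  }
  class(ev) <- "subset_evaluator"
  ev
}

#' @export
print.subset_evaluator <- function(x, ...) {
  cat(sprintf("<subset_evaluator> %s / %s; %d evaluations, %d cache hits\n",
              x$classifier, x$cv, x$n_evals, x$n_hits))
  invisible(x)
}

#' Evaluate a country (accuracy + fitness), using the cache
#'
#' @param country a `country` with at least one selected gene.
#' @param evaluator a [make_evaluator()] object.
#' @param weights a [fitness_weights()] object.
#' @return The country with `accuracy` and `fitness` set.
#' @export
evaluate_country <- function(country, evaluator, weights) {
  if (country$n_selected < 1L)
    stop("country has no selected genes; repair before evaluating")
  a <- evaluator$accuracy(selected_indices(country))
  n <- evaluator$n_genes
  country$accuracy <- a
  country$fitness <- weights$w1 * a +
    weights$w2 * (n - country$n_selected) / n
  country
}

#' Fitness of a gene subset
#'
#' Convenience wrapper returning the scalar fitness
#' `w1 * A + w2 * (n - D) / n` of a country.
#'
#' @inheritParams evaluate_country
#' @return The fitness value.
#' @export
subset_fitness <- function(country, evaluator, weights) {
  evaluate_country(country, evaluator, weights)$fitness
}

#' Evaluate a list of countries
#'
#' Countries whose fitness is already set are left untouched; the rest are
#' evaluated through the cache, so duplicated bit patterns cost one
#' classifier-fit pass in total.
#'
#' @param countries list of `country` objects.
#' @inheritParams evaluate_country
#' @return The same list with `fitness` and `accuracy` set on every country.
#' @export
evaluate_population <- function(countries, evaluator, weights) {
  lapply(countries, function(co) {
    if (is.na(co$fitness)) evaluate_country(co, evaluator, weights) else co
  })
}
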