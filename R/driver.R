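#' Configuration for a HICATS run
#'
#' Defaults follow the published parameter setting of the algorithm: 15
#' countries, 4 imperialists (hence 11 colonies), 50 generations, accuracy
#' weight `w1 = 0.8` (so the parsimony weight is 0.2). The remaining knobs —
#' initial density, tabu-search budget, competition damping — are search
#' parameters the method leaves open; their defaults are discussed in the
#' methods vignette.
#'
#' @param n_pop population size (countries).
#' @param n_imp number of imperialists; `n_pop - n_imp` colonies.
#' @param generations number of outer iterations.
#' @param w1 fitness weight on accuracy (`w2 = 1 - w1`).
#' @param init_density initial probability that a gene is selected.
#' @param ts_iters tabu-search steps per imperialist per generation.
#' @param ts_neighbors flip-neighborhood sample size per tabu step.
#' @param ts_tenure tabu tenure (iterations a flipped position is forbidden).
#' @param xi colony damping weight in the empire total power.
#' @param classifier `"svm"`, `"knn"` or `"centroid"`.
#' @param cv `"loocv"` or `"kfold"` (stratified; faster).
#' @param folds fold count when `cv = "kfold"`.
#' @param seed integer seed for the whole run, or NULL to leave the RNG
#'   stream untouched.
#' @param tabu logical; FALSE disables the tabu refinement of imperialists,
#'   giving the plain binary-ICA baseline used for ablation.
#' @return An object of class `hicats_config`.
#' @export
hicats_config <- function(n_pop = 15L, n_imp = 4L, generations = 50L,
                          w1 = 0.8, init_density = 0.1, ts_iters = 5L,
                          ts_neighbors = 20L, ts_tenure = 7L, xi = 0.1,
                          classifier = "svm", cv = "loocv", folds = 5L,
                          seed = NULL, tabu = TRUE) {
  if (n_pop < 2L) stop("n_pop must be at least 2")
  if (n_imp < 1L || n_imp >= n_pop) stop("need n_pop > n_imp >= 1")
  if (generations < 0L) stop("generations must be non-negative")
  if (init_density <= 0 || init_density > 1)
    stop("init_density must lie in (0, 1]")
  if (xi < 0 || xi > 1) stop("xi must lie in [0, 1]")
  weights <- fitness_weights(w1)
  structure(
    list(n_pop = as.integer(n_pop), n_imp = as.integer(n_imp),
         generations = as.integer(generations),
         w1 = weights$w1, w2 = weights$w2,
         init_density = init_density,
         ts_iters = as.integer(ts_iters),
         ts_neighbors = as.integer(ts_neighbors),
         ts_tenure = as.integer(ts_tenure),
         xi = xi, classifier = classifier, cv = cv, folds = as.integer(folds),
         seed = seed, tabu = isTRUE(tabu)),
    class = "hicats_config"
  )
}

#' @export
print.hicats_config <- function(x, ...) {
  cat("<hicats_config>\n")
  for (nm in names(unclass(x)))
    cat(sprintf("  %-12s %s\n", nm, paste(format(x[[nm]]), collapse = ",")))
  invisible(x)
}

#' Run HICATS gene subset selection
#'
#' The full hybrid search: a random population of bit-vector countries is
#' evaluated and partitioned into empires; each generation the imperialists
#' are refined by tabu search, every colony is assimilated toward its
#' imperialist, colonies that overtake their imperialist are promoted,
#' empires compete for colonies, and colony-less empires are dissolved. An
#' elitist archive tracks the best country ever evaluated, independent of the
#' final population, and a per-generation convergence log is kept.
#'
#' @param dataset a [gene_dataset()].
#' @param config a [hicats_config()].
#' @return An object of class `hicats_result` with fields `best_country`,
#'   `best_fitness`, `best_accuracy`, `best_n_selected`,
#'   `selected_gene_names`, `log` (data.frame with one row per generation,
#'   initialization included) and `config`.
#' @export
run_hicats <- function(dataset, config = hicats_config()) {
  stopifnot(inherits(dataset, "gene_dataset"),
            inherits(config, "hicats_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  evaluator <- make_evaluator(dataset, classifier = config$classifier,
                              cv = config$cv, folds = config$folds)
  weights <- fitness_weights(config$w1)

  population <- replicate(config$n_pop,
                          random_country(dataset$n, config$init_density),
                          simplify = FALSE)
  population <- evaluate_population(population, evaluator, weights)
  empires <- initialize_empires(population, config$n_imp)

  best <- archive_best(empire_countries(empires), NULL)
  log <- vector("list", config$generations + 1L)
  log[[1L]] <- log_record(0L, best, empires, evaluator)

  for (gen in seq_len(config$generations)) {
    if (config$tabu) {
      for (m in seq_along(empires)) {
        empires[[m]]$imperialist <- tabu_search(
          empires[[m]]$imperialist, evaluator, weights,
          iters = config$ts_iters, k = config$ts_neighbors,
          tenure = config$ts_tenure
        )
      }
    }
    for (m in seq_along(empires)) {
      imp <- empires[[m]]$imperialist
      empires[[m]]$colonies <- lapply(empires[[m]]$colonies, function(co) {
        evaluate_country(assimilate(imp, co), evaluator, weights)
      })
    }
    empires <- lapply(empires, swap_best_colony)
    if (length(empires) >= 2L)
      empires <- imperialist_competition(empires, config$xi)
    empires <- eliminate_empty(empires, config$xi)

    countries <- empire_countries(empires)
    stopifnot(length(countries) == config$n_pop)
    best <- archive_best(countries, best)
    log[[gen + 1L]] <- log_record(gen, best, empires, evaluator)
  }

  log <- do.call(rbind, log)
  structure(
    list(best_country = best,
         best_fitness = best$fitness,
         best_accuracy = best$accuracy,
         best_n_selected = best$n_selected,
         selected_gene_names = dataset$gene_names[selected_indices(best)],
         log = log,
         config = config),
    class = "hicats_result"
  )
}

#' Plain binary-ICA baseline (tabu search disabled)
#'
#' Identical to [run_hicats()] except the tabu refinement of imperialists is
#' skipped — the ablation counterpart used to measure what the local search
#' contributes.
#'
#' @inheritParams run_hicats
#' @return A `hicats_result`.
#' @export
run_ica_baseline <- function(dataset, config = hicats_config()) {
  config$tabu <- FALSE
  run_hicats(dataset, config)
}

archive_best <- function(countries, best) {
  fits <- vapply(countries, function(co) co$fitness, numeric(1))
  i <- which.max(fits)
  if (is.null(best) || fits[i] > best$fitness) countries[[i]] else best
}

log_record <- function(generation, best, empires, evaluator) {
  countries <- empire_countries(empires)
  fits <- vapply(countries, function(co) co$fitness, numeric(1))
  data.frame(
    generation = generation,
    best_fitness = best$fitness,
    best_accuracy = best$accuracy,
    best_n_selected = best$n_selected,
    mean_fitness = mean(fits),
    n_empires = length(empires),
    evaluations = evaluator$n_evals
  )
}

#' @export
print.hicats_result <- function(x, ...) {
  cat("<hicats_result>\n")
  cat(sprintf("  best accuracy : %.2f%%\n", 100 * x$best_accuracy))
  cat(sprintf("  best fitness  : %.4f\n", x$best_fitness))
  cat(sprintf("  genes selected: %d (%s)\n", x$best_n_selected,
              paste(x$selected_gene_names, collapse = ", ")))
  cat(sprintf("  generations   : %d, evaluations: %d\n",
              max(x$log$generation), x$log$evaluations[nrow(x$log)]))
  invisible(x)
}
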