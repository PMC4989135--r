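#' Construct an empire
#'
#' @param imperialist the empire's leading `country`.
#' @param colonies list of colony `country` objects (possibly empty).
#' @return An object of class `empire`.
#' @export
new_empire <- function(imperialist, colonies = list()) {
  structure(list(imperialist = imperialist, colonies = colonies),
            class = "empire")
}

#' @export
print.empire <- function(x, ...) {
  cat(sprintf("<empire> imperialist fitness %.4f, %d colonies\n",
              x$imperialist$fitness, length(x$colonies)))
  invisible(x)
}

#' Normalize imperialist fitness values
#'
#' Shifts fitness so the weakest imperialist maps to 0:
#' `Fit_m = fit_m - min_i fit_i`.
#'
#' @param fits fitness of each imperialist.
#' @return Non-negative normalized values, same length.
#' @export
normalize_imperialist_fitness <- function(fits) {
  if (length(fits) == 0L) stop("need at least one imperialist")
  fits - min(fits)
}

#' Normalized imperialist power
#'
#' `p_m = Fit_m / sum_i Fit_i`. When every imperialist ties (all normalized
#' values 0) the ratio is 0/0; powers fall back to the uniform distribution
#' so the cold-start population can still be partitioned.
#'
#' @param normalized non-negative normalized fitness values.
#' @return Powers summing to 1.
#' @export
imperialist_powers <- function(normalized) {
  if (any(normalized < 0)) stop("normalized fitness must be non-negative")
  s <- sum(normalized)
  if (s == 0) rep(1 / length(normalized), length(normalized))
  else normalized / s
}

#' Allocate colonies to imperialists proportionally to power
#'
#' Initial counts are `round(p_m * n_col)`. Rounding can break the total;
#' excess is shed from (and deficit added to) the entries with the largest
#' fractional remainder of `p_m * n_col`. Finally, when there are at least as
#' many colonies as empires, every empire is guaranteed one colony by moving
#' colonies from the richest empire — a powerless imperialist would otherwise
#' be eliminated before the search starts.
#'
#' @param powers per-imperialist powers summing to 1.
#' @param n_col total number of colonies to distribute.
#' @return Integer counts summing to `n_col`.
#' @export
allocate_colonies <- function(powers, n_col) {
  if (n_col < 0) stop("n_col must be non-negative")
  if (abs(sum(powers) - 1) > 1e-8) stop("powers must sum to 1")
  target <- powers * n_col
  counts <- as.integer(round(target))
  rem <- target - floor(target)
  while (sum(counts) > n_col) {
    cand <- which(counts > 0L)
    i <- cand[which.max(rem[cand])]
    counts[i] <- counts[i] - 1L
    rem[i] <- rem[i] - 1
  }
  while (sum(counts) < n_col) {
    i <- which.max(rem)
    counts[i] <- counts[i] + 1L
    rem[i] <- rem[i] - 1
  }
  if (n_col >= length(powers)) {
    while (any(counts == 0L)) {
      empty <- which(counts == 0L)[1L]
      rich <- which.max(counts)
      counts[rich] <- counts[rich] - 1L
      counts[empty] <- counts[empty] + 1L
    }
  }
  counts
}

#' Form the initial empires from an evaluated population
#'
#' The `n_imp` highest-fitness countries become imperialists (ties broken by
#' position in the population); the remaining countries are shuffled and
#' dealt to empires according to [allocate_colonies()] on the imperialists'
#' normalized powers.
#'
#' @param population list of evaluated `country` objects.
#' @param n_imp number of imperialists (`1 <= n_imp < length(population)`).
#' @return List of `empire` objects; total country count is conserved.
#' @export
initialize_empires <- function(population, n_imp) {
  n_pop <- length(population)
  if (n_imp < 1L || n_imp >= n_pop)
    stop("need population size > n_imp >= 1")
  fits <- vapply(population, function(co) co$fitness, numeric(1))
  if (anyNA(fits)) stop("population must be evaluated first")
  ord <- order(-fits, seq_len(n_pop))
  imp_idx <- ord[seq_len(n_imp)]
  col_idx <- ord[(n_imp + 1L):n_pop]
  powers <- imperialist_powers(normalize_imperialist_fitness(fits[imp_idx]))
  counts <- allocate_colonies(powers, length(col_idx))
  col_idx <- sample_vec(col_idx, length(col_idx))
  empires <- vector("list", n_imp)
  offset <- 0L
  for (m in seq_len(n_imp)) {
    take <- if (counts[m] > 0L) col_idx[offset + seq_len(counts[m])] else integer(0)
    offset <- offset + counts[m]
    empires[[m]] <- new_empire(population[[imp_idx[m]]], population[take])
  }
  empires
}
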