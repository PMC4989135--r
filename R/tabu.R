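#' Flip one bit of a country
#'
#' The elementary tabu-search move: the output differs from the input at
#' exactly `position` (its own inverse when applied twice). Cached fitness is
#' cleared. Note the result may select zero genes; [sample_neighborhood()]
#' repairs such neighbors.
#'
#' @param country a `country`.
#' @param position 1-based gene index to flip.
#' @return The flipped `country`, fitness unset.
#' @export
flip_neighbor <- function(country, position) {
  n <- length(country$bits)
  if (position < 1L || position > n)
    stop("position out of range 1..", n)
  bits <- country$bits
  bits[position] <- 1L - bits[position]
  new_country(bits)
}

#' Sample a bit-flip neighborhood
#'
#' Draws `k` distinct positions uniformly without replacement (all positions
#' when `k >= n`) and pairs each with its flipped neighbor. Full
#' neighborhoods are infeasible at microarray dimension with cross-validated
#' fitness, hence the subsample. Neighbors emptied by the flip are repaired.
#'
#' @param country a `country`.
#' @param k neighborhood size (>= 1).
#' @return List of `list(position =, country =)` pairs.
#' @export
sample_neighborhood <- function(country, k) {
  if (k < 1L) stop("k must be >= 1")
  n <- length(country$bits)
  positions <- if (k >= n) seq_len(n) else sample_vec(seq_len(n), k)
  lapply(positions, function(p)
    list(position = p, country = repair_country(flip_neighbor(country, p))))
}

#' Create an empty tabu list
#'
#' Recency memory over move attributes: the attribute of a move is the
#' flipped bit position, and a position is tabu while its recorded expiry
#' iteration exceeds the current iteration.
#'
#' @param tenure number of iterations a move stays tabu.
#' @param n_genes number of positions.
#' @return An object of class `tabu_list`.
#' @export
new_tabu_list <- function(tenure, n_genes) {
  structure(list(tenure = as.integer(tenure),
                 expiry = integer(n_genes)),
            class = "tabu_list")
}

is_tabu <- function(tlist, position, iteration) {
  tlist$expiry[position] > iteration
}

mark_tabu <- function(tlist, position, iteration) {
  tlist$expiry[position] <- iteration + tlist$tenure
  tlist
}

#' One tabu-search step
#'
#' Samples `k` flip neighbors of `current` and evaluates them. A neighbor is
#' admissible if its position is not tabu, or — the aspiration criterion — if
#' its fitness exceeds the best fitness seen so far in the search. The
#' highest-fitness admissible neighbor becomes the next solution even when it
#' is worse than the current one, which is what lets the search leave local
#' optima; its position becomes tabu for `tenure` iterations. Exact fitness
#' ties (common once accuracy saturates, when removing any redundant gene
#' gains the same parsimony reward) are broken uniformly at random — a
#' positional tie-break would systematically prune low-index genes first and
#' bias which of several equivalent subsets the search settles on. If no
#' neighbor is admissible the step is a no-op.
#'
#' @param current evaluated `country`.
#' @param best_so_far_fitness best fitness seen so far (aspiration level).
#' @param tlist a [new_tabu_list()].
#' @param iteration current iteration number.
#' @param evaluator,weights see [evaluate_country()].
#' @param k neighborhood sample size.
#' @return `list(country =, flipped = position or NULL, tlist =)`.
#' @export
tabu_step <- function(current, best_so_far_fitness, tlist, iteration,
                      evaluator, weights, k) {
  nb <- sample_neighborhood(current, k)
  cands <- vector("list", length(nb))
  fits <- rep(-Inf, length(nb))
  for (i in seq_along(nb)) {
    cand <- evaluate_country(nb[[i]]$country, evaluator, weights)
    cands[[i]] <- cand
    if (!is_tabu(tlist, nb[[i]]$position, iteration) ||
        cand$fitness > best_so_far_fitness)
      fits[i] <- cand$fitness
  }
  if (all(fits == -Inf))
    return(list(country = current, flipped = NULL, tlist = tlist))
  tied <- which(fits == max(fits))
  pick <- if (length(tied) == 1L) tied else sample_vec(tied, 1L)
  best_pos <- nb[[pick]]$position
  list(country = cands[[pick]], flipped = best_pos,
       tlist = mark_tabu(tlist, best_pos, iteration))
}

#' Tabu-search refinement of an imperialist
#'
#' Runs `iters` tabu steps from the imperialist and returns the best country
#' visited, the start included, so the returned fitness never falls below the
#' input's.
#'
#' @param imperialist evaluated `country` to refine.
#' @param evaluator,weights see [evaluate_country()].
#' @param iters number of tabu steps.
#' @param k neighborhood sample size per step.
#' @param tenure tabu tenure (iterations a flipped position stays forbidden).
#' @return The best `country` visited.
#' @export
tabu_search <- function(imperialist, evaluator, weights, iters = 5L,
                        k = 20L, tenure = 7L) {
  if (is.na(imperialist$fitness))
    stop("imperialist must be evaluated before tabu search")
  tlist <- new_tabu_list(tenure, length(imperialist$bits))
  current <- imperialist
  best <- imperialist
  for (it in seq_len(iters)) {
    st <- tabu_step(current, best$fitness, tlist, it, evaluator, weights, k)
    current <- st$country
    tlist <- st$tlist
    if (current$fitness > best$fitness) best <- current
  }
  best
}
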