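#' Promote a colony that outgrew its imperialist
#'
#' If any colony's fitness strictly exceeds the imperialist's, the strongest
#' such colony (ties: lowest index) swaps roles with the imperialist, so the
#' imperialist is always the empire's best country.
#'
#' @param empire an evaluated `empire`.
#' @return The (possibly) updated `empire`.
#' @export
swap_best_colony <- function(empire) {
  if (length(empire$colonies) == 0L) return(empire)
  fits <- vapply(empire$colonies, function(co) co$fitness, numeric(1))
  i <- which.max(fits)
  if (fits[i] > empire$imperialist$fitness) {
    old_imp <- empire$imperialist
    empire$imperialist <- empire$colonies[[i]]
    empire$colonies[[i]] <- old_imp
  }
  empire
}

#' Total power of an empire
#'
#' Imperialist fitness plus `xi` times the mean colony fitness (the classical
#' damped-colony form); with no colonies, the imperialist fitness alone.
#'
#' @param empire an evaluated `empire`.
#' @param xi colony damping weight in \[0, 1\].
#' @return The total power.
#' @export
empire_total_power <- function(empire, xi) {
  p <- empire$imperialist$fitness
  if (length(empire$colonies) > 0L) {
    fits <- vapply(empire$colonies, function(co) co$fitness, numeric(1))
    p <- p + xi * mean(fits)
  }
  p
}

#' One round of imperialist competition
#'
#' The weakest empire (lowest total power) loses its weakest colony to a
#' winner drawn by roulette over min-shifted total powers (`power - min
#' power`, the loser excluded; uniform when all remaining powers tie).
#' Stronger empires thereby accumulate colonies and weak empires erode. An
#' empire that is weakest but already colony-less is left alone here — its
#' elimination is [eliminate_empty()]'s job.
#'
#' @param empires list of at least one evaluated `empire`.
#' @param xi colony damping weight for [empire_total_power()].
#' @return The updated list of empires (country count conserved).
#' @export
imperialist_competition <- function(empires, xi) {
  if (length(empires) < 1L) stop("need at least one empire")
  if (length(empires) < 2L) return(empires)
  powers <- vapply(empires, empire_total_power, numeric(1), xi = xi)
  loser <- which.min(powers)
  if (length(empires[[loser]]$colonies) == 0L) return(empires)
  cfits <- vapply(empires[[loser]]$colonies, function(co) co$fitness,
                  numeric(1))
  weakest_col <- which.min(cfits)
  colony <- empires[[loser]]$colonies[[weakest_col]]
  empires[[loser]]$colonies[[weakest_col]] <- NULL

  candidates <- setdiff(seq_along(empires), loser)
  shifted <- powers[candidates] - min(powers)
  prob <- if (sum(shifted) == 0) rep(1 / length(candidates), length(candidates))
          else shifted / sum(shifted)
  winner <- candidates[sample.int(length(candidates), 1L, prob = prob)]
  empires[[winner]]$colonies <- c(empires[[winner]]$colonies, list(colony))
  empires
}

#' Dissolve empires that lost all colonies
#'
#' Every colony-less empire is eliminated: its imperialist is demoted to a
#' colony of the highest-total-power surviving empire, so the population size
#' never changes. When a single empire remains overall no elimination occurs.
#'
#' @param empires list of evaluated `empire` objects.
#' @param xi colony damping weight for [empire_total_power()].
#' @return The updated (possibly shorter) list of empires.
#' @export
eliminate_empty <- function(empires, xi) {
  repeat {
    if (length(empires) <= 1L) return(empires)
    empty <- which(vapply(empires, function(e) length(e$colonies) == 0L,
                          logical(1)))
    if (length(empty) == 0L) return(empires)
    e <- empty[1L]
    dissolved <- empires[[e]]
    empires[[e]] <- NULL
    powers <- vapply(empires, empire_total_power, numeric(1), xi = xi)
    strongest <- which.max(powers)
    empires[[strongest]]$colonies <-
      c(empires[[strongest]]$colonies, list(dissolved$imperialist))
  }
}

# all countries across a list of empires (imperialists first per empire)
empire_countries <- function(empires) {
  unlist(lapply(empires, function(e) c(list(e$imperialist), e$colonies)),
         recursive = FALSE)
}
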