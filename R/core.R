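#' hicats: binary imperialist competition + tabu search gene selection
#'
#' Wrapper feature selection for expression matrices: candidate gene subsets
#' are bit-vector "countries" organised into empires, evolved by assimilation,
#' imperialist competition and tabu-search refinement, and scored by
#' cross-validated classification accuracy combined with a parsimony reward.
#'
#' Start with [make_synthetic()] or [read_expression_table()] to obtain a
#' `gene_dataset`, then call [run_hicats()].
#'
#' @keywords internal
"_PACKAGE"

#' Construct a country (candidate gene subset)
#'
#' A country is a fixed-length 0/1 vector over genes; a 1 at position `i`
#' means gene `i` is part of the subset. Fitness and accuracy are cached on
#' the object once evaluated.
#'
#' @param bits integer vector of 0s and 1s, one per gene.
#' @return An object of class `country` with fields `bits`, `n_selected`,
#'   `fitness` (NA until evaluated) and `accuracy` (NA until evaluated).
#' @export
new_country <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) < 1L || anyNA(bits) || any(bits != 0L & bits != 1L))
    stop("bits must be a non-empty vector of 0s and 1s")
  structure(
    list(bits = bits, n_selected = sum(bits),
         fitness = NA_real_, accuracy = NA_real_),
    class = "country"
  )
}

#' Generate a random country
#'
#' Each bit is set independently with probability `density`, then the result
#' is repaired so that at least one gene is selected (an empty subset has no
#' defined classification accuracy). Uses the global RNG stream; seed with
#' [set.seed()] for reproducibility.
#'
#' @param n_genes number of genes (length of the bit vector).
#' @param density probability in (0, 1] that a bit starts as 1. The default
#'   0.1 keeps initial subsets small, matching the small final subsets this
#'   kind of search converges to on microarray data.
#' @return A `country`.
#' @export
random_country <- function(n_genes, density = 0.1) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stop("n_genes must be a positive integer")
  if (!is.numeric(density) || length(density) != 1L ||
      density <= 0 || density > 1)
    stop("density must lie in (0, 1]")
  bits <- as.integer(stats::runif(n_genes) < density)
  repair_country(new_country(bits))
}

#' Positions of the selected genes
#'
#' @param country a `country`.
#' @return Ascending 1-based positions of the 1-bits (integer(0) if none).
#' @export
selected_indices <- function(country) {
  which(country$bits == 1L)
}

#' Repair an empty country
#'
#' If no gene is selected, one uniformly chosen bit is set to 1; otherwise the
#' country is returned unchanged. Keeps the population free of unevaluable
#' empty subsets without discarding individuals.
#'
#' @param country a `country`.
#' @return A `country` with `n_selected >= 1`.
#' @export
repair_country <- function(country) {
  if (country$n_selected >= 1L) return(country)
  i <- sample.int(length(country$bits), 1L)
  bits <- country$bits
  bits[i] <- 1L
  new_country(bits)
}

#' @export
print.country <- function(x, ...) {
  idx <- selected_indices(x)
  cat(sprintf("<country> %d/%d genes selected", x$n_selected, length(x$bits)))
  if (!is.na(x$fitness))
    cat(sprintf("; fitness %.4f, accuracy %.4f", x$fitness, x$accuracy))
  cat("\n")
  if (length(idx) <= 25L) cat("  positions:", paste(idx, collapse = ", "), "\n")
  invisible(x)
}

# sample() treats a length-1 x as 1:x; this always samples from the vector
sample_vec <- function(x, size) {
  x[sample.int(length(x), size)]
}
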