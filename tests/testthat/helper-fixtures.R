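# shared in-code fixtures: tiny datasets and stub fitness landscapes

# two well-separated classes on one informative gene (values differ by sign)
separable_one_gene_dataset <- function() {
  m <- matrix(c(-5, -4, -6, 5, 4, 6), ncol = 1)
  gene_dataset(m, labels = c("a", "a", "a", "b", "b", "b"),
               gene_names = "g1")
}

# evaluator over an explicit landscape: accuracy of a subset is looked up in
# `values` by the subset's bit pattern (base-2 code), so every landscape is
# enumerable by brute force.
landscape_evaluator <- function(n, values) {
  stopifnot(length(values) == 2^n)
  evaluator_from_function(function(subset) {
    code <- sum(2^(subset - 1L))
    values[code + 1L]
  }, n_genes = n)
}

# evaluator whose accuracy is the fraction of selected genes: a monotone
# landscape whose unique optimum is the all-ones country (with w1 = 1)
count_evaluator <- function(n) {
  evaluator_from_function(function(subset) length(subset) / n, n_genes = n)
}

# a country with the given selected positions
country_from <- function(positions, n) {
  bits <- integer(n)
  bits[positions] <- 1L
  new_country(bits)
}

# a country stub with fitness set directly (for empire/competition tests
# that need no classifier)
scored_country <- function(fitness, n = 4L) {
  co <- country_from(1L, n)
  co$fitness <- fitness
  co$accuracy <- fitness
  co
}

tiny_synthetic <- function(seed = 7L) {
  make_synthetic(n_samples = 16, n_genes = 40, n_informative = 3,
                 n_classes = 2, effect_size = 3, noise_sd = 1, seed = seed)
}
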