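test_that("bit flips are single-position involutions", {
  co <- new_country(c(1, 1, 0, 0, 1, 0, 1, 0, 0, 1))
  expect_equal(flip_neighbor(co, 3)$bits,
               as.integer(c(1, 1, 1, 0, 1, 0, 1, 0, 0, 1)))
  expect_identical(flip_neighbor(flip_neighbor(co, 7), 7)$bits, co$bits)
  expect_error(flip_neighbor(co, 11))
  for (p in 1:10)
    expect_equal(sum(flip_neighbor(co, p)$bits != co$bits), 1)
})

test_that("neighborhood sampling is exhaustive at k >= n and uniform below", {
  co <- new_country(c(1, 1, 0, 0, 1, 0, 1, 0, 0, 1))
  nb <- sample_neighborhood(co, 15)
  expect_length(nb, 10)
  expect_setequal(vapply(nb, `[[`, integer(1), "position"), 1:10)

  set.seed(12); a <- sample_neighborhood(co, 1)[[1]]$position
  set.seed(12); b <- sample_neighborhood(co, 1)[[1]]$position
  expect_equal(a, b)

  # flipping the only selected bit triggers repair to a non-empty country
  single <- country_from(3, 5)
  nb1 <- sample_neighborhood(single, 5)
  for (item in nb1) expect_gte(item$country$n_selected, 1L)

  set.seed(31)
  n <- 100; k <- 5; draws <- 2000
  counts <- integer(n)
  big <- random_country(n, 0.3)
  for (i in seq_len(draws)) {
    pos <- vapply(sample_neighborhood(big, k), `[[`, integer(1), "position")
    counts[pos] <- counts[pos] + 1L
  }
  freq <- counts / (draws * k)
  se <- sqrt(0.05 * 0.95 / (draws * k))
  # aggregate check: all position frequencies near 1/n
  expect_true(all(abs(freq - 1 / n) < 4 * se))
})

test_that("a tenure-0 full-neighborhood step equals steepest ascent", {
  set.seed(23)
  n <- 8
  w <- fitness_weights(1)
  for (rep in 1:100) {
    values <- runif(2^n)
    ev <- landscape_evaluator(n, values)
    start <- random_country(n, 0.5)
    if (start$n_selected < 2L) start <- country_from(c(1, 2), n)
    start <- evaluate_country(start, ev, w)
    st <- tabu_step(start, start$fitness, new_tabu_list(0, n), 1, ev, w, k = n)
    # brute-force oracle: best fitness over all single-bit flips
    oracle <- max(vapply(seq_len(n), function(p)
      evaluate_country(flip_neighbor(start, p), ev, w)$fitness, numeric(1)))
    expect_equal(st$country$fitness, oracle)
  }
})

test_that("aspiration admits tabu moves that beat the global best", {
  n <- 6
  w <- fitness_weights(1)
  ev <- count_evaluator(n)
  current <- evaluate_country(country_from(1:3, n), ev, w)

  # every position tabu and nothing can beat an unreachable best: no move
  tl <- new_tabu_list(100, n)
  tl$expiry[] <- 1000L
  st <- tabu_step(current, 2, tl, 1, ev, w, k = n)
  expect_identical(st$country$bits, current$bits)
  expect_null(st$flipped)

  # same tabu list, but a neighbor exceeding the best-so-far is selectable
  st2 <- tabu_step(current, current$fitness, tl, 1, ev, w, k = n)
  expect_equal(st2$country$n_selected, 4L)  # adds a gene: fitness 4/6 > 3/6
  expect_false(is.null(st2$flipped))
})

test_that("tabu search climbs monotone landscapes and never regresses", {
  n <- 8
  w <- fitness_weights(1)
  ev <- count_evaluator(n)
  start <- evaluate_country(country_from(2, n), ev, w)

  expect_identical(tabu_search(start, ev, w, iters = 0), start)

  set.seed(41)
  out <- tabu_search(start, ev, w, iters = 8, k = n, tenure = 2)
  expect_equal(out$bits, rep(1L, n))  # unique optimum of the count landscape

  # elitism: returned fitness >= input fitness on arbitrary landscapes
  set.seed(55)
  for (i in 1:200) {
    ev_i <- landscape_evaluator(6, runif(2^6))
    s <- evaluate_country(random_country(6, 0.5), ev_i, w)
    out_i <- tabu_search(s, ev_i, w, iters = 4, k = 3, tenure = 2)
    expect_gte(out_i$fitness, s$fitness)
  }
})

test_that("the tabu list blocks at most tenure positions at a time", {
  n <- 10
  tl <- new_tabu_list(3, n)
  for (it in 1:8) {
    tl <- hicats:::mark_tabu(tl, ((it - 1) %% n) + 1L, it)
    blocked <- sum(vapply(1:n, function(p) hicats:::is_tabu(tl, p, it),
                          logical(1)))
    expect_lte(blocked, min(3, n))
  }
})
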