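test_that("gene_dataset validates dimensions and labels", {
  m <- matrix(rnorm(12), nrow = 3)
  ds <- gene_dataset(m, c("a", "b", "a"))
  expect_equal(ds$n, 4)
  expect_equal(ds$gene_names, paste0("g", 1:4))
  expect_error(gene_dataset(m, c("a", "b")))
  expect_error(gene_dataset(m, c("a", "b", "a"), gene_names = c("x", "y")))
  expect_error(gene_dataset(m[1, , drop = FALSE], "a"))
})

test_that("expression tables round-trip through both orientations", {
  m <- matrix(round(rnorm(12), 4), nrow = 3,
              dimnames = list(NULL, paste0("gene", 1:4)))
  labels <- c("tumor", "normal", "tumor")

  csv <- tempfile(fileext = ".csv")
  df <- data.frame(m, check.names = FALSE)
  df$class <- labels
  write.csv(df, csv, row.names = FALSE)
  ds <- read_expression_table(csv, label_column = "class")
  expect_equal(unname(ds$matrix), unname(m))
  expect_equal(as.character(ds$labels), labels)
  expect_equal(ds$gene_names, paste0("gene", 1:4))

  # genes-in-rows layout with a separate label file gives the same dataset
  tsv <- tempfile(fileext = ".tsv")
  tm <- t(m)
  write.table(data.frame(gene = rownames(tm), tm, check.names = FALSE),
              tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  lab <- tempfile(fileext = ".txt")
  writeLines(labels, lab)
  ds2 <- read_expression_table(tsv, orientation = "genes", label_file = lab)
  expect_equal(unname(ds2$matrix), unname(m))
  expect_equal(ds2$gene_names, ds$gene_names)
  expect_equal(as.character(ds2$labels), labels)

  short <- tempfile(fileext = ".txt")
  writeLines(labels[1:2], short)
  expect_error(read_expression_table(tsv, orientation = "genes",
                                     label_file = short), "mismatch")
})

test_that("the synthetic generator plants what it promises", {
  syn <- make_synthetic(40, 200, 5, 3, effect_size = 3, noise_sd = 1, seed = 1)
  ds <- syn$dataset
  expect_equal(dim(ds$matrix), c(40, 200))
  expect_equal(as.integer(table(ds$labels)), c(14, 13, 13))
  expect_length(syn$planted, 5)
  expect_false(is.unsorted(syn$planted, strictly = TRUE))
  expect_true(all(syn$planted >= 1 & syn$planted <= 200))

  # pure function of its spec: same seed, identical data
  syn2 <- make_synthetic(40, 200, 5, 3, effect_size = 3, noise_sd = 1, seed = 1)
  expect_identical(syn$dataset$matrix, syn2$dataset$matrix)
  expect_identical(syn$planted, syn2$planted)

  # with no effect, informative columns are indistinguishable from noise
  syn0 <- make_synthetic(60, 50, 5, 2, effect_size = 0, seed = 3)
  cm <- colMeans(syn0$dataset$matrix[, syn0$planted, drop = FALSE])
  expect_true(all(abs(cm) < 4 / sqrt(60)))

  expect_error(make_synthetic(10, 5, 6))
  expect_error(make_synthetic(2, 10, 1, n_classes = 3))
})

test_that("planted genes out-classify random subsets of the same size", {
  syn <- make_synthetic(40, 200, 5, 3, effect_size = 3, noise_sd = 1, seed = 2)
  a_planted <- loocv_accuracy(syn$dataset, syn$planted, classifier = "centroid")
  set.seed(10)
  a_random <- replicate(200, {
    loocv_accuracy(syn$dataset, sample(200, 5), classifier = "centroid")
  })
  expect_gt(a_planted, quantile(a_random, 0.95))
})

test_that("labels without planted signal score near chance", {
  syn <- make_synthetic(30, 40, 0, 2, seed = 6)
  accs <- replicate(20, {
    loocv_accuracy(syn$dataset, sample(40, 3), classifier = "centroid")
  })
  expect_lt(mean(accs), 0.75)
})

test_that("results are written readably and round-trip numerically", {
  syn <- tiny_synthetic()
  cfg <- hicats_config(generations = 2, ts_iters = 1, ts_neighbors = 3,
                       cv = "kfold", folds = 4, seed = 5)
  res <- run_hicats(syn$dataset, cfg)
  prefix <- file.path(tempdir(), "hicats_test_run")
  paths <- write_result(res, prefix)
  expect_true(all(file.exists(paths)))

  summary_txt <- readLines(paths[1])
  expect_true(any(grepl(sprintf("%.2f", 100 * res$best_accuracy),
                        summary_txt, fixed = TRUE)))
  expect_true(any(grepl(sprintf("selected genes: %d", res$best_n_selected),
                        summary_txt, fixed = TRUE)))
  for (g in res$selected_gene_names)
    expect_true(any(grepl(g, summary_txt, fixed = TRUE)))

  relog <- read.delim(paths[2])
  expect_equal(nrow(relog), nrow(res$log))
  expect_equal(relog$best_fitness, res$log$best_fitness)
  expect_equal(relog$evaluations, res$log$evaluations)

  manifest <- jsonlite::read_json(paths[3])
  expect_equal(manifest$best_accuracy, res$best_accuracy)
  expect_equal(unlist(manifest$selected_genes), res$selected_gene_names)
})
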