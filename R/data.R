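#' Construct a gene expression dataset
#'
#' @param matrix numeric samples x genes matrix.
#' @param labels one class label per sample (coerced to factor).
#' @param gene_names optional gene identifiers; defaults to the matrix column
#'   names or `g1..gN`.
#' @return An object of class `gene_dataset` with fields `matrix`, `labels`,
#'   `gene_names` and `n` (total gene count, the denominator of the parsimony
#'   term of the fitness).
#' @export
gene_dataset <- function(matrix, labels, gene_names = NULL) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (anyNA(matrix)) stop("expression matrix contains missing values")
  if (nrow(matrix) != length(labels))
    stop(sprintf("matrix has %d rows but %d labels", nrow(matrix), length(labels)))
  if (nrow(matrix) < 2L) stop("need at least 2 samples")
  if (is.null(gene_names)) gene_names <- colnames(matrix)
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(ncol(matrix)))
  if (length(gene_names) != ncol(matrix))
    stop(sprintf("matrix has %d genes but %d gene names",
                 ncol(matrix), length(gene_names)))
  labels <- factor(labels)
  if (nlevels(labels) < 1L) stop("labels contain no classes")
  colnames(matrix) <- gene_names
  structure(
    list(matrix = matrix, labels = labels, gene_names = gene_names,
         n = ncol(matrix)),
    class = "gene_dataset"
  )
}

#' @export
print.gene_dataset <- function(x, ...) {
  cat(sprintf("<gene_dataset> %d samples x %d genes, %d classes (%s)\n",
              nrow(x$matrix), x$n, nlevels(x$labels),
              paste(levels(x$labels), collapse = ", ")))
  invisible(x)
}

#' Read an expression table from delimited text
#'
#' Reads a CSV/TSV expression matrix with a header row. The delimiter is
#' inferred from the extension (`.csv` comma; `.tsv`/`.txt` tab). Labels come
#' either from a named column of the table (`label_column`) or from a separate
#' single-column file (`label_file`), matched to samples by order.
#'
#' @param path path to the delimited expression table.
#' @param orientation `"samples"` if samples are rows (default) or `"genes"`
#'   if genes are rows (the layout many microarray distributions use); the
#'   latter is transposed on read.
#' @param label_column name of the column holding class labels (only for
#'   samples-in-rows input).
#' @param label_file path to a headerless single-column text file with one
#'   label per sample.
#' @return A [gene_dataset()].
#' @export
read_expression_table <- function(path, orientation = c("samples", "genes"),
                                  label_column = NULL, label_file = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  labels <- NULL
  if (!is.null(label_column)) {
    if (orientation == "genes")
      stop("label_column applies only to samples-in-rows input; ",
           "use label_file for genes-in-rows data")
    if (!label_column %in% names(tab))
      stop("label column '", label_column, "' not found in ", path)
    labels <- tab[[label_column]]
    tab <- tab[, setdiff(names(tab), label_column), drop = FALSE]
  }
  first_col_ids <- !all(vapply(tab[1L], is.numeric, logical(1)))
  if (first_col_ids) {
    rn <- as.character(tab[[1L]])
    tab <- tab[, -1L, drop = FALSE]
    rownames(tab) <- rn
  }
  bad <- which(!vapply(tab, is.numeric, logical(1)))
  if (length(bad))
    stop("non-numeric expression values in column(s): ",
         paste(names(tab)[bad], collapse = ", "))
  m <- as.matrix(tab)
  if (orientation == "genes") m <- t(m)
  if (!is.null(label_file)) {
    if (!file.exists(label_file)) stop("label file not found: ", label_file)
    labels <- scan(label_file, what = character(), quiet = TRUE)
  }
  if (is.null(labels))
    stop("no labels: supply label_column or label_file")
  if (length(labels) != nrow(m))
    stop(sprintf("label/sample mismatch: %d labels for %d samples",
                 length(labels), nrow(m)))
  gene_dataset(m, labels)
}

#' Generate a synthetic expression dataset with planted informative genes
#'
#' Emulates the regime of public microarray benchmarks — tens of samples,
#' hundreds to thousands of genes, few classes — with a known ground truth:
#' `n_informative` genes carry class signal, the rest are pure noise. Samples
#' are split across classes as evenly as possible. For each informative gene,
#' class `c` (0-based) has mean `c * effect_size * noise_sd`, an additive
#' ladder of class means separated by `effect_size` noise standard deviations;
#' non-informative genes have mean 0 for every class. All values are Gaussian
#' with standard deviation `noise_sd`.
#'
#' @param n_samples,n_genes dataset dimensions.
#' @param n_informative number of genes carrying class signal.
#' @param n_classes number of classes (`n_samples >= n_classes`).
#' @param effect_size class-mean separation in units of `noise_sd`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed optional integer seed; the same spec + seed always yields an
#'   identical dataset.
#' @return A list with elements `dataset` (a [gene_dataset()]) and `planted`
#'   (sorted positions of the informative genes).
#' @export
make_synthetic <- function(n_samples = 40, n_genes = 200, n_informative = 5,
                           n_classes = 3, effect_size = 3, noise_sd = 1,
                           seed = NULL) {
  if (n_informative > n_genes) stop("n_informative exceeds n_genes")
  if (n_classes < 1L) stop("need at least one class")
  if (n_samples < n_classes) stop("need at least one sample per class")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (!is.null(seed)) set.seed(seed)
  sizes <- rep(n_samples %/% n_classes, n_classes)
  extra <- n_samples %% n_classes
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- rep(paste0("class", seq_len(n_classes)), times = sizes)
  planted <- sort(sample_vec(seq_len(n_genes), n_informative))
  m <- matrix(stats::rnorm(n_samples * n_genes, sd = noise_sd),
              n_samples, n_genes)
  class_idx <- rep(seq_len(n_classes) - 1L, times = sizes)
  for (g in planted)
    m[, g] <- m[, g] + class_idx * effect_size * noise_sd
  list(dataset = gene_dataset(m, labels), planted = planted)
}

#' Write run results to disk
#'
#' Writes three files under a common prefix: `<prefix>_summary.txt` (human-
#' readable best subset, accuracy as a percentage, configuration and seed),
#' `<prefix>_convergence.tsv` (per-generation log, tab-separated at full
#' precision) and `<prefix>_manifest.json` (machine-readable configuration,
#' seed and selected genes).
#'
#' @param result a `hicats_result` from [run_hicats()].
#' @param out_prefix path prefix for the output files.
#' @return Invisibly, the paths written.
#' @export
write_result <- function(result, out_prefix) {
  stopifnot(inherits(result, "hicats_result"))
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summary_path <- paste0(out_prefix, "_summary.txt")
  log_path <- paste0(out_prefix, "_convergence.tsv")
  manifest_path <- paste0(out_prefix, "_manifest.json")

  cfg <- result$config
  lines <- c(
    "HICATS run summary",
    sprintf("best accuracy (%%): %.2f", 100 * result$best_accuracy),
    sprintf("selected genes: %d", result$best_n_selected),
    sprintf("gene names: %s", paste(result$selected_gene_names, collapse = ", ")),
    sprintf("best fitness: %.6f", result$best_fitness),
    "",
    "configuration:",
    sprintf("  %s: %s", names(unclass(cfg)),
            vapply(unclass(cfg), function(v) paste(format(v), collapse = ","),
                   character(1)))
  )
  writeLines(lines, summary_path)
  utils::write.table(result$log, log_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(cfg),
         best_accuracy = result$best_accuracy,
         best_fitness = result$best_fitness,
         selected_genes = as.list(result$selected_gene_names)),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(summary_path, log_path, manifest_path))
}
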