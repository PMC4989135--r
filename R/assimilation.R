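#' Asymmetric difference mask between imperialist and colony
#'
#' Bit `i` is 1 iff the imperialist selects gene `i` and the colony does not
#' (1 - 0 = 1; all other bit combinations give 0). The 1-bits mark the
#' "difference genes" a colony can learn from its imperialist.
#'
#' @param imperialist,colony `country` objects of equal length.
#' @return 0/1 integer vector of the same length.
#' @export
difference_mask <- function(imperialist, colony) {
  if (length(imperialist$bits) != length(colony$bits))
    stop("imperialist and colony have different lengths")
  as.integer(imperialist$bits == 1L & colony$bits == 0L)
}

#' Number of difference genes transferred to the colony
#'
#' `beta * diff_count` rounded to the nearest integer with halves rounded up,
#' capped at `diff_count`.
#'
#' @param diff_count number of difference genes (non-negative).
#' @param beta learning rate in (0, 1): the proportion of difference genes
#'   the colony acquires.
#' @return Integer in `0..diff_count`.
#' @export
transfer_count <- function(diff_count, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta >= 1)
    stop("beta must lie in (0, 1)")
  if (diff_count < 0) stop("diff_count must be non-negative")
  min(diff_count, floor(beta * diff_count + 0.5))
}

#' Random binary templates for assimilation
#'
#' `bt` is a fair-coin bit vector whose length is the larger of the two
#' subset sizes; `btf` is its bitwise complement. `imbt` and `cobt` are the
#' prefixes of `bt` and `btf` of the imperialist's and colony's subset sizes
#' respectively. Only `cobt` shapes the assimilation output (it masks which
#' of the colony's own genes survive); `imbt` is carried for completeness.
#'
#' @param n_im_selected,n_co_selected subset sizes (both >= 1).
#' @return An object of class `assimilation_templates` with fields `bt`,
#'   `btf`, `imbt`, `cobt`.
#' @export
make_templates <- function(n_im_selected, n_co_selected) {
  if (n_im_selected < 1L || n_co_selected < 1L)
    stop("subset sizes must be positive")
  len <- max(n_im_selected, n_co_selected)
  bt <- as.integer(stats::runif(len) < 0.5)
  btf <- 1L - bt
  structure(
    list(bt = bt, btf = btf,
         imbt = bt[seq_len(n_im_selected)],
         cobt = btf[seq_len(n_co_selected)]),
    class = "assimilation_templates"
  )
}

#' Assimilate a colony toward its imperialist
#'
#' The Baldwinian binary move: the colony acquires a random `beta` proportion
#' of the difference genes (genes its imperialist selects but it does not),
#' and keeps only those of its own genes whose position in the colony-side
#' template `cobt` (ascending gene order) carries a 1. The union of acquired
#' and kept genes forms the new colony; every selected gene of the output was
#' selected by the imperialist or the colony. Because the template halves the
#' colony's own genes in expectation, assimilation also shrinks subsets.
#'
#' `beta`, `templates` and `transfer` default to fresh random draws; passing
#' them explicitly pins the move (useful for tracing a single assimilation by
#' hand).
#'
#' @param imperialist,colony evaluated/repaired `country` objects of equal
#'   length.
#' @param beta learning rate in (0, 1); drawn uniformly per call by default.
#' @param templates an [make_templates()] object, or NULL to draw one.
#' @param transfer positions of the difference genes to transfer, or NULL to
#'   sample `transfer_count` of them uniformly without replacement.
#' @return The assimilated colony (unevaluated, repaired to non-empty).
#' @export
assimilate <- function(imperialist, colony, beta = NULL, templates = NULL,
                       transfer = NULL) {
  mask <- difference_mask(imperialist, colony)
  diff_pos <- which(mask == 1L)
  if (is.null(beta)) beta <- stats::runif(1)
  if (is.null(transfer)) {
    k <- transfer_count(length(diff_pos), beta)
    transfer <- sample_vec(diff_pos, k)
  } else {
    if (!all(transfer %in% diff_pos))
      stop("transfer positions must be difference genes")
  }
  co_sel <- selected_indices(colony)
  if (is.null(templates))
    templates <- make_templates(max(imperialist$n_selected, 1L),
                                max(colony$n_selected, 1L))
  cobt <- templates$cobt
  if (length(cobt) != length(co_sel))
    stop("cobt length does not match the colony's subset size")
  kept <- co_sel[cobt == 1L]
  bits <- integer(length(colony$bits))
  bits[c(transfer, kept)] <- 1L
  if (!any(bits == 1L)) {
    # repair inside the parents' gene pool: assimilation never invents a gene
    pool <- union(selected_indices(imperialist), co_sel)
    bits[sample_vec(pool, 1L)] <- 1L
  }
  new_country(bits)
}
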