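#' Discretize expression into equal-frequency tertiles
#'
#' Each gene's non-missing values are ranked (stable, ties broken by sample
#' index) and split into three equal-frequency bins coded 0/1/2; bin counts
#' differ by at most one. Genes with zero interquartile range carry no usable
#' signal for a three-level dependence test: they are set to the middle level
#' everywhere and listed in `degenerate_genes`, and downstream stages exclude
#' them from candidate pairs while keeping them as cluster members for
#' bookkeeping. Missing cells (already below the reader's per-gene tolerance)
#' are assigned the middle level.
#'
#' @param x An `expression_matrix`.
#' @return A `discretized_matrix`: list with `gene_ids`, `sample_ids`, `levels`
#'   (integer matrix, entries 0/1/2), `bin_edges` (per-gene value thresholds),
#'   `degenerate_genes`.
#' @examples
#' m <- matrix(1:9, 1, dimnames = list("g1", paste0("s", 1:9)))
#' x <- new_expression_matrix("g1", colnames(m), m, m == Inf)
#' discretize(x)$levels  # 0 0 0 1 1 1 2 2 2
#' @export
discretize <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (length(x$sample_ids) < 6L) {
    stop(ddn_validation_error("discretize requires at least 6 samples"))
  }
  n_genes <- length(x$gene_ids)
  lev <- matrix(1L, n_genes, length(x$sample_ids),
                dimnames = dimnames(x$values))
  edges <- matrix(NA_real_, n_genes, 2,
                  dimnames = list(x$gene_ids, c("lower", "upper")))
  degenerate <- character(0)
  for (i in seq_len(n_genes)) {
    obs <- which(!x$missing_mask[i, ])
    v <- x$values[i, obs]
    if (length(v) < 6L || stats::IQR(v) == 0) {
      degenerate <- c(degenerate, x$gene_ids[i])
      next
    }
    r <- rank(v, ties.method = "first")
    n <- length(v)
    lev[i, obs] <- as.integer(floor((r - 1) * 3 / n))
    edges[i, ] <- stats::quantile(v, c(1 / 3, 2 / 3), type = 7)
  }
  structure(
    list(gene_ids = x$gene_ids, sample_ids = x$sample_ids, levels = lev,
         bin_edges = edges, degenerate_genes = degenerate),
    class = "discretized_matrix"
  )
}

new_discretized_matrix <- function(levels, degenerate_genes = character(0)) {
  stopifnot(is.matrix(levels), all(levels %in% 0:2))
  structure(
    list(gene_ids = rownames(levels), sample_ids = colnames(levels),
         levels = levels,
         bin_edges = matrix(NA_real_, nrow(levels), 2,
                            dimnames = list(rownames(levels), c("lower", "upper"))),
         degenerate_genes = degenerate_genes),
    class = "discretized_matrix"
  )
}

#' @export
print.discretized_matrix <- function(x, ...) {
  cat(sprintf("<discretized_matrix> %d genes x %d samples (%d degenerate)\n",
              length(x$gene_ids), length(x$sample_ids),
              length(x$degenerate_genes)))
  invisible(x)
}

#' G-test of independence for a discretized gene pair
#'
#' Likelihood-ratio test on the 3x3 contingency table of two level vectors:
#' G = 2 * sum O * ln(O/E) over non-zero cells, with degrees of freedom
#' (r-1)(c-1) after deleting all-zero rows and columns, and the p-value from
#' the chi-square upper tail. A table with fewer than two non-empty rows or
#' columns (e.g. a constant gene) is uninformative and reported as independent
#' (p = 1).
#'
#' @param levels_a,levels_b Equal-length integer vectors with entries in 0:2.
#' @param williams Apply Williams' small-sample correction (divide G by the
#'   Williams q factor). The plain statistic (default) matches the closed-form
#'   G; the corrected variant is what the resampling engine uses internally,
#'   where effective sample sizes are small.
#' @return List with `G`, `df`, `p`, and `informative` (FALSE for degenerate
#'   tables).
#' @examples
#' a <- rep(0:2, each = 10)
#' g_test_pair(a, a)$G  # 60 * log(3)
#' @export
g_test_pair <- function(levels_a, levels_b, williams = FALSE) {
  stopifnot(length(levels_a) == length(levels_b), length(levels_a) >= 10L,
            all(levels_a %in% 0:2), all(levels_b %in% 0:2))
  r <- .gtest_pair_cpp(as.integer(levels_a), as.integer(levels_b), williams)
  list(G = r[[1]], df = as.integer(r[[2]]), p = r[[3]], informative = r[[4]] == 1)
}
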