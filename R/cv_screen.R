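#' Minimum-expression filter
#'
#' Drops genes that fall below a minimum expression level in *any* sample.
#' Genes expressed this low make poor qPCR references because they are hard
#' to detect and quantify reliably. The boundary is inclusive: a gene exactly
#' at the threshold in its weakest sample is retained (only values strictly
#' below the threshold exclude).
#'
#' @param m an [expr_matrix] in FPKM.
#' @param min_expression threshold in FPKM (default 5).
#' @return A list with `matrix` (the retained [expr_matrix]) and `excluded`
#'   (data.frame `gene_id`, `sample_id`, `value` giving, per excluded gene,
#'   the sample with its lowest expression).
#' @export
filter_min_expression <- function(m, min_expression = 5) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "FPKM")
    stop_refstab("filter_min_expression expects FPKM (got %s); convert counts first", m$unit)
  if (nrow(m$values) == 0) stop_refstab("empty expression matrix")
  if (min_expression < 0) stop_refstab("min_expression must be >= 0")
  lo <- apply(m$values, 1, min)
  keep <- lo >= min_expression
  if (any(!keep)) {
    worst <- colnames(m$values)[
      apply(m$values[!keep, , drop = FALSE], 1, which.min)]
  } else {
    worst <- character(0)
  }
  excluded <- data.frame(gene_id = rownames(m$values)[!keep],
                         sample_id = worst,
                         value = lo[!keep],
                         row.names = NULL, stringsAsFactors = FALSE)
  kept <- m
  kept$values <- m$values[keep, , drop = FALSE]
  list(matrix = kept, excluded = excluded)
}

#' Per-gene expression stability by coefficient of variation
#'
#' For every gene, the arithmetic mean and sample standard deviation
#' (n-1 denominator) are taken over all samples, and the coefficient of
#' variation CV = SD/mean is the stability score: low CV means stable
#' expression. Genes are ranked ascending by CV (rank 1 = most stable), with
#' ties broken lexicographically by gene id. A gene with mean 0 has an
#' undefined CV; it is flagged (`cv = NA`) and not ranked.
#'
#' @param m an [expr_matrix] with at least two samples, normally already
#'   passed through [filter_min_expression].
#' @return A `stability_table`: data.frame with columns `gene_id`, `mean`,
#'   `sd`, `cv`, `rank`, ordered by rank (unranked genes last).
#' @examples
#' vals <- matrix(c(8, 12, 10, 10), nrow = 2, byrow = TRUE,
#'                dimnames = list(c("gA", "gB"), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"), species = "x",
#'                    tissue = c("leaf", "stem"), batch = "T1")
#' stability_cv(expr_matrix(vals, meta, "FPKM"))
#' @export
stability_cv <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < 2)
    stop_refstab("stability_cv needs at least 2 samples")
  mu <- rowMeans(m$values)
  sdev <- apply(m$values, 1, stats::sd)
  cv <- ifelse(mu == 0, NA_real_, sdev / mu)
  tab <- data.frame(gene_id = rownames(m$values), mean = mu, sd = sdev,
                    cv = cv, rank = NA_integer_,
                    row.names = NULL, stringsAsFactors = FALSE)
  ok <- !is.na(cv)
  tab$rank[ok] <- rank_with_ties(tab$cv[ok], tab$gene_id[ok])
  tab <- tab[order(is.na(tab$rank), tab$rank, tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("stability_table", "data.frame")
  tab
}

#' Top-n most stable genes
#'
#' @param t a `stability_table` from [stability_cv].
#' @param n how many genes to return; if `n` exceeds the number of ranked
#'   genes, all are returned with a warning.
#' @return The first `n` rows by rank, with attribute `max_cv` giving the
#'   largest CV in the list.
#' @export
top_stable <- function(t, n) {
  stopifnot(inherits(t, "stability_table"), n >= 1)
  ranked <- t[!is.na(t$rank), , drop = FALSE]
  ranked <- ranked[order(ranked$rank), , drop = FALSE]
  if (n > nrow(ranked)) {
    warning(sprintf("requested top %d but only %d ranked genes; returning all",
                    n, nrow(ranked)))
    n <- nrow(ranked)
  }
  out <- ranked[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "max_cv") <- max(out$cv)
  out
}

#' Count genes below a CV threshold
#'
#' Uses a strict inequality: a gene exactly at the threshold is not counted.
#' The conventional cut-off for a usable qPCR reference gene across
#' heterogeneous samples is CV < 0.5.
#'
#' @param t a `stability_table`.
#' @param threshold CV cut-off (default 0.5).
#' @return list with `below` (genes with CV strictly below) and `total`
#'   (ranked genes evaluated).
#' @export
cv_threshold_summary <- function(t, threshold = 0.5) {
  stopifnot(inherits(t, "stability_table"))
  ok <- !is.na(t$cv)
  list(below = sum(t$cv[ok] < threshold), total = sum(ok))
}

#' @export
print.stability_table <- function(x, ...) {
  cat(sprintf("stability_table: %d genes (%d ranked)\n",
              nrow(x), sum(!is.na(x$rank))))
  print.data.frame(utils::head(x, 10), digits = 4)
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}
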