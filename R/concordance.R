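#' Per-gene summary statistics of an expression matrix
#'
#' @param m an [expr_matrix].
#' @return data.frame with `gene_id`, `mean`, `cv` over the matrix's samples.
#' @export
gene_stats <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  mu <- rowMeans(m$values)
  cv <- ifelse(mu == 0, NA_real_, apply(m$values, 1, stats::sd) / mu)
  data.frame(gene_id = rownames(m$values), mean = mu, cv = cv,
             row.names = NULL, stringsAsFactors = FALSE)
}

new_concordance_report <- function(metric, source_a, source_b, x, y,
                                   exclusion_rule) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input vector: Pearson correlation undefined")
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(metric = metric, source_a = source_a, source_b = source_b,
                 n_genes = length(x), pearson_r = r, p_value = p,
                 exclusion_rule = exclusion_rule),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance [%s] %s vs %s: r = %.3f, p = %.3g, n = %d\n",
              x$metric, x$source_a, x$source_b, x$pearson_r, x$p_value,
              x$n_genes))
  if (nzchar(x$exclusion_rule)) cat("  exclusions:", x$exclusion_rule, "\n")
  invisible(x)
}

#' Cross-batch concordance of expression means or CVs
#'
#' Compares two expression matrices (typically the two biological-replicate
#' transcriptome sets of one species, each spanning the same tissues) on a
#' per-gene summary: either the mean expression or the CV across each
#' batch's samples. Genes whose mean falls below `min_mean_fpkm` in either
#' batch are excluded. Mean concordance is computed on log10 values by
#' default, since expression means span orders of magnitude; CVs are
#' correlated on the raw scale.
#'
#' @param a,b two [expr_matrix] objects sharing gene ids.
#' @param metric `"mean"` or `"cv"`.
#' @param min_mean_fpkm exclusion threshold on the per-batch mean (default 1).
#' @param log10_means log10-transform means before correlating (default TRUE;
#'   ignored for `metric = "cv"`).
#' @param log_offset added before the log when zeros are possible (default 0).
#' @return A `concordance_report` with Pearson r and the two-sided p-value
#'   from the linear-model t-test at n-2 degrees of freedom.
#' @export
replicate_concordance <- function(a, b, metric = c("mean", "cv"),
                                  min_mean_fpkm = 1, log10_means = TRUE,
                                  log_offset = 0) {
  metric <- match.arg(metric)
  sa <- gene_stats(a); sb <- gene_stats(b)
  shared <- intersect(sa$gene_id, sb$gene_id)
  if (length(shared) < 3) stop_refstab("fewer than 3 shared genes")
  ia <- match(shared, sa$gene_id); ib <- match(shared, sb$gene_id)
  keep <- sa$mean[ia] >= min_mean_fpkm & sb$mean[ib] >= min_mean_fpkm
  ia <- ia[keep]; ib <- ib[keep]
  if (length(ia) < 3)
    stop_refstab("fewer than 3 genes after the mean >= %.3g exclusion", min_mean_fpkm)
  if (metric == "mean") {
    x <- sa$mean[ia]; y <- sb$mean[ib]
    if (log10_means) { x <- log10(x + log_offset); y <- log10(y + log_offset) }
  } else {
    x <- sa$cv[ia]; y <- sb$cv[ib]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
  }
  rule <- sprintf("genes with mean < %.3g in either batch excluded", min_mean_fpkm)
  new_concordance_report(metric, "batch_a", "batch_b", x, y, rule)
}

#' Cross-platform concordance (RNA-seq vs qPCR)
#'
#' Correlates matched per-gene summaries from two measurement platforms,
#' e.g. RNA-seq FPKM means against qPCR relative-expression means (the two
#' are on different scales, but Pearson r on log10 values is scale-free), or
#' RNA-seq CVs against qPCR CVs on the raw scale.
#'
#' @param x,y named numeric vectors of per-gene summaries; names must match
#'   one-to-one.
#' @param metric `"mean"` or `"cv"` (means are log10-transformed by default).
#' @param log10_means,log_offset as in [replicate_concordance].
#' @param source_a,source_b labels for the report.
#' @return A `concordance_report`. With a constant input the correlation is
#'   undefined: `pearson_r` is `NA` and a warning is raised.
#' @export
platform_concordance <- function(x, y, metric = c("mean", "cv"),
                                 log10_means = TRUE, log_offset = 0,
                                 source_a = "rnaseq", source_b = "qpcr") {
  metric <- match.arg(metric)
  if (is.null(names(x)) || is.null(names(y)))
    stop_refstab("x and y must be named by gene id")
  unmatched <- c(setdiff(names(x), names(y)), setdiff(names(y), names(x)))
  if (length(unmatched))
    stop_refstab("unmatched gene id(s): %s", paste(unique(unmatched), collapse = ", "))
  y <- y[names(x)]
  if (length(x) < 3) stop_refstab("need at least 3 genes, got %d", length(x))
  if (metric == "mean" && log10_means) {
    x <- log10(x + log_offset); y <- log10(y + log_offset)
  }
  new_concordance_report(metric, source_a, source_b, x, y, "")
}
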