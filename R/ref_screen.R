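#' Screen a transcriptome for candidate qPCR reference genes
#'
#' The package's central estimator. Runs, on one gene x sample expression
#' matrix:
#' \enumerate{
#'   \item the minimum-expression filter (genes below `min_expression` FPKM
#'     in any sample are dropped — too weakly expressed to normalize against);
#'   \item the CV screen: per-gene coefficient of variation (SD/mean over all
#'     samples) ranked ascending, the conventional usable-reference cut-off
#'     being CV < `cv_cutoff`;
#'   \item the fold-change screen: any gene whose absolute log2 fold change
#'     exceeds `fc_cutoff` in any pairwise sample comparison is eliminated.
#' }
#' Each surviving gene receives a verdict: `STRONG` when it is both
#' fold-change-retained and within the CV top `top_n`; `CV_ONLY` / `FC_ONLY`
#' when only one screen selects it; `REJECTED` otherwise. Ideal reference
#' genes score well on both metrics.
#'
#' @param m an [expr_matrix]; counts are converted to FPKM for the filter and
#'   CV screen when `gene_lengths` is supplied.
#' @param min_expression FPKM filter threshold (default 5).
#' @param cv_cutoff CV threshold for the summary count (default 0.5).
#' @param top_n CV list size defining `STRONG`/`CV_ONLY` (default 50).
#' @param fc_cutoff fold-change elimination cutoff in log2 units
#'   (default 0.4).
#' @param normalize normalization for the fold-change screen: `"cpm"` for
#'   counts, `"none"` for FPKM input.
#' @param pseudocount pseudocount for log fold changes (default 0.5).
#' @param gene_lengths named vector of lengths in bp; required when `m` is
#'   counts.
#' @param homeolog_map optional homeolog pairing (see [average_homeologs]);
#'   pairs are averaged before screening.
#' @param qpcr_cv optional named vector of per-gene qPCR CVs to carry into
#'   the report for validated genes.
#' @return An object of class `ref_screen` with components `report`
#'   (per-gene candidate table), `stability` (the `stability_table`), `fc`
#'   (the `fc_screen` table), `excluded` (filter casualties), `summary`
#'   (counts), and `params`.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 300, n_stable = 10, seed = 7))
#' fit <- screen_reference_genes(sim$counts, gene_lengths = sim$gene_lengths,
#'                               normalize = "cpm")
#' fit
#' head(summary(fit))
#' @export
screen_reference_genes <- function(m, min_expression = 5, cv_cutoff = 0.5,
                                   top_n = 50, fc_cutoff = 0.4,
                                   normalize = c("none", "cpm"),
                                   pseudocount = 0.5, gene_lengths = NULL,
                                   homeolog_map = NULL, qpcr_cv = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  normalize <- match.arg(normalize)
  if (m$unit == "COUNTS") {
    if (is.null(gene_lengths))
      stop_refstab("counts input needs gene_lengths to compute FPKM for the filter/CV screen")
    fpkm <- counts_to_fpkm(m, gene_lengths)
    fc_input_full <- m                     # fold changes from counts, CPM-normalized
    if (normalize == "none") normalize <- "cpm"
  } else {
    fpkm <- m
    fc_input_full <- m
    normalize <- "none"                    # FPKM is already depth/length normalized
  }
  if (!is.null(homeolog_map)) {
    fpkm <- average_homeologs(fpkm, homeolog_map)
    fc_input_full <- average_homeologs(fc_input_full, homeolog_map)
  }
  flt <- filter_min_expression(fpkm, min_expression)
  kept_ids <- rownames(flt$matrix$values)
  stab <- stability_cv(flt$matrix)
  fc_input <- subset_expr(fc_input_full, genes = kept_ids)
  fc <- foldchange_screen(fc_input, cutoff = fc_cutoff, normalize = normalize,
                          pseudocount = pseudocount)

  report <- stab[, c("gene_id", "mean", "sd", "cv", "rank")]
  class(report) <- "data.frame"
  names(report)[names(report) == "rank"] <- "cv_rank"
  fi <- match(report$gene_id, fc$gene_id)
  report$max_abs_logfc <- fc$max_abs_logfc[fi]
  report$in_fc_list <- fc$retained[fi]
  report$qpcr_cv <- if (is.null(qpcr_cv)) NA_real_
                    else unname(qpcr_cv[report$gene_id])
  in_top <- !is.na(report$cv_rank) & report$cv_rank <= top_n
  report$verdict <- ifelse(report$in_fc_list & in_top, "STRONG",
                    ifelse(in_top, "CV_ONLY",
                    ifelse(report$in_fc_list, "FC_ONLY", "REJECTED")))
  report <- report[order(report$cv_rank), , drop = FALSE]
  rownames(report) <- NULL

  thr <- cv_threshold_summary(stab, cv_cutoff)
  structure(list(
    report = report,
    stability = stab,
    fc = fc,
    excluded = flt$excluded,
    summary = list(n_input = nrow(fpkm$values),
                   n_filtered = length(kept_ids),
                   n_cv_below_cutoff = thr$below,
                   n_fc_retained = sum(fc$retained),
                   top_n_max_cv = attr(top_stable(stab, min(top_n, sum(!is.na(stab$rank)))),
                                       "max_cv"),
                   n_strong = sum(report$verdict == "STRONG")),
    params = list(min_expression = min_expression, cv_cutoff = cv_cutoff,
                  top_n = top_n, fc_cutoff = fc_cutoff,
                  normalize = normalize, pseudocount = pseudocount)),
    class = "ref_screen")
}

#' @export
print.ref_screen <- function(x, ...) {
  s <- x$summary; p <- x$params
  cat("Reference-gene stability screen\n")
  cat(sprintf("  input genes:            %d\n", s$n_input))
  cat(sprintf("  pass >= %g FPKM filter: %d\n", p$min_expression, s$n_filtered))
  cat(sprintf("  CV < %g:                %d\n", p$cv_cutoff, s$n_cv_below_cutoff))
  cat(sprintf("  top-%d max CV:          %.4f\n", p$top_n, s$top_n_max_cv))
  cat(sprintf("  fold-change retained (|log2FC| <= %g): %d\n",
              p$fc_cutoff, s$n_fc_retained))
  cat(sprintf("  STRONG candidates (both screens): %d\n", s$n_strong))
  invisible(x)
}

#' @export
summary.ref_screen <- function(object, ...) {
  object$report
}

#' Per-gene stability coefficients of a screen
#'
#' @param object a `ref_screen`.
#' @param ... unused.
#' @return Named numeric vector of CVs for the filtered genes, in rank order.
#' @export
coef.ref_screen <- function(object, ...) {
  stats::setNames(object$report$cv, object$report$gene_id)
}

#' Plot the CV distribution of a screen
#'
#' Density of per-gene CVs over all filtered genes, with the usable-reference
#' cut-off marked and the top-n region shaded.
#'
#' @param x a `ref_screen`.
#' @param ... passed to [graphics::plot].
#' @export
plot.ref_screen <- function(x, ...) {
  cvs <- x$stability$cv[!is.na(x$stability$cv)]
  d <- stats::density(cvs, from = 0)
  graphics::plot(d, main = "Per-gene expression CV", xlab = "CV (SD/mean)", ...)
  top_max <- x$summary$top_n_max_cv
  sel <- d$x <= top_max
  graphics::polygon(c(d$x[sel], top_max, 0), c(d$y[sel], 0, 0), col = "black")
  graphics::abline(v = x$params$cv_cutoff, lty = 2)
  graphics::legend("topright", bty = "n",
                   legend = c(sprintf("top-%d region", x$params$top_n),
                              sprintf("CV cut-off %.2f", x$params$cv_cutoff)),
                   lty = c(NA, 2), pch = c(15, NA))
  invisible(x)
}
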