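#' Library-size (counts-per-million) normalization
#'
#' Scales each sample's counts to counts per million so that pairwise fold
#' changes are not driven by sequencing depth. This is plain per-sample
#' library-size scaling; any alternative normalizer returning a gene x sample
#' matrix can be plugged into [foldchange_screen] via `normalizer`.
#'
#' @param m an [expr_matrix] with unit `"COUNTS"`.
#' @return An `expr_matrix` with values in CPM; the unit tag stays
#'   `"COUNTS"`, since CPM is a per-sample rescaling of counts.
#' @export
normalize_library_size <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "COUNTS")
    stop_refstab("normalize_library_size expects COUNTS, got %s", m$unit)
  libs <- colSums(m$values)
  if (any(libs == 0))
    stop_refstab("zero library size in sample(s): %s",
                 paste(colnames(m$values)[libs == 0], collapse = ", "))
  out <- m
  out$values <- sweep(m$values, 2, libs / 1e6, "/")
  out
}

#' All pairwise log2 fold changes
#'
#' For every unordered sample pair (i, j) and every gene g,
#' `lfc[g, i~j] = log2((v[g,i] + p) / (v[g,j] + p))` with pseudocount `p`
#' guarding zeros. Antisymmetric in (i, j) by construction.
#'
#' @param m an [expr_matrix] (already normalized as desired).
#' @param pseudocount added to both numerator and denominator (default 0.5).
#' @return Numeric matrix, genes x pairs; column names `"i|j"`. The pair
#'   definition is stored in attribute `pairs` (data.frame `a`, `b`).
#' @export
pairwise_logfc <- function(m, pseudocount = 0.5) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- m$values
  ns <- ncol(v)
  if (ns < 2) stop_refstab("pairwise_logfc needs at least 2 samples")
  if (pseudocount < 0) stop_refstab("pseudocount must be >= 0")
  idx <- utils::combn(ns, 2)
  lfc <- log2(v[, idx[1, ], drop = FALSE] + pseudocount) -
         log2(v[, idx[2, ], drop = FALSE] + pseudocount)
  a <- colnames(v)[idx[1, ]]
  b <- colnames(v)[idx[2, ]]
  colnames(lfc) <- paste(a, b, sep = "|")
  attr(lfc, "pairs") <- data.frame(a = a, b = b, stringsAsFactors = FALSE)
  lfc
}

#' Fold-change exclusion screen for stable genes
#'
#' Eliminates every gene whose absolute log2 fold change exceeds `cutoff` in
#' *any* pairwise sample comparison; what survives is a short list of genes
#' with uniformly low expression variation. Retention uses `<=`: a gene whose
#' worst pair sits exactly at the cutoff survives. The input should already
#' be restricted to reliably expressed genes (see [filter_min_expression]).
#'
#' @param m an [expr_matrix]; counts are CPM-normalized first unless
#'   `normalize = "none"` (use `"none"` for FPKM input, which is already
#'   length- and depth-normalized).
#' @param cutoff maximum tolerated absolute log2 fold change (e.g. 0.4).
#' @param normalize `"cpm"` or `"none"`.
#' @param pseudocount passed to [pairwise_logfc].
#' @param normalizer optional function `expr_matrix -> expr_matrix` replacing
#'   the built-in CPM step.
#' @return data.frame (class `fc_screen`) with columns `gene_id`,
#'   `max_abs_logfc`, `worst_pair_a`, `worst_pair_b`, `retained`, ordered by
#'   `max_abs_logfc` ascending. Attribute `cutoff` records the cutoff.
#' @export
foldchange_screen <- function(m, cutoff, normalize = c("cpm", "none"),
                              pseudocount = 0.5, normalizer = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  normalize <- match.arg(normalize)
  if (cutoff <= 0) stop_refstab("cutoff must be > 0")
  if (!is.null(normalizer)) {
    m <- normalizer(m)
  } else if (normalize == "cpm") {
    m <- normalize_library_size(m)
  }
  lfc <- pairwise_logfc(m, pseudocount = pseudocount)
  pairs <- attr(lfc, "pairs")
  worst_idx <- apply(abs(lfc), 1, which.max)
  max_abs <- abs(lfc)[cbind(seq_len(nrow(lfc)), worst_idx)]
  out <- data.frame(gene_id = rownames(lfc),
                    max_abs_logfc = max_abs,
                    worst_pair_a = pairs$a[worst_idx],
                    worst_pair_b = pairs$b[worst_idx],
                    retained = max_abs <= cutoff,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$max_abs_logfc, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!any(out$retained))
    warning(sprintf("no genes retained at cutoff %.3g", cutoff))
  attr(out, "cutoff") <- cutoff
  class(out) <- c("fc_screen", "data.frame")
  out
}

#' Agreement between the fold-change and CV screens
#'
#' For each list size n, counts how many fold-change-retained genes also sit
#' within the top n of the CV ranking, and reports the worst (largest) CV
#' rank among the retained genes.
#'
#' @param fc an `fc_screen` table from [foldchange_screen].
#' @param cv a `stability_table` from [stability_cv].
#' @param n_list integer vector of CV list sizes (default `c(50, 200)`).
#' @return list with `overlap` (data.frame `n`, `overlap`), `max_cv_rank`,
#'   and `retained_genes`.
#' @export
method_concordance <- function(fc, cv, n_list = c(50, 200)) {
  stopifnot(inherits(fc, "fc_screen"), inherits(cv, "stability_table"))
  if (!length(intersect(fc$gene_id, cv$gene_id)))
    stop_refstab("fold-change and CV tables share no genes")
  kept <- fc$gene_id[fc$retained]
  ranks <- cv$rank[match(kept, cv$gene_id)]
  if (anyNA(ranks))
    stop_refstab("retained gene(s) missing from CV ranking: %s",
                 paste(kept[is.na(ranks)], collapse = ", "))
  list(overlap = data.frame(n = n_list,
                            overlap = vapply(n_list, function(n) sum(ranks <= n),
                                             integer(1))),
       max_cv_rank = if (length(ranks)) max(ranks) else NA_integer_,
       retained_genes = kept)
}
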