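#' Gene-by-sample expression matrix with sample metadata
#'
#' The central data container: a numeric gene x sample matrix of non-negative
#' abundances together with per-sample metadata (species, tissue, batch and,
#' optionally, library size) and a unit tag, either `"FPKM"` or `"COUNTS"`.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row names
#'   are gene identifiers and must be unique; column names are sample ids.
#' @param samples data.frame of sample metadata with columns `sample_id`,
#'   `species`, `tissue`, `batch` and optionally `library_size`. One row per
#'   column of `values`, matched by `sample_id`.
#' @param unit `"FPKM"` or `"COUNTS"`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `samples` and `unit`.
#' @examples
#' vals <- matrix(c(10, 20, 5, 8, 12, 6), nrow = 3,
#'                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"), species = "mimulus",
#'                    tissue = c("leaf", "stem"), batch = "T1")
#' m <- expr_matrix(vals, meta, unit = "FPKM")
#' dim(m)
#' @export
expr_matrix <- function(values, samples, unit = c("FPKM", "COUNTS")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop_refstab("'values' must be a numeric matrix")
  if (is.null(rownames(values)) && nrow(values) > 0)
    stop_refstab("'values' must carry gene ids as row names")
  if (is.null(colnames(values)) && ncol(values) > 0)
    stop_refstab("'values' must carry sample ids as column names")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  obj <- structure(list(values = values, samples = samples, unit = unit),
                   class = "expr_matrix")
  validate_expr_matrix(obj)
  if (!identical(colnames(values), as.character(samples$sample_id))) {
    # align metadata rows with matrix column order (order comes from the file)
    obj$samples <- samples[match(colnames(values), samples$sample_id), ,
                           drop = FALSE]
    rownames(obj$samples) <- NULL
  }
  obj
}

validate_expr_matrix <- function(m) {
  v <- m$values
  s <- m$samples
  dup <- rownames(v)[duplicated(rownames(v))]
  if (length(dup))
    stop_refstab("duplicate gene id(s): %s", paste(unique(dup), collapse = ", "))
  if (anyNA(v))
    stop_refstab("expression matrix contains missing values")
  if (any(v < 0))
    stop_refstab("expression matrix contains negative values")
  need <- c("sample_id", "species", "tissue", "batch")
  miss <- setdiff(need, names(s))
  if (length(miss))
    stop_refstab("sample metadata lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(s$sample_id))
    stop_refstab("duplicate sample_id in metadata")
  if (any(!nzchar(as.character(s$tissue))) || any(!nzchar(as.character(s$batch))))
    stop_refstab("tissue and batch must be non-empty for every sample")
  absent <- setdiff(colnames(v), s$sample_id)
  if (length(absent))
    stop_refstab("no metadata for sample column(s): %s", paste(absent, collapse = ", "))
  invisible(m)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  tab <- table(x$samples$tissue, x$samples$batch)
  cat("samples per tissue x batch:\n")
  print(tab)
  invisible(x)
}

#' Subset an expression matrix by genes and/or samples
#'
#' @param x an [expr_matrix].
#' @param genes,samples character vectors of ids to keep (default: all).
#' @return An `expr_matrix` restricted to the requested rows/columns, with
#'   metadata subset accordingly.
#' @export
subset_expr <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (!is.null(genes)) {
    bad <- setdiff(genes, rownames(v))
    if (length(bad))
      stop_refstab("gene id(s) not in matrix: %s", paste(bad, collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  s <- x$samples
  if (!is.null(samples)) {
    bad <- setdiff(samples, colnames(v))
    if (length(bad))
      stop_refstab("sample id(s) not in matrix: %s", paste(bad, collapse = ", "))
    v <- v[, samples, drop = FALSE]
    s <- s[match(samples, s$sample_id), , drop = FALSE]
  }
  expr_matrix(v, s, unit = x$unit)
}

#' Convert raw fragment counts to FPKM
#'
#' FPKM (fragments per kilobase of transcript per million mapped fragments)
#' for gene g in sample s is
#' `count[g,s] / (length[g]/1e3) / (libsize[s]/1e6)`. Library sizes are taken
#' from the sample metadata when present, otherwise from the column sums.
#'
#' @param m an [expr_matrix] with unit `"COUNTS"`.
#' @param gene_lengths named numeric vector of gene lengths in bp covering
#'   every gene in `m`; all lengths must be positive.
#' @param library_sizes optional named numeric vector of per-sample fragment
#'   totals, overriding metadata/column sums.
#' @return An `expr_matrix` with unit `"FPKM"`.
#' @examples
#' vals <- matrix(100, 1, 1, dimnames = list("g1", "s1"))
#' meta <- data.frame(sample_id = "s1", species = "x", tissue = "leaf",
#'                    batch = "T1", library_size = 1e6)
#' m <- expr_matrix(vals, meta, unit = "COUNTS")
#' counts_to_fpkm(m, c(g1 = 1000))$values   # 100 FPKM
#' @export
counts_to_fpkm <- function(m, gene_lengths, library_sizes = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "COUNTS")
    stop_refstab("counts_to_fpkm expects a COUNTS matrix, got %s", m$unit)
  genes <- rownames(m$values)
  miss <- setdiff(genes, names(gene_lengths))
  if (length(miss))
    stop_refstab("missing gene length(s): %s", paste(utils::head(miss, 5), collapse = ", "))
  len <- gene_lengths[genes]
  if (any(len <= 0)) stop_refstab("gene lengths must be positive")
  if (is.null(library_sizes)) {
    if (!is.null(m$samples$library_size) && !anyNA(m$samples$library_size)) {
      library_sizes <- stats::setNames(m$samples$library_size, m$samples$sample_id)
    } else {
      library_sizes <- colSums(m$values)
    }
  }
  lib <- library_sizes[colnames(m$values)]
  if (anyNA(lib) || any(lib <= 0)) stop_refstab("library sizes must be positive for all samples")
  fpkm <- m$values / (len / 1e3)
  fpkm <- sweep(fpkm, 2, lib / 1e6, "/")
  out <- m
  out$values <- fpkm
  out$unit <- "FPKM"
  out
}

#' Average homeolog pairs in a polyploid expression matrix
#'
#' Replaces each homeolog pair by a single row whose per-sample value is the
#' arithmetic mean of the two copies; unpaired genes pass through unchanged.
#' Useful for allopolyploids where the two subgenome copies of a gene are
#' quantified separately.
#'
#' @param m an [expr_matrix].
#' @param map data.frame with columns `gene_a`, `gene_b` and optionally
#'   `group` (label for the merged row; defaults to `"gene_a|gene_b"`). Each
#'   gene may appear in at most one pair and all ids must be present in `m`.
#' @return An `expr_matrix` with one row per pair plus all unpaired genes.
#' @export
average_homeologs <- function(m, map) {
  stopifnot(inherits(m, "expr_matrix"))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (nrow(map) == 0) return(m)
  if (!all(c("gene_a", "gene_b") %in% names(map)))
    stop_refstab("homeolog map needs columns gene_a, gene_b")
  ids <- c(map$gene_a, map$gene_b)
  if (anyDuplicated(ids))
    stop_refstab("gene(s) appear in more than one homeolog pair: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  absent <- setdiff(ids, rownames(m$values))
  if (length(absent))
    stop_refstab("homeolog map id(s) absent from matrix: %s",
                 paste(absent, collapse = ", "))
  lab <- map$group %||% paste(map$gene_a, map$gene_b, sep = "|")
  merged <- (m$values[map$gene_a, , drop = FALSE] +
             m$values[map$gene_b, , drop = FALSE]) / 2
  rownames(merged) <- lab
  keep <- setdiff(rownames(m$values), ids)
  out <- m
  out$values <- rbind(m$values[keep, , drop = FALSE], merged)
  out
}

#' Average two homeologs' stability scores
#'
#' For reporting stability of a homeolog pair as a single number, the CV of
#' each copy is computed separately and the two CVs averaged (as opposed to
#' computing the CV of the averaged expression, which [average_homeologs]
#' enables).
#'
#' @param stab a stability table from [stability_cv].
#' @param map homeolog map as in [average_homeologs].
#' @return data.frame with columns `group`, `gene_a`, `gene_b`, `cv` (mean of
#'   the two copies' CVs).
#' @export
average_homeolog_cv <- function(stab, map) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  idx_a <- match(map$gene_a, stab$gene_id)
  idx_b <- match(map$gene_b, stab$gene_id)
  if (anyNA(idx_a) || anyNA(idx_b))
    stop_refstab("homeolog map id(s) absent from stability table")
  data.frame(group = map$group %||% paste(map$gene_a, map$gene_b, sep = "|"),
             gene_a = map$gene_a, gene_b = map$gene_b,
             cv = (stab$cv[idx_a] + stab$cv[idx_b]) / 2,
             stringsAsFactors = FALSE)
}
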