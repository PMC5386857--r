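# Delimited-text readers/writers for expression matrices, metadata,
# homeolog maps and qPCR tables. Only tab and comma dialects are accepted;
# a header line containing both is rejected rather than guessed.

detect_delim <- function(path) {
  if (!file.exists(path)) stop_refstab("file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop_refstab("empty file: %s", path)
  n_tab <- lengths(regmatches(first, gregexpr("\t", first)))
  n_com <- lengths(regmatches(first, gregexpr(",", first)))
  if (n_tab > 0 && n_com == 0) return("\t")
  if (n_com > 0 && n_tab == 0) return(",")
  stop_refstab("cannot determine delimiter of %s (found %d tabs and %d commas in header); use a pure TSV or CSV",
               path, n_tab, n_com)
}

read_delim_checked <- function(path) {
  sep <- detect_delim(path)
  utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#",
                    colClasses = "character", quote = "\"")
}

#' Read an expression matrix and its sample metadata from delimited text
#'
#' The matrix file has the gene identifier in its first column and one column
#' per sample; the metadata file has columns `sample_id`, `species`, `tissue`,
#' `batch` and optionally `library_size`, covering every sample column of the
#' matrix. Tab- and comma-delimited files are auto-detected; mixed dialects
#' are rejected.
#'
#' @param path matrix file.
#' @param meta_path sample metadata file.
#' @param unit `"FPKM"` or `"COUNTS"`.
#' @return An [expr_matrix] with sample order as in the matrix file.
#' @export
read_expression_matrix <- function(path, meta_path, unit = c("FPKM", "COUNTS")) {
  unit <- match.arg(unit)
  raw <- read_delim_checked(path)
  if (ncol(raw) < 2)
    stop_refstab("matrix file %s needs a gene id column plus at least one sample", path)
  gene_ids <- raw[[1]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop_refstab("duplicate gene id(s) in %s: %s", path, paste(dup, collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(gene_ids, colnames(vals))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop_refstab("non-numeric or missing value at gene '%s', sample '%s' in %s",
                 gene_ids[bad[1]], colnames(num)[bad[2]], path)
  }
  meta <- read_sample_meta(meta_path)
  expr_matrix(num, meta, unit = unit)
}

#' Read a sample metadata table
#'
#' @param path delimited file with columns `sample_id`, `species`, `tissue`,
#'   `batch` and optionally `library_size`.
#' @return data.frame of sample metadata.
#' @export
read_sample_meta <- function(path) {
  meta <- read_delim_checked(path)
  need <- c("sample_id", "species", "tissue", "batch")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop_refstab("metadata %s lacks column(s): %s", path, paste(miss, collapse = ", "))
  if ("library_size" %in% names(meta))
    meta$library_size <- as.numeric(meta$library_size)
  meta
}

#' Write an expression matrix and its metadata to delimited text
#'
#' @param m an [expr_matrix].
#' @param path output matrix file.
#' @param meta_path optional output metadata file.
#' @param sep field delimiter (tab by default).
#' @param digits significant digits for numeric formatting; `NA` writes full
#'   precision (up to 17 significant digits, round-trip safe).
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(m, path, meta_path = NULL, sep = "\t",
                                    digits = NA) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- m$values
  fmt <- if (is.na(digits)) format(v, digits = 17, trim = TRUE, scientific = FALSE)
         else format(v, digits = digits, trim = TRUE)
  out <- data.frame(gene_id = rownames(v), fmt, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out) <- c("gene_id", colnames(v))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.table(m$samples, meta_path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read a homeolog pairing table
#'
#' @param path delimited file whose first two columns are the paired gene
#'   ids (a `group` column is carried through if present).
#' @return data.frame with columns `gene_a`, `gene_b` and optionally `group`.
#' @export
read_homeolog_map <- function(path) {
  map <- read_delim_checked(path)
  if (ncol(map) < 2)
    stop_refstab("homeolog map %s needs two id columns", path)
  names(map)[1:2] <- c("gene_a", "gene_b")
  map[, intersect(c("gene_a", "gene_b", "group"), names(map)), drop = FALSE]
}

#' Read a long-format Cq table
#'
#' @param path delimited file with columns `gene`, `species`, `tissue`,
#'   `bio_rep`, `tech_rep`, `cq` and optionally `run_id`.
#' @return data.frame with `cq` numeric.
#' @export
read_cq_table <- function(path) {
  cq <- read_delim_checked(path)
  need <- c("gene", "species", "tissue", "bio_rep", "tech_rep", "cq")
  miss <- setdiff(need, names(cq))
  if (length(miss))
    stop_refstab("Cq table %s lacks column(s): %s", path, paste(miss, collapse = ", "))
  cq$cq <- as.numeric(cq$cq)
  if (anyNA(cq$cq)) stop_refstab("non-numeric Cq value(s) in %s", path)
  cq
}

#' Read per-gene amplification efficiencies
#'
#' @param path delimited file with columns `gene` and `efficiency` (base E,
#'   around 1.6-2.1; 2.0 means perfect doubling).
#' @return named numeric vector of efficiencies.
#' @export
read_efficiencies <- function(path) {
  eff <- read_delim_checked(path)
  if (!all(c("gene", "efficiency") %in% names(eff)))
    stop_refstab("efficiency table %s needs columns gene, efficiency", path)
  stats::setNames(as.numeric(eff$efficiency), eff$gene)
}

#' Read a dilution-series Cq table
#'
#' @param path delimited file with columns `gene`, `dilution` (relative
#'   concentration, e.g. 0.25 for a 1:4 dilution) and `cq`.
#' @return data.frame with numeric `dilution` and `cq`.
#' @export
read_dilution_series <- function(path) {
  d <- read_delim_checked(path)
  if (!all(c("gene", "dilution", "cq") %in% names(d)))
    stop_refstab("dilution table %s needs columns gene, dilution, cq", path)
  d$dilution <- as.numeric(d$dilution)
  d$cq <- as.numeric(d$cq)
  d
}
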