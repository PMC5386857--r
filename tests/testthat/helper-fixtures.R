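# Fixture builders shared across the test files. All data is generated in
# code; nothing is read from disk except files the tests themselves write.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Quick expr_matrix from a numeric matrix; metadata invented to match.
make_em <- function(values, unit = "FPKM",
                    tissues = NULL, batches = NULL, species = "sp") {
  ns <- ncol(values)
  dimnames(values) <- list(
    rownames(values) %||% sprintf("g%d", seq_len(nrow(values))),
    colnames(values) %||% sprintf("s%d", seq_len(ns)))
  if (is.null(tissues)) tissues <- rep_len(c("leaf", "stem", "petal", "calyx"), ns)
  if (is.null(batches)) batches <- rep_len(c("T1", "T2"), ns)
  meta <- data.frame(sample_id = colnames(values), species = species,
                     tissue = tissues, batch = batches,
                     stringsAsFactors = FALSE)
  expr_matrix(values, meta, unit = unit)
}

# 4 tissues x 2 batches layout: tissue varies slow, batch fast -> recycle
# per-column so the standard 8-sample design is tissue i in both batches.
make_em8 <- function(values, unit = "FPKM") {
  stopifnot(ncol(values) == 8)
  make_em(values, unit = unit,
          tissues = rep(c("leaf", "stem", "petal", "calyx"), each = 2),
          batches = rep(c("T1", "T2"), 4))
}

# Random non-negative FPKM-like matrix.
rand_mat <- function(ng, ns, seed = 1, min = 5, max = 500) {
  set.seed(seed)
  matrix(runif(ng * ns, min, max), ng, ns,
         dimnames = list(sprintf("g%03d", seq_len(ng)),
                         paste0("s", seq_len(ns))))
}

# Independent oracles: direct per-gene formula evaluation with plain loops.
oracle_cv <- function(values) {
  out <- numeric(nrow(values))
  for (i in seq_len(nrow(values))) {
    x <- values[i, ]
    m <- sum(x) / length(x)
    s <- sqrt(sum((x - m)^2) / (length(x) - 1))
    out[i] <- s / m
  }
  names(out) <- rownames(values)
  out
}

oracle_max_abs_logfc <- function(values, pseudocount) {
  out <- numeric(nrow(values))
  for (g in seq_len(nrow(values))) {
    best <- 0
    for (i in seq_len(ncol(values) - 1)) {
      for (j in (i + 1):ncol(values)) {
        lfc <- abs(log2((values[g, i] + pseudocount) /
                        (values[g, j] + pseudocount)))
        if (lfc > best) best <- lfc
      }
    }
    out[g] <- best
  }
  names(out) <- rownames(values)
  out
}

write_tsv_tmp <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, paste0("t", as.integer(stats::runif(1, 1, 1e8)), ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
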