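# Pipeline driver: YAML/list config in, TSV tables with provenance headers
# out. Every threshold in the outputs is traceable to the config; results go
# to files, log messages to stderr.

#' Write a table with a provenance header
#'
#' Prepends `#`-prefixed lines recording the package version, a hash of the
#' configuration that produced the table, the seed, and a timestamp, then the
#' TSV body. Readers in this package skip `#` lines.
#'
#' @param x data.frame.
#' @param path output file.
#' @param config the configuration list the run used (hashed, not printed).
#' @param seed integer seed recorded in the header (or `NA`).
#' @return Invisibly, `path`.
#' @export
write_report_table <- function(x, path, config = list(), seed = NA) {
  cfg_hash <- fnv1a32(deparse(config))
  hdr <- c(sprintf("# refstab %s", as.character(utils::packageVersion("refstab"))),
           sprintf("# config_hash %s", cfg_hash),
           sprintf("# seed %s", as.character(seed)),
           sprintf("# written %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_report_table]
#'
#' @param path file path.
#' @return data.frame (provenance lines skipped).
#' @export
read_report_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

default_pipeline_config <- function() {
  list(min_expression = 5, cv_cutoff = 0.5, top_n = 50, fc_cutoff = 0.4,
       normalize = "none", pseudocount = 0.5, seed = 1)
}

#' Run the full reference-gene selection pipeline from a config
#'
#' Stages: read (or simulate) the expression matrix, minimum-expression
#' filter, CV screen, fold-change screen, optional qPCR validation arm,
#' optional cross-batch concordance, and the combined candidate report. All
#' tables are written to `out_dir` with provenance headers. Stage failures
#' propagate with the stage name prefixed.
#'
#' Config keys (YAML file or list): `matrix`, `meta` (paths; or `simulate:`
#' with [sim_config] fields), `unit`, `gene_lengths` (path, for counts),
#' `homeolog_map` (path), `min_expression`, `cv_cutoff`, `top_n`,
#' `fc_cutoff`, `normalize`, `pseudocount`, `seed`, and optionally `qpcr:`
#' (`cq`, `efficiencies` paths, `calibrator` as `species:tissue:bio_rep`,
#' `exclude_tissues`) and `concordance: {metric, min_mean_fpkm}` comparing
#' the batches of the input matrix.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir directory for output tables (created if needed).
#' @return Invisibly, a list with the `ref_screen` fit, the qPCR CV table (if
#'   run), concordance reports (if run), and the paths written.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_refstab("stage %s: %s", name, conditionMessage(e)))
  }

  gene_lengths <- NULL
  if (!is.null(cfg$simulate)) {
    message("simulating expression data")
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    scfg <- stage("simulate", do.call(sim_config, sim_args))
    sim <- stage("simulate", simulate_expression(scfg))
    m <- sim$counts
    gene_lengths <- sim$gene_lengths
    truth_df <- data.frame(gene_id = sim$truth$stable_gene_ids)
    p <- file.path(out_dir, "truth_stable_genes.tsv")
    write_report_table(truth_df, p, cfg, cfg$seed); paths <- c(paths, p)
  } else {
    if (is.null(cfg$matrix) || is.null(cfg$meta))
      stop_refstab("config needs either 'simulate' or 'matrix' + 'meta'")
    m <- stage("read", read_expression_matrix(cfg$matrix, cfg$meta,
                                              unit = cfg$unit %||% "FPKM"))
    if (!is.null(cfg$gene_lengths)) {
      gl <- read_delim_checked(cfg$gene_lengths)
      gene_lengths <- stats::setNames(as.numeric(gl[[2]]), gl[[1]])
    }
  }
  hmap <- if (!is.null(cfg$homeolog_map)) stage("read", read_homeolog_map(cfg$homeolog_map))

  fit <- stage("screen", screen_reference_genes(
    m, min_expression = cfg$min_expression, cv_cutoff = cfg$cv_cutoff,
    top_n = cfg$top_n, fc_cutoff = cfg$fc_cutoff,
    normalize = cfg$normalize, pseudocount = cfg$pseudocount,
    gene_lengths = gene_lengths, homeolog_map = hmap))

  p <- file.path(out_dir, "stability.tsv")
  write_report_table(fit$stability, p, cfg, cfg$seed); paths <- c(paths, p)
  p <- file.path(out_dir, "fc_screen.tsv")
  write_report_table(fit$fc, p, cfg, cfg$seed); paths <- c(paths, p)

  qpcr_tab <- NULL
  if (!is.null(cfg$qpcr)) {
    qc <- cfg$qpcr
    cq <- stage("qpcr", read_cq_table(qc$cq))
    eff <- stage("qpcr", read_efficiencies(qc$efficiencies))
    cal <- qc$calibrator
    if (is.character(cal) && length(cal) == 1) {
      parts <- strsplit(cal, ":", fixed = TRUE)[[1]]
      if (length(parts) != 3)
        stop_refstab("stage qpcr: calibrator must be species:tissue:bio_rep")
      cal <- list(species = parts[1], tissue = parts[2], bio_rep = parts[3])
    }
    collapsed <- stage("qpcr", collapse_tech_reps(cq))
    cal$bio_rep <- utils::type.convert(as.character(cal$bio_rep), as.is = TRUE)
    rel <- stage("qpcr", relative_expression(collapsed, eff, cal))
    qpcr_tab <- stage("qpcr", qpcr_cv(rel, exclude_tissues = qc$exclude_tissues))
    p <- file.path(out_dir, "qpcr_cv.tsv")
    write_report_table(qpcr_tab, p, cfg, cfg$seed); paths <- c(paths, p)
    qv <- stats::setNames(qpcr_tab$cv, qpcr_tab$gene)
    common <- intersect(names(qv), fit$report$gene_id)
    fit$report$qpcr_cv[match(common, fit$report$gene_id)] <- qv[common]
  }

  conc <- NULL
  if (!is.null(cfg$concordance)) {
    cc <- cfg$concordance
    batches <- unique(m$samples$batch)
    if (length(batches) >= 2) {
      a <- subset_expr(m, samples = m$samples$sample_id[m$samples$batch == batches[1]])
      b <- subset_expr(m, samples = m$samples$sample_id[m$samples$batch == batches[2]])
      if (a$unit == "COUNTS") {
        a <- counts_to_fpkm(a, gene_lengths); b <- counts_to_fpkm(b, gene_lengths)
      }
      metrics <- cc$metric %||% c("mean", "cv")
      conc <- lapply(metrics, function(mt)
        stage("concordance",
              replicate_concordance(a, b, metric = mt,
                                    min_mean_fpkm = cc$min_mean_fpkm %||% 1)))
      names(conc) <- metrics
      conc_df <- do.call(rbind, lapply(conc, function(r)
        data.frame(metric = r$metric, source_a = batches[1], source_b = batches[2],
                   n_genes = r$n_genes, pearson_r = r$pearson_r,
                   p_value = r$p_value, stringsAsFactors = FALSE)))
      p <- file.path(out_dir, "concordance.tsv")
      write_report_table(conc_df, p, cfg, cfg$seed); paths <- c(paths, p)
    }
  }

  p <- file.path(out_dir, "candidate_report.tsv")
  write_report_table(fit$report, p, cfg, cfg$seed); paths <- c(paths, p)
  message(sprintf("pipeline complete: %d tables under %s", length(paths), out_dir))
  invisible(list(fit = fit, qpcr = qpcr_tab, concordance = conc, paths = paths))
}
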