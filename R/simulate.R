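#' Configuration for the synthetic study generator
#'
#' Describes a simulated multi-tissue, two-batch expression study mirroring
#' the design the screens are meant for: 4 tissue types sampled in each of 2
#' biological-replicate batches, negative-binomial fragment counts with
#' gene-specific tissue effects and dispersions, a designated subset of truly
#' stable genes, and a matched qPCR arm (Cq values consistent with the
#' simulated expression under per-gene amplification efficiencies plus
#' technical noise).
#'
#' Batch effects act multiplicatively on the per-gene noise SD of the second
#' batch rather than on the means (`batch_variance_inflation`), so raising
#' the inflation perturbs expression variability while leaving expression
#' levels essentially unchanged.
#'
#' @param n_genes number of genes (default 5000).
#' @param n_stable number of designated truly stable genes (default 50).
#' @param tissues tissue types (default leaf, stem, petal, calyx).
#' @param batches batch labels (default T1, T2).
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @param baseline_log2_range range of per-gene baseline log2 relative
#'   abundance.
#' @param tissue_effect_sd_unstable SD (log2) of per-tissue effects for
#'   ordinary genes.
#' @param tissue_effect_sd_stable SD (log2) of per-tissue effects for the
#'   stable subset (near 0).
#' @param dispersion_range negative-binomial dispersion range for ordinary
#'   genes (counts ~ NB with variance mu + dispersion * mu^2).
#' @param dispersion_stable dispersion for stable genes (minimal).
#' @param sample_noise_sd per-sample lognormal noise SD (log2 scale).
#' @param batch_variance_inflation multiplier (>= 1) applied to
#'   `sample_noise_sd` in every batch after the first.
#' @param gene_length_range transcript length range in bp.
#' @param library_size_range per-sample total fragment range.
#' @param duplicate_leaf add a second leaf sample to the last batch (the
#'   asymmetric 9th sample some designs carry).
#' @param qpcr list of qPCR-arm settings: `n_genes` assayed (drawn half from
#'   the stable subset), `efficiency_range` (base E), `cq_noise_sd` (cycles),
#'   `n_bio_reps`, `n_tech_reps`, `calibrator_cq` (Cq of the calibrator
#'   sample), `calibrator_tissue`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000, n_stable = 50,
                       tissues = c("leaf", "stem", "petal", "calyx"),
                       batches = c("T1", "T2"),
                       seed = 1,
                       baseline_log2_range = c(2, 9),
                       tissue_effect_sd_unstable = 0.8,
                       tissue_effect_sd_stable = 0.02,
                       dispersion_range = c(0.02, 0.4),
                       dispersion_stable = 0.005,
                       sample_noise_sd = 0.15,
                       batch_variance_inflation = 1,
                       gene_length_range = c(500, 3000),
                       library_size_range = c(8e6, 12e6),
                       duplicate_leaf = FALSE,
                       qpcr = list()) {
  qpcr_defaults <- list(n_genes = 8, efficiency_range = c(1.8, 2.05),
                        cq_noise_sd = 0.15, n_bio_reps = 4, n_tech_reps = 3,
                        calibrator_cq = 20, calibrator_tissue = "leaf")
  qpcr <- utils::modifyList(qpcr_defaults, qpcr)
  cfg <- structure(list(n_genes = n_genes, n_stable = n_stable,
                        tissues = tissues, batches = batches, seed = seed,
                        baseline_log2_range = baseline_log2_range,
                        tissue_effect_sd_unstable = tissue_effect_sd_unstable,
                        tissue_effect_sd_stable = tissue_effect_sd_stable,
                        dispersion_range = dispersion_range,
                        dispersion_stable = dispersion_stable,
                        sample_noise_sd = sample_noise_sd,
                        batch_variance_inflation = batch_variance_inflation,
                        gene_length_range = gene_length_range,
                        library_size_range = library_size_range,
                        duplicate_leaf = duplicate_leaf,
                        qpcr = qpcr),
                   class = "sim_config")
  if (n_genes < 1 || length(tissues) < 1 || length(batches) < 1)
    stop_refstab("degenerate config: need >= 1 gene, tissue and batch")
  if (n_stable > n_genes) stop_refstab("n_stable exceeds n_genes")
  if (tissue_effect_sd_unstable < 0 || tissue_effect_sd_stable < 0 ||
      sample_noise_sd < 0 || qpcr$cq_noise_sd < 0)
    stop_refstab("noise SDs must be >= 0")
  if (batch_variance_inflation < 1)
    stop_refstab("batch_variance_inflation must be >= 1")
  cfg
}

#' Simulate a multi-tissue, multi-batch count matrix with known truth
#'
#' Per gene g and sample s (a tissue x batch combination), fragment counts
#' are drawn as `NB(mean = mu[g,s], dispersion)` where
#' `log2 mu = baseline_g + tissue_effect_{g,t} + noise_{g,s}` is scaled to
#' the sample's library size, and `noise` has SD
#' `sample_noise_sd * batch_variance_inflation^(batch index - 1)`.
#' Designated stable genes get near-zero tissue effects and minimal
#' dispersion, so their expression is genuinely stable across all samples.
#'
#' @param cfg a [sim_config].
#' @return list with `counts` (an [expr_matrix] of unit COUNTS),
#'   `gene_lengths` (named vector, bp), and `truth` (list: `stable_gene_ids`,
#'   `baseline_log2`, `tissue_effects` gene x tissue matrix (log2),
#'   `dispersions`).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ng <- cfg$n_genes
  genes <- sprintf("gene%05d", seq_len(ng))
  stable <- sort(sample(genes, cfg$n_stable))
  is_stable <- genes %in% stable

  baseline <- stats::runif(ng, cfg$baseline_log2_range[1], cfg$baseline_log2_range[2])
  # stable genes kept comfortably expressed so they survive the 5-FPKM filter
  baseline[is_stable] <- stats::runif(sum(is_stable),
                                      mean(cfg$baseline_log2_range),
                                      cfg$baseline_log2_range[2])
  nt <- length(cfg$tissues)
  tissue_sd <- ifelse(is_stable, cfg$tissue_effect_sd_stable,
                      cfg$tissue_effect_sd_unstable)
  tissue_eff <- matrix(stats::rnorm(ng * nt, 0, rep(tissue_sd, nt)),
                       nrow = ng, dimnames = list(genes, cfg$tissues))
  disp <- stats::runif(ng, cfg$dispersion_range[1], cfg$dispersion_range[2])
  disp[is_stable] <- cfg$dispersion_stable
  lengths <- stats::setNames(
    round(stats::runif(ng, cfg$gene_length_range[1], cfg$gene_length_range[2])),
    genes)

  design <- expand.grid(tissue = cfg$tissues, batch = cfg$batches,
                        stringsAsFactors = FALSE)
  if (cfg$duplicate_leaf)
    design <- rbind(design, data.frame(tissue = cfg$tissues[1],
                                       batch = cfg$batches[length(cfg$batches)]))
  ns <- nrow(design)
  sample_ids <- make.unique(paste(design$tissue, design$batch, sep = "_"))
  libsize <- round(stats::runif(ns, cfg$library_size_range[1],
                                cfg$library_size_range[2]))

  counts <- matrix(0L, ng, ns, dimnames = list(genes, sample_ids))
  for (s in seq_len(ns)) {
    bi <- match(design$batch[s], cfg$batches)
    noise_sd <- cfg$sample_noise_sd * cfg$batch_variance_inflation^(bi - 1)
    log2_expr <- baseline + tissue_eff[, design$tissue[s]] +
      stats::rnorm(ng, 0, noise_sd)
    rel <- 2^log2_expr
    mu <- rel / sum(rel) * libsize[s]
    counts[, s] <- stats::rnbinom(ng, mu = mu, size = 1 / disp)
  }
  meta <- data.frame(sample_id = sample_ids, species = "sim",
                     tissue = design$tissue, batch = design$batch,
                     library_size = colSums(counts),
                     stringsAsFactors = FALSE)
  list(counts = expr_matrix(counts, meta, unit = "COUNTS"),
       gene_lengths = lengths,
       truth = list(stable_gene_ids = stable, baseline_log2 = baseline,
                    tissue_effects = tissue_eff, dispersions = disp))
}

#' Simulate a matched qPCR arm (Cq tables and dilution series)
#'
#' Picks a panel of assayed genes (half from the designated stable subset,
#' half from the rest), assigns each a true amplification efficiency E, and
#' generates Cq values consistent with the simulated expression:
#' `Cq = calibrator_cq - log_E(expr / anchor) + N(0, cq_noise_sd)`, where the
#' anchor is the interplate-calibrator gene's expression in the calibrator
#' tissue — one global reference, so Cq carries absolute abundance
#' differences between genes, as on a real instrument. The configured number
#' of technical replicates per biological sample and biological replicates
#' per tissue are generated. A noisy 1:4 dilution series
#' (relative concentrations 1 down to 1/1024) is generated per gene from its
#' true E. At `cq_noise_sd = 0`, [relative_expression] on the generated Cq
#' values recovers the expression ratios exactly and [fit_efficiency]
#' recovers E exactly.
#'
#' @param sim output of [simulate_expression].
#' @param cfg the same [sim_config].
#' @return list with `cq` (long data.frame: gene, species, tissue, bio_rep,
#'   tech_rep, cq), `efficiencies` (named vector of true E), `calibrator`
#'   (list species/tissue/bio_rep), `calibrator_gene` (the anchor gene),
#'   `dilution` (data.frame gene, dilution, cq), `expr_tissue` (true
#'   per-gene, per-tissue expression used), `genes` (assayed panel).
#' @export
simulate_cq <- function(sim, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  q <- cfg$qpcr
  truth <- sim$truth
  n_half <- q$n_genes %/% 2
  stable_pick <- sample(truth$stable_gene_ids, min(n_half, length(truth$stable_gene_ids)))
  others <- setdiff(rownames(sim$counts$values), truth$stable_gene_ids)
  other_pick <- sample(others, q$n_genes - length(stable_pick))
  panel <- c(stable_pick, other_pick)

  # true expression per (gene, tissue): expected relative abundance;
  # baseline_log2 is parallel to the gene universe (tissue_effects rownames)
  expr_tissue <- 2^(truth$baseline_log2[match(panel, rownames(truth$tissue_effects))] +
                    truth$tissue_effects[panel, , drop = FALSE])
  rownames(expr_tissue) <- panel

  eff <- stats::setNames(stats::runif(q$n_genes, q$efficiency_range[1],
                                      q$efficiency_range[2]), panel)
  cal_tissue <- q$calibrator_tissue
  if (!cal_tissue %in% cfg$tissues)
    stop_refstab("calibrator tissue '%s' not simulated", cal_tissue)

  grid <- expand.grid(gene = panel, tissue = cfg$tissues,
                      bio_rep = seq_len(q$n_bio_reps),
                      tech_rep = seq_len(q$n_tech_reps),
                      stringsAsFactors = FALSE)
  expr <- expr_tissue[cbind(grid$gene, grid$tissue)]
  if (any(expr == 0)) {
    warning("gene(s) with zero expression: Cq capped at the 40-cycle ceiling")
  }
  # Cq anchored to one interplate calibrator (first panel gene in the
  # calibrator tissue), so Cq reflects absolute abundance across genes:
  # a weakly expressed gene sits at high Cq in every tissue.
  cal_gene <- panel[1]
  anchor <- expr_tissue[cal_gene, cal_tissue]
  cq_true <- q$calibrator_cq - log(expr / anchor, base = eff[grid$gene])
  cq <- cq_true + stats::rnorm(nrow(grid), 0, q$cq_noise_sd)
  cq[!is.finite(cq) | cq > 40] <- 40
  cq_df <- data.frame(gene = grid$gene, species = "sim", tissue = grid$tissue,
                      bio_rep = grid$bio_rep, tech_rep = grid$tech_rep,
                      cq = cq, stringsAsFactors = FALSE)

  dil <- 4^-(0:5)
  dseries <- do.call(rbind, lapply(panel, function(g) {
    slope <- -1 / log10(eff[g])
    data.frame(gene = g, dilution = dil,
               cq = q$calibrator_cq + slope * log10(dil) +
                 stats::rnorm(length(dil), 0, q$cq_noise_sd),
               stringsAsFactors = FALSE)
  }))
  rownames(dseries) <- NULL

  list(cq = cq_df, efficiencies = eff,
       calibrator = list(species = "sim", tissue = cal_tissue, bio_rep = 1),
       calibrator_gene = cal_gene,
       dilution = dseries, expr_tissue = expr_tissue, genes = panel)
}
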