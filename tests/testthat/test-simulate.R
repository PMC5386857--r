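cfg_small <- function(...) {
  sim_config(n_genes = 600, n_stable = 20, seed = 101, ...)
}

test_that("the generator is deterministic under a fixed seed", {
  s1 <- simulate_expression(cfg_small())
  s2 <- simulate_expression(cfg_small())
  expect_identical(s1$counts$values, s2$counts$values)
  expect_identical(s1$truth$stable_gene_ids, s2$truth$stable_gene_ids)
  q1 <- simulate_cq(s1, cfg_small())
  q2 <- simulate_cq(s2, cfg_small())
  expect_identical(q1$cq, q2$cq)
  expect_identical(q1$dilution, q2$dilution)
  s3 <- simulate_expression(sim_config(n_genes = 600, n_stable = 20, seed = 102))
  expect_false(identical(s1$counts$values, s3$counts$values))
})

test_that("designated stable genes have lower CV than the rest", {
  sim <- simulate_expression(cfg_small())
  fpkm <- counts_to_fpkm(sim$counts, sim$gene_lengths)
  st <- gene_stats(fpkm)
  is_stable <- st$gene_id %in% sim$truth$stable_gene_ids
  expect_lt(mean(st$cv[is_stable]), mean(st$cv[!is_stable]))
  expect_lt(mean(st$cv[is_stable]), 0.15)
})

test_that("the noiseless limit collapses stable-gene CV toward zero", {
  cfg <- sim_config(n_genes = 300, n_stable = 15, seed = 7,
                    tissue_effect_sd_stable = 0, dispersion_stable = 1e-8,
                    sample_noise_sd = 0,
                    library_size_range = c(1e7, 1e7))
  sim <- simulate_expression(cfg)
  fpkm <- counts_to_fpkm(sim$counts, sim$gene_lengths)
  st <- gene_stats(fpkm)
  stable_cv <- st$cv[st$gene_id %in% sim$truth$stable_gene_ids]
  expect_lt(max(stable_cv), 0.05)
})

test_that("the expression design matches the configured layout", {
  cfg <- cfg_small()
  sim <- simulate_expression(cfg)
  expect_equal(dim(sim$counts), c(600L, 8L))
  expect_identical(sim$counts$unit, "COUNTS")
  tab <- table(sim$counts$samples$tissue, sim$counts$samples$batch)
  expect_true(all(tab == 1))
  # optional duplicated leaf sample in the last batch (9th column)
  sim9 <- simulate_expression(sim_config(n_genes = 100, n_stable = 5,
                                         seed = 3, duplicate_leaf = TRUE))
  expect_equal(ncol(sim9$counts$values), 9L)
  expect_equal(sum(sim9$counts$samples$tissue == "leaf" &
                   sim9$counts$samples$batch == "T2"), 2L)
})

test_that("zero-noise Cq inverts through relative_expression exactly", {
  cfg <- sim_config(n_genes = 300, n_stable = 15, seed = 19,
                    qpcr = list(cq_noise_sd = 0))
  sim <- simulate_expression(cfg)
  qsim <- simulate_cq(sim, cfg)
  collapsed <- collapse_tech_reps(qsim$cq)
  rel <- relative_expression(collapsed, qsim$efficiencies, qsim$calibrator)
  cal_t <- cfg$qpcr$calibrator_tissue
  for (g in qsim$genes) {
    want <- qsim$expr_tissue[g, ] / qsim$expr_tissue[g, cal_t]
    got <- rel$rel_expr[rel$gene == g][match(colnames(qsim$expr_tissue),
                                             rel$tissue[rel$gene == g])]
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})

test_that("an injected aberrant technical replicate is the one dropped", {
  cfg <- sim_config(n_genes = 300, n_stable = 15, seed = 19,
                    qpcr = list(cq_noise_sd = 0.05))
  sim <- simulate_expression(cfg)
  qsim <- simulate_cq(sim, cfg)
  cq <- qsim$cq
  idx <- which(cq$gene == qsim$genes[1] & cq$tissue == "stem" &
               cq$bio_rep == 2 & cq$tech_rep == 2)
  cq$cq[idx] <- cq$cq[idx] + 3
  collapsed <- collapse_tech_reps(cq)
  row <- collapsed[collapsed$gene == qsim$genes[1] &
                   collapsed$tissue == "stem" & collapsed$bio_rep == 2, ]
  expect_equal(row$dropped_rep, 2L)
})

test_that("noiseless dilution series round-trips the true efficiency", {
  cfg <- sim_config(n_genes = 200, n_stable = 10, seed = 5,
                    qpcr = list(cq_noise_sd = 0,
                                efficiency_range = c(1.9, 1.9)))
  sim <- simulate_expression(cfg)
  qsim <- simulate_cq(sim, cfg)
  d1 <- qsim$dilution[qsim$dilution$gene == qsim$genes[1], ]
  expect_equal(fit_efficiency(d1$dilution, d1$cq)$efficiency, 1.9,
               tolerance = 1e-9)
})

test_that("stable genes are hypergeometrically enriched in both screens", {
  cfg <- sim_config(seed = 2026)            # default study design: 5000 x 50
  sim <- simulate_expression(cfg)
  fit <- screen_reference_genes(sim$counts, gene_lengths = sim$gene_lengths)
  stable <- sim$truth$stable_gene_ids
  universe <- fit$report$gene_id
  stable_in_univ <- intersect(stable, universe)

  top50 <- fit$report$gene_id[!is.na(fit$report$cv_rank) & fit$report$cv_rank <= 50]
  k_cv <- length(intersect(top50, stable))
  p_cv <- phyper(k_cv - 1, length(stable_in_univ),
                 length(universe) - length(stable_in_univ), length(top50),
                 lower.tail = FALSE)
  expect_lt(p_cv, 0.01)

  fc_kept <- fit$fc$gene_id[fit$fc$retained]
  k_fc <- length(intersect(fc_kept, stable))
  p_fc <- phyper(k_fc - 1, length(stable_in_univ),
                 length(universe) - length(stable_in_univ), length(fc_kept),
                 lower.tail = FALSE)
  expect_lt(p_fc, 0.01)
  # the screens genuinely recover the designed-in stable set
  expect_gt(k_cv / 50, 0.5)
})

test_that("batch variance inflation degrades CV concordance, not mean concordance", {
  r_cv <- r_mean <- numeric(0)
  for (infl in c(1, 2.5, 6)) {
    cfg <- sim_config(n_genes = 1500, n_stable = 30, seed = 404,
                      batch_variance_inflation = infl)
    sim <- simulate_expression(cfg)
    fpkm <- counts_to_fpkm(sim$counts, sim$gene_lengths)
    t1 <- subset_expr(fpkm, samples = fpkm$samples$sample_id[fpkm$samples$batch == "T1"])
    t2 <- subset_expr(fpkm, samples = fpkm$samples$sample_id[fpkm$samples$batch == "T2"])
    r_cv <- c(r_cv, replicate_concordance(t1, t2, "cv")$pearson_r)
    r_mean <- c(r_mean, replicate_concordance(t1, t2, "mean")$pearson_r)
  }
  expect_true(all(diff(r_cv) < 0))          # monotone degradation
  expect_true(all(r_mean > 0.9))            # means stay concordant
  expect_lt(r_cv[3], r_cv[1] - 0.1)
})
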