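test_that("technical replicates average plainly within 1 Cq, else drop the outlier", {
  r <- average_tech_reps(c(20.0, 20.1, 20.2))
  expect_equal(r$mean, 20.1); expect_true(is.na(r$dropped))

  r <- average_tech_reps(c(20.0, 20.1, 23.0))   # outlier rule
  expect_equal(r$mean, 20.05); expect_equal(r$dropped, 3L)

  r <- average_tech_reps(c(23.0, 20.0, 20.1))   # outlier listed first
  expect_equal(r$mean, 20.05); expect_equal(r$dropped, 1L)

  expect_equal(average_tech_reps(20.0)$mean, 20.0)        # singleton
  expect_equal(average_tech_reps(c(19.5, 20.5))$mean, 20) # 2 reps within 1

  r <- average_tech_reps(c(19.0, 21.0))         # 2 reps, no identifiable outlier
  expect_true(r$unresolvable); expect_true(is.na(r$mean))
})

test_that("collapse_tech_reps applies the rule per biological sample", {
  cq <- data.frame(gene = "GAP", species = "sim",
                   tissue = rep(c("leaf", "stem"), each = 3),
                   bio_rep = 1L, tech_rep = rep(1:3, 2),
                   cq = c(20.0, 20.1, 23.0, 25.0, 25.2, 25.1))
  out <- collapse_tech_reps(cq)
  expect_equal(nrow(out), 2)
  expect_equal(out$cq[out$tissue == "leaf"], 20.05)
  expect_equal(out$dropped_rep[out$tissue == "leaf"], 3L)
  expect_equal(out$cq[out$tissue == "stem"], 25.1)

  bad <- data.frame(gene = "G", species = "s", tissue = "leaf", bio_rep = 1L,
                    tech_rep = 1:2, cq = c(19, 21))
  expect_warning(res <- collapse_tech_reps(bad), "excluded")
  expect_equal(nrow(res), 0)
})

test_that("standard-curve efficiency follows E = 10^(1/-slope)", {
  # perfect doubling: Cq rises 2 per 1:4 step -> slope -2/log10(4)
  d <- 4^-(0:4)
  cq <- 20 - log2(d)
  fit <- fit_efficiency(d, cq)
  expect_equal(fit$efficiency, 2, tolerance = 1e-12)
  expect_equal(fit$percent, 100, tolerance = 1e-9)

  # printed-formula evaluation at slope -3.59 -> E ~= 1.90 (90%)
  cq2 <- 20 + (-3.59) * log10(d)
  fit2 <- fit_efficiency(d, cq2)
  expect_equal(fit2$slope, -3.59, tolerance = 1e-10)
  expect_equal(fit2$efficiency, 10^(1 / 3.59), tolerance = 1e-10)
  expect_equal(fit2$efficiency, 1.90, tolerance = 0.005)

  expect_error(fit_efficiency(d[1:2], cq[1:2]), "3 dilution points")
  expect_error(fit_efficiency(d, 20 + 3 * log10(d)), "slope")
})

test_that("efficiency recovery is exact on noiseless series across E", {
  d <- 4^-(0:5)
  for (E in c(1.55, 1.7, 1.85, 1.95, 2.05, 2.1)) {
    cq <- 22 - log(d, base = E)
    expect_equal(fit_efficiency(d, cq)$efficiency, E, tolerance = 1e-9)
  }
})

test_that("relative expression is E^(delta Cq) against each gene's calibrator", {
  # calibrator sample is leaf/rep1; each gene normalizes to its own Cq there
  # (gene A: 20, gene B: 22.4)
  cq <- data.frame(gene = rep(c("A", "B"), each = 3), species = "sim",
                   tissue = rep(c("leaf", "stem", "petal"), 2),
                   bio_rep = 1L,
                   cq = c(20, 19, 24.1, 22.4, 24.1, 22.4))
  eff <- c(A = 2, B = 1.9)
  cal <- list(species = "sim", tissue = "leaf", bio_rep = 1L)
  rel <- relative_expression(cq, eff, cal)
  expect_equal(rel$rel_expr[1], 1)            # delta Cq = 0
  expect_equal(rel$rel_expr[2], 2)            # one-cycle doubling at E = 2
  expect_equal(rel$rel_expr[5], 1.9^(-1.7), tolerance = 1e-12)
  expect_equal(rel$rel_expr[5], 0.336, tolerance = 1e-3)
  expect_equal(rel$rel_expr[6], 1)

  # monotone decreasing in sample Cq for E > 1
  cqs <- seq(15, 30, by = 0.5)
  re <- 2^(20 - cqs)
  expect_true(all(diff(re) < 0))

  expect_error(relative_expression(cq, c(A = 2), cal), "B")
  expect_error(
    relative_expression(cq, eff, list(species = "sim", tissue = "root",
                                      bio_rep = 1L)),
    "calibrator")
})

test_that("qPCR CV averages bio reps within tissue, then CV across tissues", {
  rel <- expand.grid(tissue = c("t1", "t2", "t3", "t4"), bio_rep = 1:4)
  rel$gene <- "G"
  # tissue means 1,2,3,4 after averaging the two-sided spread
  base <- c(t1 = 1, t2 = 2, t3 = 3, t4 = 4)
  # bio reps 1-2 sit 0.1 low, reps 3-4 sit 0.1 high: tissue means stay 1:4
  rel$rel_expr <- unname(base[as.character(rel$tissue)]) +
    rep(c(-0.1, 0.1), each = 8)
  out <- qpcr_cv(rel)
  expect_equal(out$mean, 2.5)
  expect_equal(out$sd, sqrt(5 / 3), tolerance = 1e-12)   # hand: sd of 1:4
  expect_equal(out$cv, sqrt(5 / 3) / 2.5, tolerance = 1e-12)
  expect_equal(out$cv, 0.516, tolerance = 1e-3)

  # equal tissue means -> CV 0
  rel0 <- rel; rel0$rel_expr <- 5
  expect_equal(qpcr_cv(rel0)$cv, 0)

  # tissue exclusion changes the basis; <2 tissues is an error
  out_ex <- qpcr_cv(rel, exclude_tissues = "t4")
  expect_equal(out_ex$n_tissues, 3)
  expect_error(qpcr_cv(rel, exclude_tissues = c("t2", "t3", "t4")), "2 tissues")
})

test_that("qPCR CV is invariant to the calibrator choice", {
  set.seed(31)
  rel <- expand.grid(tissue = c("t1", "t2", "t3", "t4"), bio_rep = 1:4)
  rel$gene <- "G"
  rel$rel_expr <- runif(16, 0.5, 4)
  cv1 <- qpcr_cv(rel)$cv
  # switching calibrator multiplies every rel_expr by one constant
  rel2 <- rel; rel2$rel_expr <- rel$rel_expr * 7.3
  expect_equal(qpcr_cv(rel2)$cv, cv1, tolerance = 1e-12)
})

test_that("3'/5' integrity ratio is E^(Cq5 - Cq3) with the 0.2-5 window", {
  expect_equal(qc_3p5p(20, 20)$ratio_3p_5p, 1)
  expect_true(qc_3p5p(20, 20)$pass)
  r <- qc_3p5p(20, 23, efficiency = 2)       # 2^3 = 8 -> degradation flag
  expect_equal(r$ratio_3p_5p, 8); expect_false(r$pass)
  r2 <- qc_3p5p(22, 20, efficiency = 2)      # 2^-2 = 0.25, inside the window
  expect_equal(r2$ratio_3p_5p, 0.25); expect_true(r2$pass)
})
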