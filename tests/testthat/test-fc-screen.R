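test_that("CPM normalization matches the unit definition and edgeR", {
  # one sample summing to 1e6: CPM equals the counts; 50 in 5e6 -> 10 CPM
  vals <- matrix(c(1, 999999), 2, 1, dimnames = list(c("a", "b"), "s1"))
  cpm1 <- normalize_library_size(make_em(vals, unit = "COUNTS"))
  expect_equal(unname(cpm1$values[, 1]), c(1, 999999))

  vals2 <- matrix(c(50, 5e6 - 50), 2, 1, dimnames = list(c("a", "b"), "s1"))
  cpm2 <- normalize_library_size(make_em(vals2, unit = "COUNTS"))
  expect_equal(unname(cpm2$values["a", 1]), 10)

  # identical columns stay identical
  set.seed(2)
  cnt <- matrix(rpois(10, 100), 5, 2,
                dimnames = list(paste0("g", 1:5), c("s1", "s2")))
  cnt[, 2] <- cnt[, 1]
  cpm3 <- normalize_library_size(make_em(cnt, unit = "COUNTS"))
  expect_equal(cpm3$values[, 1], cpm3$values[, 2])

  # independent cross-check against edgeR's library-size CPM
  skip_if_not_installed("edgeR")
  cnt4 <- matrix(rpois(80, 200), 10, 8,
                 dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:8)))
  ours <- normalize_library_size(make_em8(cnt4, unit = "COUNTS"))$values
  theirs <- edgeR::cpm(cnt4, normalized.lib.sizes = FALSE, log = FALSE)
  expect_equal(ours, theirs, tolerance = 1e-12, ignore_attr = TRUE)

  zero <- matrix(c(0, 0, 1, 1), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(normalize_library_size(make_em(zero, unit = "COUNTS")), "s1")
})

test_that("pairwise log fold changes are correct and antisymmetric", {
  vals <- rbind(eq = c(7, 7), dbl = c(20, 10), zero = c(10, 0))
  colnames(vals) <- c("s1", "s2")
  m <- make_em(vals)
  lfc0 <- pairwise_logfc(m, pseudocount = 0)
  expect_equal(unname(lfc0["eq", 1]), 0)
  expect_equal(unname(lfc0["dbl", 1]), 1)
  lfc <- pairwise_logfc(m, pseudocount = 0.5)
  expect_equal(unname(lfc["zero", 1]), log2(10.5 / 0.5), tolerance = 1e-12)

  # antisymmetry: flip the two samples, logFC negates exactly
  m_rev <- subset_expr(m, samples = c("s2", "s1"))
  expect_equal(pairwise_logfc(m_rev, 0.5)[, 1], -lfc[, 1],
               tolerance = 0, ignore_attr = TRUE)
})

test_that("foldchange_screen retains at <= cutoff and finds the worst pair", {
  vals <- rbind(flat = rep(50, 8),
                jump = c(10, 10, 10, 20, 10, 10, 10, 10),  # one 2x jump
                mild = c(10, 10, 10, 12, 10, 10, 10, 10))
  colnames(vals) <- paste0("s", 1:8)
  fc <- foldchange_screen(make_em8(vals), cutoff = 0.4, normalize = "none",
                          pseudocount = 0)
  expect_true(fc$retained[fc$gene_id == "flat"])
  expect_equal(fc$max_abs_logfc[fc$gene_id == "flat"], 0)
  jump <- fc[fc$gene_id == "jump", ]
  expect_false(jump$retained)
  expect_equal(jump$max_abs_logfc, 1)
  expect_true("s4" %in% c(jump$worst_pair_a, jump$worst_pair_b))
  expect_equal(fc$gene_id, c("flat", "mild", "jump"))  # ascending order
  # gene exactly at the cutoff survives (8 vs 16 is exactly 1 log2 unit)
  at_cut <- foldchange_screen(make_em(matrix(c(8, 16), 1, 2,
                                             dimnames = list("g", c("a", "b")))),
                              cutoff = 1, normalize = "none", pseudocount = 0)
  expect_true(at_cut$retained)
  expect_equal(at_cut$max_abs_logfc, 1)
  wob <- rand_mat(10, 8, seed = 8, min = 1, max = 1000)  # no flat gene
  expect_warning(
    foldchange_screen(make_em8(wob), cutoff = 1e-6, normalize = "none"),
    "no genes retained")
})

test_that("retained sets are monotone in the cutoff", {
  vals <- rand_mat(50, 8, seed = 9, min = 1, max = 200)
  m <- make_em8(vals)
  cuts <- c(0.1, 0.3, 0.5, 1, 2, 6)
  sets <- lapply(cuts, function(cc) {
    fc <- suppressWarnings(foldchange_screen(m, cc, normalize = "none"))
    fc$gene_id[fc$retained]
  })
  for (i in seq_len(length(cuts) - 1))
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("max |logFC| matches the exhaustive triple-loop oracle", {
  for (seed in 1:5) {
    vals <- rand_mat(20, 8, seed = seed, min = 0, max = 300)
    fc <- suppressWarnings(foldchange_screen(make_em8(vals), cutoff = 0.4,
                                             normalize = "none",
                                             pseudocount = 0.5))
    expected <- oracle_max_abs_logfc(vals, 0.5)
    got <- setNames(fc$max_abs_logfc, fc$gene_id)[names(expected)]
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("depth scaling of one sample leaves CPM-based logFC unchanged", {
  set.seed(4)
  cnt <- matrix(rpois(80, 500), 10, 8,
                dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:8)))
  m1 <- make_em8(cnt, unit = "COUNTS")
  cnt2 <- cnt; cnt2[, 3] <- cnt2[, 3] * 5          # 5x deeper library
  m2 <- make_em8(cnt2, unit = "COUNTS")
  lfc1 <- pairwise_logfc(normalize_library_size(m1), pseudocount = 0)
  lfc2 <- pairwise_logfc(normalize_library_size(m2), pseudocount = 0)
  expect_equal(lfc1, lfc2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("method_concordance counts the fc/CV overlap", {
  vals <- rbind(a = c(10, 10.1), b = c(10, 11), c = c(10, 30), d = c(10, 80))
  colnames(vals) <- c("s1", "s2")
  m <- make_em(vals)
  cv <- stability_cv(m)
  fc <- foldchange_screen(m, cutoff = 0.2, normalize = "none", pseudocount = 0)
  res <- method_concordance(fc, cv, n_list = c(1, 2, 4))
  expect_equal(res$retained_genes, c("a", "b"))
  expect_equal(res$overlap$overlap, c(1L, 2L, 2L))
  expect_equal(res$max_cv_rank, 2L)
  cv_other <- cv; cv_other$gene_id <- paste0("x", cv$gene_id)
  expect_error(method_concordance(fc, cv_other), "no genes")
})
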