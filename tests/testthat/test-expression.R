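test_that("delta-delta-CT recovers hand-computed fold changes", {
  # identical CT in both strains: fold change 1
  ct <- mk_ct(list(t = 24), list(t = 24))
  expect_equal(relative_expression(ct, "t", "ref", "mut", "wt")$fold_change,
               1.0)

  # worked example: ddCT = 4, fold change 2^-4
  ct <- mk_ct(list(t = 24), list(t = 28))
  rel <- relative_expression(ct, "t", "ref", "mut", "wt")
  expect_equal(rel$ddct, 4)
  expect_equal(rel$fold_change, 0.0625)
  expect_equal(unname(rel$rel_calibrator), rep(1, 3))

  # undetermined in the calibrator strain: detection flag, not a number
  ct_na <- ct; ct_na$ct[ct_na$gene == "t"] <- NA
  expect_false(relative_expression(ct_na, "t", "ref", "mut",
                                   "wt")$detected)

  # undetermined reference is a hard error
  ct_badref <- ct; ct_badref$ct[ct_badref$gene == "ref"][1:3] <- NA
  expect_error(relative_expression(ct_badref, "t", "ref", "mut", "wt"),
               "undetermined")
})

test_that("fold change is invariant to a constant CT shift of one strain", {
  set.seed(21)
  for (k in 1:20) {
    wt_t <- runif(1, 22, 30); mut_t <- runif(1, 22, 30)
    ct <- mk_ct(list(t = wt_t), list(t = mut_t))
    shifted <- ct
    idx <- shifted$strain == "mut"
    shifted$ct[idx] <- shifted$ct[idx] + 3  # target and reference alike
    fc0 <- relative_expression(ct, "t", "ref", "mut", "wt")$fold_change
    fc1 <- relative_expression(shifted, "t", "ref", "mut", "wt")$fold_change
    expect_equal(fc1, fc0)
  }
})

test_that("two-group ANOVA matches the pooled t-test and handles degeneracy", {
  expect_equal(anova_p(c(1, 1, 1), c(1, 1, 1)), 1.0)
  # clear separation is decisively significant
  expect_lt(anova_p(c(1.0, 1.1, 0.9), c(0.05, 0.04, 0.06)), 0.001)
  # t^2 = F identity over random instances
  set.seed(42)
  for (k in 1:100) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1), mean = runif(1))
    expect_equal(anova_p(x, y),
                 t.test(x, y, var.equal = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("regulation classes partition the fold-change/p space", {
  th <- expression_thresholds()
  expect_equal(classify_gene(0.0625, 0.001), "abolished")
  expect_equal(classify_gene(0.4, 0.01), "downregulated")
  expect_equal(classify_gene(0.9, 0.4), "unchanged")
  expect_equal(classify_gene(0.9, 0.01), "unchanged")  # significant but small
  expect_equal(classify_gene(3, 0.01), "upregulated")
  expect_equal(classify_gene(NA, NA, detected = FALSE), "not_expressed")
  # exhaustive partition over a grid: exactly one class each
  for (fc in c(0.01, 0.1, 0.3, 2 / 3, 1, 1.4, 1.5, 5))
    for (p in c(0.001, 0.049, 0.05, 0.9))
      expect_true(classify_gene(fc, p) %in%
                    c("abolished", "downregulated", "unchanged",
                      "upregulated"))
})

test_that("locus analysis classifies every assayed gene once", {
  ct <- mk_ct(list(g1 = 24, g2 = 25), list(g1 = 30, g2 = 25))
  res <- analyze_locus(ct, "ref", "mut", "wt")
  expect_equal(nrow(res), 2)
  expect_false("ref" %in% res$gene)
  expect_error(analyze_locus(ct[ct$gene != "ref", ], "ref", "mut", "wt"),
               "reference")
})

test_that("planted expression classes are recovered from the CT fixture", {
  abolished <- paste0("mrpig", c("A", "H", "M", "N", "O", "P"))
  down <- c(paste0("mrpig", c("D", "E", "F", "G")), "mrpigAup1",
            "mrpigPdown1")
  core16 <- paste0("mrpig", LETTERS[1:16])
  for (seed in 1:10) {
    fx <- bgc_fixture("qpcr_panel", seed = seed)
    res <- analyze_locus(fx$ct_table, "GAPDH", "dmrpigB", "M7")
    expect_setequal(res$gene[res$reg_class == "abolished"], abolished)
    expect_setequal(res$gene[res$reg_class == "downregulated"], down)
    expect_identical(res$gene[res$reg_class == "not_expressed"], "mrpigI")
    inside_unchanged <- res$gene[res$reg_class == "unchanged" &
                                   res$gene %in% core16]
    expect_setequal(inside_unchanged,
                    paste0("mrpig", c("C", "J", "K", "L")))
  }
})

test_that("ANOVA p-values are near-uniform under the null fold change", {
  # 1000 independent single-gene assays (each with its own reference
  # measurements; genes sharing one physical reference well have dependent
  # p-values, which is a property of the assay design, not of the test)
  genes <- data.frame(gene = "null_gene", true_fc = 1,
                      not_expressed = FALSE)
  p <- vapply(1:1000, function(seed) {
    ct <- generate_ct_table(expression_design(genes, seed = seed))
    analyze_locus(ct, "GAPDH", "dmrpigB", "M7")$p_value
  }, numeric(1))
  ks <- ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
  # and the false-positive rate sits near alpha
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
})

test_that("CT tables round-trip through CSV with blanks as undetermined", {
  fx <- bgc_fixture("qpcr_panel", seed = 2)
  path <- tempfile(fileext = ".csv")
  write_ct_table(fx$ct_table, path)
  back <- read_ct_table(path)
  expect_equal(back$ct, fx$ct_table$ct, tolerance = 1e-10)
  expect_true(anyNA(back$ct))
})
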