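test_that("mutation to a target identity is exact in length and close in identity", {
  set.seed(8)
  p <- random_protein(300)
  expect_identical(mutate_to_identity(p, 1.0, seed = 1), p)
  for (seed in 1:20) {
    m <- mutate_to_identity(p, 0.7, seed = seed)
    expect_equal(nchar(m), 300)
    ident <- mean(strsplit(p, "")[[1]] == strsplit(m, "")[[1]])
    expect_gte(ident, 0.67)
    expect_lte(ident, 0.73)
  }
  expect_error(mutate_to_identity("MKVLA", 0.7), "too short")
})

test_that("generators are pure functions of config and seed", {
  a <- bgc_fixture("m7_atcc18224", seed = 42)
  b <- bgc_fixture("m7_atcc18224", seed = 42)
  expect_identical(a$genome_a$proteome, b$genome_a$proteome)
  expect_identical(a$genome_b$genes, b$genome_b$genes)
  c <- bgc_fixture("m7_atcc18224", seed = 43)
  expect_false(identical(a$genome_a$proteome, c$genome_a$proteome))

  t1 <- bgc_fixture("qpcr_panel", seed = 5)$ct_table
  t2 <- bgc_fixture("qpcr_panel", seed = 5)$ct_table
  expect_identical(t1, t2)

  k1 <- bgc_fixture("knockout_panel", seed = 5)
  k2 <- bgc_fixture("knockout_panel", seed = 5)
  expect_identical(k1$wt$amounts, k2$wt$amounts)
})

test_that("the locus fixture has the documented topology", {
  fx <- bgc_fixture("m7_atcc18224", seed = 42)
  reg <- locus_registry()
  expect_equal(nrow(fx$genome_a$genes), 40)  # 20-gene locus + 20 background
  expect_true(all(reg$genes %in% fx$genome_a$genes$gene_id))
  # locus genes are contiguous in genome A
  idx <- match(reg$genes, fx$genome_a$genes$gene_id)
  expect_equal(idx, seq(min(idx), length.out = 20))
  # partners exist for the lettered genes except F, O, L; flanks unpartnered
  partnered <- unique(fx$truth$gene_a)
  expect_setequal(partnered,
                  setdiff(paste0("mrpig", LETTERS[1:16]),
                          c("mrpigF", "mrpigO", "mrpigL")))
  # the split partner contributes two consecutive genome-B fragments
  frags <- fx$truth$gene_b[fx$truth$gene_a == "mrpigH"]
  expect_length(frags, 2)
  fidx <- match(frags, fx$genome_b$genes$gene_id)
  expect_equal(diff(sort(fidx)), 1)
  # 14 partner genes total in genome B
  expect_equal(nrow(fx$truth), 14)
})

test_that("the non-syntenic fixture shuffles partners but keeps the anchor block", {
  fx <- bgc_fixture("pm1_nonsyntenic", seed = 7)
  bidx <- match(fx$truth$gene_b, fx$genome_b$genes$gene_id)
  # the 14 partner genes still form one contiguous stretch in genome B
  expect_equal(sort(bidx), seq(min(bidx), length.out = 14))
  # the preserved anchor block is contiguous and in order
  anchor <- match(paste0("tm_", c("mrpigI", "mrpigJ", "mrpigK")),
                  fx$genome_b$genes$gene_id)
  expect_equal(diff(anchor), c(1, 1))
  # but the arrangement as a whole is not syntenic
  syn <- bgc_fixture("m7_atcc18224", seed = 7)
  expect_false(identical(
    fx$genome_b$genes$gene_id[sort(bidx)],
    syn$genome_b$genes$gene_id[sort(match(syn$truth$gene_b,
                                          syn$genome_b$genes$gene_id))]))
})

test_that("planted orthologs pass the E-value filter; background never does", {
  for (seed in 1:10) {
    fx <- generate_genome_pair(small_pair_config(1000 + seed))
    g <- build_homolog_graph(fx$genome_a, fx$genome_b)
    planted <- paste(fx$truth$gene_a, fx$truth$gene_b)
    found <- paste(g$gene_a, g$gene_b)
    expect_true(all(planted %in% found))  # identity >= 0.4 recovered
    bg <- grepl("bg", g$gene_a) | grepl("bg", g$gene_b)
    expect_false(any(bg))
  }
})

test_that("a noise-free CT design round-trips fold changes exactly", {
  genes <- data.frame(gene = c("t1", "t2", "t3"),
                      true_fc = c(0.0625, 1, 4),
                      not_expressed = FALSE)
  des <- expression_design(genes, bio_sd = 0, tech_sd = 0, seed = 1)
  ct <- generate_ct_table(des)
  res <- analyze_locus(ct, "GAPDH", "dmrpigB", "M7")
  expect_equal(res$fold_change[match(c("t1", "t2", "t3"), res$gene)],
               c(0.0625, 1, 4), tolerance = 1e-12)
})

test_that("zero-noise knockout profiles equal their templates", {
  cfg <- list(wt_amounts = c(`1` = 120, `2` = 100, `3` = 80, `4` = 90,
                             `5` = 0, `6` = 0),
              strains = list(dx = list(mult = c(`1` = 1, `2` = 1,
                                                `3` = 1, `4` = 1))),
              noise_sd = 0)
  out <- generate_knockout_profiles(cfg, seed = 1)
  expect_equal(unname(out$wt$amounts[1:4]), c(120, 100, 80, 90))
  expect_equal(out$mutants$dx$amounts, out$wt$amounts)
})

test_that("fixture files are written in the standard plain-text formats", {
  dir <- tempfile()
  paths <- simulate_fixture("qpcr_panel", seed = 1, dir = dir)
  expect_true(file.exists(file.path(dir, "ct_table.csv")))
  dir2 <- tempfile()
  simulate_fixture("m7_atcc18224", seed = 1, dir = dir2)
  gt <- load_genome(file.path(dir2, "genome_a.tsv"),
                    file.path(dir2, "genome_a.faa"))
  expect_equal(nrow(gt$genes), 40)
})
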