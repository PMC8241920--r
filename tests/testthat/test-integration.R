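# Evidence fixtures mirroring the locus study: cg span mrpigA..mrpigP,
# border genes regulated but knockout-neutral, unregulated interior genes.
m7_evidence <- function() {
  reg <- locus_registry()
  cg <- span_gene_names(reg, "mrpigA", "mrpigP")
  reg_class <- c(
    setNames(rep("abolished", 6), paste0("mrpig", c("A","H","M","N","O","P"))),
    setNames(rep("downregulated", 6),
             c(paste0("mrpig", c("D","E","F","G")), "mrpigAup1",
               "mrpigPdown1")),
    setNames(rep("unchanged", 6),
             c("mrpigAup2", paste0("mrpig", c("C","J","K","L")),
               "mrpigPdown2")),
    mrpigI = "not_expressed")
  ko <- c(mrpigAup2 = "unchanged", mrpigAup1 = "unchanged",
          mrpigA = "abolished", mrpigO = "shunt", mrpigP = "ratio_shift",
          mrpigPdown1 = "unchanged", mrpigPdown2 = "unchanged")
  evidence_table(reg$genes, cg, reg_class, ko)
}

test_that("a cg-only evidence table returns the span verbatim", {
  genes <- paste0("g", 1:10)
  ev <- evidence_table(genes, genes[4:7])
  call <- call_bgc(ev)
  expect_identical(call$members, genes[4:7])
  expect_error(call_bgc(evidence_table(genes, character(0))),
               "boundary stage")
  expect_error(evidence_table(genes, genes[c(2, 5)]), "contiguous")
})

test_that("the locus evidence fixture resolves to the 16-gene consensus", {
  call <- call_bgc(m7_evidence())
  expect_equal(call$n_genes, 16)
  expect_equal(call$first_gene, "mrpigA")
  expect_equal(call$last_gene, "mrpigP")
  # border genes regulated by the pathway regulator but knockout-neutral
  # are excluded with a machine-readable reason
  excl <- setNames(call$excluded$reason, call$excluded$gene)
  expect_equal(unname(excl["mrpigAup1"]), "regulated-but-ko-neutral")
  expect_equal(unname(excl["mrpigPdown1"]), "regulated-but-ko-neutral")
  # unregulated interior genes are retained
  expect_true(all(paste0("mrpig", c("C", "J", "K", "L")) %in%
                    call$members))
  tiers <- setNames(call$evidence$tier, call$evidence$gene)
  expect_equal(unname(tiers["mrpigL"]), "retained-interior")
  expect_equal(unname(tiers["mrpigA"]), "strong")
})

test_that("supporting knockout evidence extends the call outward", {
  ev <- m7_evidence()
  ev$ko_category[ev$gene == "mrpigPdown1"] <- "shunt"
  call <- call_bgc(ev)
  expect_equal(call$n_genes, 17)
  expect_equal(call$last_gene, "mrpigPdown1")
  # transcriptional downregulation alone never admits a gene
  ev2 <- m7_evidence()
  ev2$ko_category[ev2$gene == "mrpigAup1"] <- NA
  expect_equal(call_bgc(ev2)$first_gene, "mrpigA")
})

test_that("ko-neutral evidence never enlarges the member set", {
  set.seed(55)
  genes <- paste0("g", 1:14)
  for (k in 1:40) {
    span <- sort(sample(14, 2)); span <- genes[span[1]:span[2]]
    rc <- sample(c(NA, "abolished", "downregulated", "unchanged"),
                 14, replace = TRUE)
    ko <- sample(c(NA, "abolished", "shunt", "ratio_shift", "unchanged"),
                 14, replace = TRUE)
    ev <- evidence_table(genes, span, setNames(rc, genes),
                         setNames(ko, genes))
    base <- call_bgc(ev)$members
    target <- sample(14, 1)
    ev2 <- ev
    ev2$ko_category[target] <- "unchanged"
    shrunk <- call_bgc(ev2)$members
    expect_true(all(shrunk %in% base))
    # contiguity always holds
    idx <- match(shrunk, genes)
    expect_equal(idx, seq(min(idx), max(idx)))
  }
})

test_that("consensus calling is idempotent", {
  call <- call_bgc(m7_evidence())
  ev2 <- evidence_table(call$evidence$gene, call$members,
                        setNames(call$evidence$reg_class,
                                 call$evidence$gene),
                        setNames(call$evidence$ko_category,
                                 call$evidence$gene))
  expect_identical(call_bgc(ev2)$members, call$members)
})

test_that("reports round-trip through JSON", {
  genes <- paste0("g", 1:3)
  call <- call_bgc(evidence_table(genes, genes))
  path <- tempfile(fileext = ".json")
  render_report(call, path)
  rep <- read_report(path)
  expect_identical(rep$call$members, genes)
  expect_equal(rep$call$n_genes, 3)
  expect_length(rep$evidence, 3)
  expect_true(file.exists(sub("\\.json$", ".txt", path)))

  # the full locus call round-trips too
  call2 <- call_bgc(m7_evidence())
  path2 <- tempfile(fileext = ".json")
  render_report(call2, path2)
  rep2 <- read_report(path2)
  expect_identical(rep2$call$members, call2$members)
  expect_equal(length(rep2$excluded), nrow(call2$excluded))
})
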