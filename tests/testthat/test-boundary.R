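test_that("seed detection finds the longest doubly-contiguous block", {
  ga <- toy_genome(paste0("a", 1:12), "A")
  gb <- toy_genome(paste0("b", 1:12), "B")

  # empty graph: no seed
  empty <- mk_graph(character(0), character(0), numeric(0))
  expect_null(detect_seed(empty, ga, gb))

  # two blocks, lengths 3 and 5: the 5-block wins, as in the exhaustive
  # block enumeration
  g <- mk_graph(gene_a = c("a1", "a2", "a3", "a7", "a8", "a9", "a10", "a11"),
                gene_b = c("b1", "b2", "b3", "b7", "b8", "b9", "b10", "b11"),
                norm_score = c(0.9, 0.9, 0.9, 0.5, 0.5, 0.5, 0.5, 0.5))
  seed <- detect_seed(g, ga, gb)
  expect_identical(seed$genes_a, paste0("a", 7:11))
  orc <- seed_oracle(12, 12, match(g$gene_a, ga$genes$gene_id),
                     match(g$gene_b, gb$genes$gene_id), g$norm_score, 3)
  expect_equal(c(orc$a1, orc$a2), c(7, 11))

  # a length tie resolves toward the higher-scoring block
  g2 <- mk_graph(gene_a = c("a1", "a2", "a3", "a7", "a8", "a9"),
                 gene_b = c("b1", "b2", "b3", "b7", "b8", "b9"),
                 norm_score = c(0.4, 0.4, 0.4, 0.9, 0.9, 0.9))
  expect_identical(detect_seed(g2, ga, gb)$genes_a, paste0("a", 7:9))

  # below the minimum length: none
  g3 <- mk_graph(c("a1", "a2"), c("b1", "b2"), c(0.9, 0.9))
  expect_null(detect_seed(g3, ga, gb))
})

test_that("a split fragment pair counts as one genome-A position", {
  ga <- toy_genome(paste0("a", 1:6), "A")
  gb <- toy_genome(paste0("b", 1:7), "B")
  g <- mk_graph(gene_a = c("a2", "a3", "a3", "a4"),
                gene_b = c("b2", "b3", "b4", "b5"),
                norm_score = c(0.8, 0.7, 0.7, 0.8))
  seed <- detect_seed(g, ga, gb)
  expect_identical(seed$genes_a, c("a2", "a3", "a4"))
  expect_identical(seed$genes_b, paste0("b", 2:5))
})

test_that("extension arithmetic matches the even-split, odd-upstream rule", {
  ids <- sprintf("g%02d", 1:60)
  gt <- toy_genome(ids, "A")
  par <- cluster_scoring_params()
  seed5 <- structure(list(genes_a = ids[21:25], genes_b = ids[21:25],
                          pairs = NULL, sum_score = 5),
                     class = "seed_region")
  w <- extend_seed(seed5, gt, gt, par)
  expect_length(w$window_a, 35)
  expect_identical(w$window_a, ids[6:40])  # positions 5..39, 0-based

  # seed near the contig start truncates silently
  seed_edge <- structure(list(genes_a = ids[3:7], genes_b = ids[3:7],
                              pairs = NULL, sum_score = 5),
                         class = "seed_region")
  we <- extend_seed(seed_edge, gt, gt, par)
  expect_identical(we$window_a[1], ids[1])
  expect_lt(length(we$window_a), 35)
  expect_identical(we$window_a, ids[1:22])

  # 4-gene seed: 16 genes upstream, 15 downstream
  seed4 <- structure(list(genes_a = ids[25:28], genes_b = ids[25:28],
                          pairs = NULL, sum_score = 4),
                     class = "seed_region")
  w4 <- extend_seed(seed4, gt, gt, par)
  expect_length(w4$window_a, 35)
  expect_identical(w4$window_a, ids[9:43])
  expect_equal(sum(w4$window_a < ids[25]), 16)
})

test_that("trimming maximizes CB on hand-checkable windows", {
  par <- cluster_scoring_params()

  # saturated case: every window gene matched at 1.0
  wA <- paste0("a", 1:4); wB <- paste0("b", 1:4)
  g <- mk_graph(wA, wB, rep(1.0, 4))
  call <- trim_boundaries(mk_window(wA, wB), g, par)
  expect_identical(call$span_a, wA)
  expect_identical(call$span_b, wB)
  expect_equal(call$cb_score, 4)

  # contributions [+0.5, -0.3, +0.9]: the optimal span keeps the interior
  # penalty gene, CB = 1.1
  wA <- c("a1", "a2", "a3"); wB <- c("b1", "b2")
  g <- mk_graph(c("a1", "a3"), c("b1", "b2"), c(0.5, 0.9))
  call <- trim_boundaries(mk_window(wA, wB), g, par)
  expect_identical(call$span_a, wA)
  expect_equal(call$cb_score, 1.1)
  expect_equal(sum(call$per_gene_contributions), call$cb_score)

  # no matched gene at all: structured error
  g0 <- mk_graph("zz", "yy", 0.5)
  expect_error(trim_boundaries(mk_window(wA, wB), g0, par),
               "no cluster evidence")
})

test_that("trimming equals exhaustive span enumeration on random windows", {
  set.seed(404)
  par <- cluster_scoring_params()
  for (k in 1:100) {
    nA <- sample(3:12, 1); nB <- sample(3:12, 1)
    wA <- paste0("A", seq_len(nA)); wB <- paste0("B", seq_len(nB))
    npair <- sample(2:(nA + 2), 1)
    ai <- sample(nA, npair, replace = TRUE)
    bi <- sample(nB, npair, replace = TRUE)
    s <- round(runif(npair, 0.1, 1), 3)
    g <- mk_graph(wA[ai], wB[bi], s)
    call <- trim_boundaries(mk_window(wA, wB), g, par)
    orc <- trim_oracle(nA, nB, ai, bi, s, par$negative_penalty)
    expect_equal(call$cb_score, orc$cb, tolerance = 1e-9)
    expect_identical(c(call$i_begin, call$i_end, call$j_begin, call$j_end),
                     c(wA[orc$i1], wA[orc$i2], wB[orc$j1], wB[orc$j2]))
  }
})

test_that("a stiffer negative penalty never widens the optimal span", {
  set.seed(77)
  for (k in 1:5) {
    nA <- 10; nB <- 10
    wA <- paste0("A", 1:nA); wB <- paste0("B", 1:nB)
    npair <- 8
    ai <- sample(nA, npair, replace = TRUE)
    bi <- sample(nB, npair, replace = TRUE)
    g <- mk_graph(wA[ai], wB[bi], round(runif(npair, 0.2, 1), 3))
    widths <- vapply(c(-0.1, -0.3, -0.6, -1, -2), function(pen) {
      call <- trim_boundaries(mk_window(wA, wB), g,
                              cluster_scoring_params(negative_penalty = pen))
      length(call$span_a) + length(call$span_b)
    }, numeric(1))
    expect_true(all(diff(widths) <= 0))
  }
})

test_that("the trimmed call dominates the seed and random alternatives", {
  fx <- bgc_fixture("m7_atcc18224", seed = 42)
  pred <- predict_cluster(fx$genome_a, fx$genome_b)
  expect_gte(pred$call$cb_score, pred$seed$sum_score)

  # CB optimality against 50 random alternative span pairs
  g <- pred$graph
  wA <- pred$window$window_a; wB <- pred$window$window_b
  ai <- match(g$gene_a, wA); bi <- match(g$gene_b, wB)
  keep <- !is.na(ai) & !is.na(bi)
  set.seed(9)
  for (k in 1:50) {
    i <- sort(sample(length(wA), 2)); j <- sort(sample(length(wB), 2))
    cb <- cb_naive(ai[keep], bi[keep], g$norm_score[keep], -0.3,
                   i[1], i[2], j[1], j[2])
    expect_gte(pred$call$cb_score, cb - 1e-9)
  }
})

test_that("the comparative stage recovers planted structure end-to-end", {
  # syntenic planted cluster is recovered exactly on both sides
  fx <- generate_genome_pair(small_pair_config(303))
  pred <- predict_cluster(fx$genome_a, fx$genome_b)
  expect_equal(pred$status, "ok")
  expect_identical(pred$call$span_a, paste0("cg", 1:6))

  # unrelated random genomes: structured no-cluster result
  lay <- data.frame(gene_a = paste0("x", 1:4), partner = "none",
                    identity = NA_real_)
  r1 <- generate_genome_pair(genome_pair_config(
    lay, background_a = 8, background_b = 8,
    protein_len_range = c(250, 300), seed = 31))
  pred0 <- predict_cluster(r1$genome_a, r1$genome_b)
  expect_equal(pred0$status, "no_cluster")
  expect_null(pred0$call)
})
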