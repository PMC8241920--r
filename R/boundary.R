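# The comparative-genomics boundary algorithm: detect the seed block of
# contiguous homolog pairs shared by both genomes, extend it to a fixed
# total window width, and trim both genomes' boundaries jointly by
# maximizing the cumulative score CB.
#
# CB of a span pair = sum over genome-A span genes of the best similarity to
# a partner inside the genome-B span (each matched A gene counted once)
# plus negative_penalty for every span gene, on either side, without a
# partner in the opposing span. Matching is order-free within the spans, so
# non-syntenic partner clusters score fully.

#' Gene-level cluster scoring parameters
#'
#' Parameters of the seed/extend/trim stage. These are *gene-level* scores
#' on the unit scale of normalized similarities; they are unrelated to the
#' residue-level gap penalties of [alignment_params()]. `gap_penalty`
#' applies to a gene with no partner anywhere, `mismatch_penalty` to a gene
#' whose partners all lie outside the opposing span (both used in seed-stage
#' bookkeeping), and `negative_penalty` to any unmatched span gene during
#' trimming.
#'
#' @param gap_penalty,mismatch_penalty,negative_penalty negative numbers
#'   (defaults -0.2, -0.2, -0.3).
#' @param extension_total total number of genes in the extended candidate
#'   window, seed included (default 35).
#' @param min_seed_len minimum seed block length in genome-A genes
#'   (default 3).
#' @return list of class `cluster_scoring_params`.
#' @export
cluster_scoring_params <- function(gap_penalty = -0.2,
                                   mismatch_penalty = -0.2,
                                   negative_penalty = -0.3,
                                   extension_total = 35,
                                   min_seed_len = 3) {
  stopifnot(gap_penalty < 0, mismatch_penalty < 0, negative_penalty < 0,
            min_seed_len >= 1, extension_total >= min_seed_len)
  structure(list(gap_penalty = gap_penalty,
                 mismatch_penalty = mismatch_penalty,
                 negative_penalty = negative_penalty,
                 extension_total = as.integer(extension_total),
                 min_seed_len = as.integer(min_seed_len)),
            class = "cluster_scoring_params")
}

#' Detect the synteny seed region
#'
#' Finds the maximal-length block of genome-A genes, contiguous in gene
#' order, whose members all have homolog partners forming a contiguous block
#' in genome B, with every genome-B gene of that block partnered back into
#' the genome-A run. One-to-many fragment pairs are handled naturally: a
#' single genome-A gene may cover several consecutive genome-B positions.
#' Ties are broken by the larger sum of normalized scores, then by the
#' leftmost genome-A position.
#'
#' @param graph a `homolog_graph` from [build_homolog_graph()].
#' @param genome_a,genome_b the two [genome_table()]s.
#' @param params a [cluster_scoring_params()].
#' @return object of class `seed_region` (list with `genes_a`, `genes_b`,
#'   `pairs`, `sum_score`), or `NULL` when no block reaches
#'   `params$min_seed_len`.
#' @export
detect_seed <- function(graph, genome_a, genome_b,
                        params = cluster_scoring_params()) {
  ga <- genome_a$genes; gb <- genome_b$genes
  if (nrow(graph) == 0L) return(NULL)

  ai <- match(graph$gene_a, ga$gene_id)
  bi <- match(graph$gene_b, gb$gene_id)
  ok <- !is.na(ai) & !is.na(bi)
  ai <- ai[ok]; bi <- bi[ok]; sc <- graph$norm_score[ok]
  if (length(ai) == 0L) return(NULL)

  # partner index lists per gene position
  partners_of_a <- split(seq_along(ai), ai)
  partners_of_b <- split(seq_along(bi), bi)
  has_partner_a <- seq_len(nrow(ga)) %in% ai

  best <- NULL
  nA <- nrow(ga)
  for (a1 in seq_len(nA)) {
    if (!has_partner_a[a1]) next
    for (a2 in a1:nA) {
      if (!has_partner_a[a2]) break
      if (ga$contig[a2] != ga$contig[a1]) break
      len <- a2 - a1 + 1L
      if (len < params$min_seed_len) next
      run <- a1:a2
      edge <- unlist(partners_of_a[as.character(run)], use.names = FALSE)
      bpos <- bi[edge]
      rng <- min(bpos):max(bpos)
      if (length(unique(gb$contig[rng])) != 1L) next
      # every B gene in the covered range must pair back into the run
      covered <- vapply(rng, function(b) {
        e <- partners_of_b[[as.character(b)]]
        !is.null(e) && any(ai[e] %in% run)
      }, logical(1))
      if (!all(covered)) next
      in_block <- ai %in% run & bi %in% rng
      score <- sum(sc[in_block])
      cand <- list(a1 = a1, a2 = a2, b1 = min(bpos), b2 = max(bpos),
                   len = len, score = score, edges = which(in_block))
      if (is.null(best) ||
          cand$len > best$len ||
          (cand$len == best$len && cand$score > best$score + 1e-12) ||
          (cand$len == best$len && abs(cand$score - best$score) <= 1e-12 &&
           cand$a1 < best$a1))
        best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  structure(list(
    genes_a = ga$gene_id[best$a1:best$a2],
    genes_b = gb$gene_id[best$b1:best$b2],
    pairs = as.data.frame(graph)[best$edges, , drop = FALSE],
    sum_score = best$score),
    class = "seed_region")
}

# Window of gene ids around a contiguous block, extended to `total` genes:
# flanks split evenly, odd remainder upstream, truncated at contig ends.
extend_block <- function(genes, block_ids, total) {
  idx <- match(block_ids, genes$gene_id)
  i1 <- min(idx); i2 <- max(idx)
  ctg <- genes$contig[i1]
  on_ctg <- which(genes$contig == ctg)
  lo <- min(on_ctg); hi <- max(on_ctg)
  flank <- max(0L, total - (i2 - i1 + 1L))
  up <- ceiling(flank / 2); down <- floor(flank / 2)
  w1 <- max(lo, i1 - up); w2 <- min(hi, i2 + down)
  genes$gene_id[w1:w2]
}

#' Extend the seed region to a fixed-width candidate window
#'
#' Adds flanking genes on both sides of the seed, in each genome, until the
#' window holds `params$extension_total` genes in total (seed included).
#' Flanks are split evenly with any odd remainder going upstream; windows
#' are truncated silently at contig ends.
#'
#' @param seed a [detect_seed()] result.
#' @inheritParams detect_seed
#' @return object of class `extended_window`: list with `window_a`,
#'   `window_b` (ordered gene-id vectors) and `seed`.
#' @export
extend_seed <- function(seed, genome_a, genome_b,
                        params = cluster_scoring_params()) {
  stopifnot(inherits(seed, "seed_region"))
  structure(list(
    window_a = extend_block(genome_a$genes, seed$genes_a,
                            params$extension_total),
    window_b = extend_block(genome_b$genes, seed$genes_b,
                            params$extension_total),
    seed = seed),
    class = "extended_window")
}

#' Trim cluster boundaries by maximizing the cumulative score
#'
#' Searches all pairs of contiguous sub-spans of the two windows and returns
#' the pair maximizing CB (see the module header). Ties are broken by the
#' smaller total span length, then by the leftmost spans. The search is
#' exhaustive over all O(n^4) span pairs (organized so the inner work is
#' vectorized); window widths of ~35 genes keep this instantaneous.
#'
#' @param window an [extend_seed()] result.
#' @param graph the `homolog_graph` used for seeding.
#' @param params a [cluster_scoring_params()].
#' @return object of class `boundary_call`: list with `i_begin`, `i_end`,
#'   `j_begin`, `j_end` (gene ids), `span_a`, `span_b` (gene-id vectors),
#'   `cb_score` and `per_gene_contributions` (named numeric; matched
#'   genome-A genes carry their best-partner score, matched genome-B genes
#'   carry 0 so that each pair is counted once, unmatched span genes carry
#'   the negative penalty).
#' @export
trim_boundaries <- function(window, graph,
                            params = cluster_scoring_params()) {
  stopifnot(inherits(window, "extended_window"))
  wA <- window$window_a; wB <- window$window_b
  nA <- length(wA); nB <- length(wB)
  ai <- match(graph$gene_a, wA)
  bi <- match(graph$gene_b, wB)
  keep <- !is.na(ai) & !is.na(bi)
  ai <- ai[keep]; bi <- bi[keep]; sc <- graph$norm_score[keep]
  if (length(ai) == 0L)
    stop("no homolog pair links the two windows: no cluster evidence")
  pen <- params$negative_penalty

  # all contiguous spans of window A, as parallel begin/end vectors
  sA1 <- unlist(lapply(seq_len(nA), function(i) rep(i, nA - i + 1L)))
  sA2 <- unlist(lapply(seq_len(nA), function(i) i:nA))
  lenA <- sA2 - sA1 + 1L
  nSA <- length(sA1)

  # unmatched indicator per genome-B gene x genome-A span, prefixed over B
  unmatchedB <- matrix(1L, nrow = nB, ncol = nSA)
  for (b in seq_len(nB)) {
    pos <- ai[bi == b]
    if (length(pos) == 0L) next
    hit <- rep(FALSE, nSA)
    for (p in pos) hit <- hit | (sA1 <= p & p <= sA2)
    unmatchedB[b, ] <- as.integer(!hit)
  }
  prefUB <- rbind(0L, apply(unmatchedB, 2, cumsum))  # (nB+1) x nSA

  best <- NULL
  eps <- 1e-9
  consider <- function(cb, tlen, i1, i2, j1, j2) {
    if (is.null(best) || cb > best$cb + eps ||
        (abs(cb - best$cb) <= eps &&
         (tlen < best$tlen ||
          (tlen == best$tlen &&
           (i1 < best$i1 || (i1 == best$i1 &&
            (j1 < best$j1 || (j1 == best$j1 &&
             (i2 < best$i2 || (i2 == best$i2 && j2 < best$j2))))))))))
      best <<- list(cb = cb, tlen = tlen, i1 = i1, i2 = i2, j1 = j1, j2 = j2)
  }

  for (j1 in seq_len(nB)) {
    bestscore <- rep(-Inf, nA)  # best partner score per A gene, B span j1..j2
    for (j2 in j1:nB) {
      newe <- which(bi == j2)
      for (e in newe)
        if (sc[e] > bestscore[ai[e]]) bestscore[ai[e]] <- sc[e]
      cA <- ifelse(is.finite(bestscore), bestscore, pen)
      prefA <- c(0, cumsum(cA))
      sumA <- prefA[sA2 + 1L] - prefA[sA1]
      ub <- prefUB[j2 + 1L, ] - prefUB[j1, ]
      cb <- sumA + pen * ub
      tl <- lenA + (j2 - j1 + 1L)
      m <- max(cb)
      for (k in which(cb > m - eps))
        consider(cb[k], tl[k], sA1[k], sA2[k], j1, j2)
    }
  }

  i1 <- best$i1; i2 <- best$i2; j1 <- best$j1; j2 <- best$j2
  span_a <- wA[i1:i2]; span_b <- wB[j1:j2]
  # per-gene contributions for the winning span pair
  bestsc <- rep(-Inf, nA)
  for (e in which(bi >= j1 & bi <= j2))
    if (sc[e] > bestsc[ai[e]]) bestsc[ai[e]] <- sc[e]
  contrib_a <- ifelse(is.finite(bestsc[i1:i2]), bestsc[i1:i2], pen)
  names(contrib_a) <- span_a
  matched_b <- vapply(j1:j2, function(b)
    any(bi == b & ai >= i1 & ai <= i2), logical(1))
  contrib_b <- ifelse(matched_b, 0, pen)
  names(contrib_b) <- span_b
  structure(list(i_begin = wA[i1], i_end = wA[i2],
                 j_begin = wB[j1], j_end = wB[j2],
                 span_a = span_a, span_b = span_b,
                 cb_score = sum(contrib_a) + sum(contrib_b),
                 per_gene_contributions = c(contrib_a, contrib_b)),
            class = "boundary_call")
}

#' @export
print.boundary_call <- function(x, ...) {
  cat("boundary_call: genome A ", x$i_begin, "..", x$i_end, " (",
      length(x$span_a), " genes); genome B ", x$j_begin, "..", x$j_end,
      " (", length(x$span_b), " genes); CB = ",
      format(x$cb_score, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Predict a cluster span from two genomes
#'
#' Composition of the comparative stage: [build_homolog_graph()],
#' [detect_seed()], [extend_seed()], [trim_boundaries()]. When no seed block
#' reaches the minimum length, a structured no-cluster result is returned
#' instead of an error.
#'
#' @param genome_a,genome_b [genome_table()] objects.
#' @param align_params an [alignment_params()].
#' @param cluster_params a [cluster_scoring_params()].
#' @return object of class `bgc_prediction`: list with `status`
#'   (`"ok"` or `"no_cluster"`), `call` (a `boundary_call` or `NULL`),
#'   `seed`, `window`, `graph` and the parameter sets used.
#' @export
predict_cluster <- function(genome_a, genome_b,
                            align_params = alignment_params(),
                            cluster_params = cluster_scoring_params()) {
  graph <- build_homolog_graph(genome_a, genome_b, align_params)
  seed <- detect_seed(graph, genome_a, genome_b, cluster_params)
  if (is.null(seed)) {
    return(structure(list(status = "no_cluster", call = NULL, seed = NULL,
                          window = NULL, graph = graph,
                          align_params = align_params,
                          cluster_params = cluster_params),
                     class = "bgc_prediction"))
  }
  window <- extend_seed(seed, genome_a, genome_b, cluster_params)
  call <- trim_boundaries(window, graph, cluster_params)
  structure(list(status = "ok", call = call, seed = seed, window = window,
                 graph = graph, align_params = align_params,
                 cluster_params = cluster_params),
            class = "bgc_prediction")
}

#' @export
print.bgc_prediction <- function(x, ...) {
  if (x$status == "no_cluster") {
    cat("bgc_prediction: no cluster found (no seed block of contiguous",
        "homolog pairs)\n")
  } else {
    cat("bgc_prediction: seed ", length(x$seed$genes_a), " genes (",
        x$seed$genes_a[1], "..",
        x$seed$genes_a[length(x$seed$genes_a)], ")\n", sep = "")
    print(x$call)
  }
  invisible(x)
}

#' Serialize a boundary prediction to JSON
#'
#' @param pred a [predict_cluster()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_boundary_report <- function(pred, path) {
  stopifnot(inherits(pred, "bgc_prediction"))
  rep <- list(status = pred$status,
              params = list(alignment = unclass(pred$align_params),
                            cluster = unclass(pred$cluster_params)))
  if (pred$status == "ok") {
    cl <- pred$call
    rep$seed <- list(genes_a = pred$seed$genes_a,
                     genes_b = pred$seed$genes_b,
                     sum_score = pred$seed$sum_score)
    rep$window <- list(window_a = pred$window$window_a,
                       window_b = pred$window$window_b)
    rep$call <- list(i_begin = cl$i_begin, i_end = cl$i_end,
                     j_begin = cl$j_begin, j_end = cl$j_end,
                     cb_score = cl$cb_score,
                     n_genes_a = length(cl$span_a),
                     n_genes_b = length(cl$span_b))
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
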