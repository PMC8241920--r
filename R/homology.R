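# Cross-genome protein similarity: Smith-Waterman local alignment (affine
# gaps, BLOSUM62 by default), self-score normalization onto [0,1], and
# Karlin-Altschul E-value filtering into the homolog-pair graph.
#
# Parameter disambiguation (important): the residue-level alignment uses
# gap open 11 / extend 1 (BLASTP defaults). The method's published "-0.2
# gap / -0.2 mismatch / -0.3 negative" penalties are GENE-level cluster
# scoring parameters and live in cluster_scoring_params(), not here.

#' Alignment and E-value parameters
#'
#' Residue-level parameters for the protein comparison stage. The affine gap
#' convention is: a gap of length L costs `gap_open + L * gap_extend`. The
#' Karlin-Altschul constants (lambda, K) are the standard gapped BLOSUM62
#' 11/1 values and are applied to the gapped Smith-Waterman score; the
#' E-value model is `E = K * m * n * exp(-lambda * S)`.
#'
#' @param substitution_matrix name of a score matrix shipped with Biostrings
#'   (e.g. `"BLOSUM62"`, `"BLOSUM50"`).
#' @param gap_open,gap_extend positive gap penalties; `gap_open >=
#'   gap_extend` is enforced.
#' @param karlin_lambda,karlin_k positive Karlin-Altschul constants.
#' @param evalue_threshold pairs with E-value below this enter the homolog
#'   graph (default `1.0e-10`).
#' @return list of class `alignment_params`.
#' @export
alignment_params <- function(substitution_matrix = "BLOSUM62",
                             gap_open = 11, gap_extend = 1,
                             karlin_lambda = 0.267, karlin_k = 0.041,
                             evalue_threshold = 1.0e-10) {
  stopifnot(gap_open > 0, gap_extend > 0, gap_open >= gap_extend,
            karlin_lambda > 0, karlin_k > 0, evalue_threshold > 0)
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 karlin_lambda = karlin_lambda, karlin_k = karlin_k,
                 evalue_threshold = evalue_threshold),
            class = "alignment_params")
}

# Fetch a substitution matrix from Biostrings' data sets.
score_matrix <- function(name) {
  e <- new.env()
  ok <- tryCatch({ utils::data(list = name, package = "Biostrings",
                               envir = e); TRUE },
                 warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = e))
    stop("unknown substitution matrix: ", name)
  get(name, envir = e)
}

check_seq <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) ||
      nchar(seq) == 0L)
    stop(what, " must be a single non-empty string")
  sanitize_protein(seq)
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score of two protein sequences under affine gap
#' penalties. Residues outside the 20 standard amino acids are treated as
#' `X` and scored with the matrix's `X` column. Scores are clamped at 0 (the
#' empty local alignment).
#'
#' @param seq_a,seq_b protein sequences (single strings).
#' @param params an [alignment_params()].
#' @return single non-negative number, the optimal local alignment score.
#' @export
#' @examples
#' smith_waterman("ACDEFGHIK", "ACDEFGHIK")  # sum of BLOSUM62 diagonal
#' smith_waterman("AAAA", "WWWW")            # 0: all substitutions negative
smith_waterman <- function(seq_a, seq_b, params = alignment_params()) {
  seq_a <- check_seq(seq_a, "seq_a")
  seq_b <- check_seq(seq_b, "seq_b")
  mat <- score_matrix(params$substitution_matrix)
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "local", substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE)
  max(0, s)
}

# Vectorized SW of one subject against a set of patterns (scores only).
sw_score_set <- function(patterns, subject, params) {
  mat <- score_matrix(params$substitution_matrix)
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE)
  pmax(0, s)
}

#' Self-score-normalized similarity
#'
#' `raw / min(self_a, self_b)`, where `self_x` is the Smith-Waterman score
#' of `x` against itself. The minimum-self-score convention keeps an exact
#' fragment of a longer partner at similarity 1.0 — deliberate tolerance for
#' split/fragment mis-annotations — and puts the score on `[0, 1]`, the unit
#' scale of the gene-level cluster penalties.
#'
#' @inheritParams smith_waterman
#' @return number in `[0, 1]`.
#' @export
normalized_score <- function(seq_a, seq_b, params = alignment_params()) {
  raw <- smith_waterman(seq_a, seq_b, params)
  if (raw <= 0) return(0)
  self_a <- smith_waterman(seq_a, seq_a, params)
  self_b <- smith_waterman(seq_b, seq_b, params)
  lo <- min(self_a, self_b)
  if (lo <= 0) return(0)
  min(1, raw / lo)
}

#' Karlin-Altschul E-value of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` for sequence lengths m, n and score S.
#' Strictly decreasing in S; linear in `m * n`.
#'
#' @param raw_score non-negative alignment score.
#' @param len_a,len_b sequence lengths (>= 1).
#' @inheritParams smith_waterman
#' @return non-negative number.
#' @export
evalue <- function(raw_score, len_a, len_b, params = alignment_params()) {
  stopifnot(raw_score >= 0, len_a >= 1, len_b >= 1)
  params$karlin_k * len_a * len_b * exp(-params$karlin_lambda * raw_score)
}

#' Build the cross-genome homolog-pair graph
#'
#' All-vs-all Smith-Waterman comparison of two proteomes; every cross-genome
#' gene pair whose alignment E-value falls below `params$evalue_threshold`
#' becomes an edge. One-to-many pairs are retained, so both halves of a
#' split (mis-annotated) gene pair with their single full-length partner.
#'
#' @param genome_a,genome_b [genome_table()] objects.
#' @param params an [alignment_params()].
#' @return object of class `homolog_graph`: data frame with columns
#'   `gene_a`, `gene_b`, `raw_score`, `norm_score`, `evalue`, and attributes
#'   `genome_a`, `genome_b`, `params`.
#' @export
build_homolog_graph <- function(genome_a, genome_b,
                                params = alignment_params()) {
  stopifnot(inherits(genome_a, "genome_table"),
            inherits(genome_b, "genome_table"))
  if (length(genome_a$proteome) == 0L || length(genome_b$proteome) == 0L)
    stop("cannot build homolog graph from an empty proteome")

  ga <- genome_a$genes; gb <- genome_b$genes
  prot_a <- unname(genome_a$proteome[ga$protein_id])
  prot_b <- unname(genome_b$proteome[gb$protein_id])
  len_a <- nchar(prot_a); len_b <- nchar(prot_b)

  self_a <- vapply(seq_len(nrow(ga)), function(i)
    smith_waterman(prot_a[i], prot_a[i], params), numeric(1))
  self_b <- vapply(seq_len(nrow(gb)), function(j)
    smith_waterman(prot_b[j], prot_b[j], params), numeric(1))

  rows <- vector("list", nrow(gb))
  for (j in seq_len(nrow(gb))) {
    raw <- sw_score_set(prot_a, prot_b[j], params)
    ev <- params$karlin_k * len_a * len_b[j] *
      exp(-params$karlin_lambda * raw)
    keep <- which(ev < params$evalue_threshold)
    if (length(keep) == 0L) next
    lo <- pmin(self_a[keep], self_b[j])
    norm <- ifelse(raw[keep] <= 0 | lo <= 0, 0,
                   pmin(1, raw[keep] / lo))
    rows[[j]] <- data.frame(gene_a = ga$gene_id[keep],
                            gene_b = gb$gene_id[j],
                            raw_score = raw[keep],
                            norm_score = norm,
                            evalue = ev[keep],
                            stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(pairs))
    pairs <- data.frame(gene_a = character(), gene_b = character(),
                        raw_score = numeric(), norm_score = numeric(),
                        evalue = numeric(), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(pairs, class = c("homolog_graph", "data.frame"),
            genome_a = genome_a$genome_id, genome_b = genome_b$genome_id,
            params = params)
}

#' Write / read a homolog graph as TSV
#'
#' @param graph a `homolog_graph`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_homolog_graph <- function(graph, path) {
  utils::write.table(as.data.frame(graph), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_homolog_graph
#' @param genome_a,genome_b genome ids to attach (metadata only).
#' @export
read_homolog_graph <- function(path, genome_a = NA, genome_b = NA) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(tab, class = c("homolog_graph", "data.frame"),
            genome_a = genome_a, genome_b = genome_b, params = NULL)
}
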