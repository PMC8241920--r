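# Small in-code builders shared across test files.

# A toy genome table with n genes on one contig and trivial proteins.
toy_genome <- function(ids, genome_id = "toy", contig = "chr1",
                       proteins = NULL) {
  if (is.null(proteins))
    proteins <- setNames(rep("MKVLAASTW", length(ids)),
                         paste0(ids, "_p"))
  g <- data.frame(gene_id = ids, contig = contig,
                  start = 1 + (seq_along(ids) - 1) * 1000,
                  end = 900 + (seq_along(ids) - 1) * 1000,
                  strand = "+", protein_id = paste0(ids, "_p"),
                  stringsAsFactors = FALSE)
  genome_table(genome_id, g, proteins)
}

# Wrap a plain pairs data frame as a homolog_graph.
mk_graph <- function(gene_a, gene_b, norm_score,
                     raw_score = norm_score * 100, evalue = 1e-30) {
  structure(data.frame(gene_a = gene_a, gene_b = gene_b,
                       raw_score = raw_score, norm_score = norm_score,
                       evalue = rep_len(evalue, length(gene_a)),
                       stringsAsFactors = FALSE),
            class = c("homolog_graph", "data.frame"),
            genome_a = "A", genome_b = "B", params = NULL)
}

# Wrap ordered id vectors as an extended_window.
mk_window <- function(window_a, window_b) {
  structure(list(window_a = window_a, window_b = window_b, seed = NULL),
            class = "extended_window")
}

# A noise-free CT table for two strains, one reference gene.
mk_ct <- function(genes_ct_wt, genes_ct_mut, ref_ct = 20, n_bio = 3,
                  n_tech = 3, case = "mut", calibrator = "wt") {
  rows <- list()
  add <- function(strain, gene, ct) {
    for (b in seq_len(n_bio)) for (t in seq_len(n_tech))
      rows[[length(rows) + 1]] <<- data.frame(
        strain = strain, gene = gene, bio_rep = b, tech_rep = t, ct = ct,
        stringsAsFactors = FALSE)
  }
  for (g in names(genes_ct_wt)) add(calibrator, g, genes_ct_wt[[g]])
  for (g in names(genes_ct_mut)) add(case, g, genes_ct_mut[[g]])
  add(calibrator, "ref", ref_ct); add(case, "ref", ref_ct)
  do.call(rbind, rows)
}

# The small planted-orthology configuration used for seeded recovery
# properties (locus-scale problems keep the alignment stage fast).
small_pair_config <- function(seed, order = "syntenic") {
  lay <- data.frame(
    gene_a = paste0("cg", 1:6),
    partner = c("single", "single", "none", "split", "single", "single"),
    identity = c(0.45, 0.60, NA, 0.80, 0.90, 0.75),
    stringsAsFactors = FALSE)
  genome_pair_config(lay, background_a = 6, background_b = 6,
                     partner_order = order,
                     preserved_block = if (order == "block_shuffled")
                       c("cg4", "cg5") else NULL,
                     protein_len_range = c(250, 350), seed = seed)
}
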