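# Domain types: gene tables, genome tables, and the canonical M7 locus
# registry. Gene order is defined purely by (contig, start); strand is kept
# as annotation only, since all downstream arithmetic works on gene ranks.

AA_STANDARD <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

#' Construct a genome table from a gene data frame and a proteome
#'
#' A `genome_table` is the package's container for one annotated genome (or
#' genomic locus): an ordered gene table plus the deduced proteome. Genes are
#' sorted by (contig, start) and assigned a 0-based `order_index`; all
#' boundary arithmetic operates on these ranks.
#'
#' @param genome_id single string identifying the genome.
#' @param genes data frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`, `protein_id`. Coordinates are 1-based inclusive (GFF
#'   convention). A `genome_id` column, if present, must agree with
#'   `genome_id`.
#' @param proteome named character vector or [Biostrings::AAStringSet] of
#'   amino-acid sequences keyed by `protein_id`. Residues outside the 20
#'   standard amino acids are coerced to `X`.
#' @return object of class `genome_table`: list with elements `genome_id`,
#'   `genes` (data frame with `order_index` added) and `proteome` (named
#'   character vector).
#' @export
#' @examples
#' g <- data.frame(gene_id = c("g1", "g2"), contig = "chr1",
#'                 start = c(1, 2000), end = c(900, 2900),
#'                 strand = "+", protein_id = c("p1", "p2"))
#' gt <- genome_table("toy", g, c(p1 = "MKVL", p2 = "MSTA"))
#' gt$genes$order_index
genome_table <- function(genome_id, genes, proteome) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  req <- c("gene_id", "contig", "start", "end", "strand", "protein_id")
  miss <- setdiff(req, names(genes))
  if (length(miss) > 0L)
    stop("gene table is missing column(s): ", paste(miss, collapse = ", "))
  if ("genome_id" %in% names(genes) &&
      !all(genes$genome_id == genome_id))
    stop("gene table genome_id column disagrees with '", genome_id, "'")
  genes <- as.data.frame(genes)[, req]
  genes$start <- as.integer(genes$start)
  genes$end   <- as.integer(genes$end)

  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0L)
    stop("duplicate gene_id in genome '", genome_id, "': ",
         paste(unique(dup), collapse = ", "))
  if (any(genes$start < 1L)) stop("gene start coordinates must be >= 1")
  if (any(genes$end < genes$start)) stop("gene end must be >= start")
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")

  if (inherits(proteome, "AAStringSet")) proteome <- as.character(proteome)
  if (is.null(names(proteome)) || any(names(proteome) == ""))
    stop("proteome sequences must be named by protein_id")
  absent <- setdiff(genes$protein_id, names(proteome))
  if (length(absent) > 0L) {
    offender <- genes$gene_id[match(absent[1L], genes$protein_id)]
    stop("gene '", offender, "' references protein '", absent[1L],
         "' absent from the proteome")
  }
  proteome <- vapply(proteome, sanitize_protein, character(1))
  if (any(nchar(proteome) == 0L)) stop("empty protein sequence in proteome")

  ord <- order(genes$contig, genes$start)
  genes <- genes[ord, , drop = FALSE]
  genes$order_index <- seq_len(nrow(genes)) - 1L
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id, genes = genes,
                 proteome = proteome[unique(genes$protein_id)]),
            class = "genome_table")
}

# Uppercase and coerce any non-standard residue to X.
sanitize_protein <- function(seq) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  chars[!(chars %in% AA_STANDARD) & chars != "X"] <- "X"
  paste(chars, collapse = "")
}

#' @export
print.genome_table <- function(x, ...) {
  cat("genome_table '", x$genome_id, "': ", nrow(x$genes), " genes on ",
      length(unique(x$genes$contig)), " contig(s), ",
      length(x$proteome), " proteins\n", sep = "")
  invisible(x)
}

#' Load a genome table from a gene TSV and a protein FASTA
#'
#' The normative fixture format: a tab-separated gene table with header
#' columns `genome_id`, `gene_id`, `contig`, `start`, `end`, `strand`,
#' `protein_id`, and a FASTA proteome keyed by `protein_id`.
#'
#' @param gene_table_path path to the TSV gene table.
#' @param fasta_path path to the protein FASTA.
#' @return a [genome_table()].
#' @export
load_genome <- function(gene_table_path, fasta_path) {
  if (!file.exists(gene_table_path)) stop("no such file: ", gene_table_path)
  if (!file.exists(fasta_path)) stop("no such file: ", fasta_path)
  tab <- utils::read.delim(gene_table_path, stringsAsFactors = FALSE)
  if (!"genome_id" %in% names(tab)) stop("gene table lacks genome_id column")
  gid <- unique(tab$genome_id)
  if (length(gid) != 1L) stop("gene table must describe exactly one genome")
  prot <- Biostrings::readAAStringSet(fasta_path)
  names(prot) <- sub("\\s.*$", "", names(prot))
  genome_table(gid, tab, prot)
}

#' Write a genome table to a gene TSV and a protein FASTA
#'
#' Inverse of [load_genome()]; writing then re-reading preserves gene order
#' and sequences exactly.
#'
#' @param genome a [genome_table()].
#' @param gene_table_path,fasta_path output paths.
#' @return invisibly, the two paths.
#' @export
write_genome <- function(genome, gene_table_path, fasta_path) {
  stopifnot(inherits(genome, "genome_table"))
  tab <- genome$genes
  tab$genome_id <- genome$genome_id
  tab <- tab[, c("genome_id", "gene_id", "contig", "start", "end",
                 "strand", "protein_id")]
  utils::write.table(tab, gene_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(genome$proteome), fasta_path)
  invisible(c(gene_table_path, fasta_path))
}

#' Inclusive ordered span of genes between two endpoints
#'
#' @param genome a [genome_table()].
#' @param from_gene,to_gene gene ids on the same contig, `from_gene` not
#'   after `to_gene` in gene order.
#' @return data frame of the gene records from `from_gene` to `to_gene`
#'   inclusive, in gene order.
#' @export
#' @examples
#' reg <- locus_registry()
#' # the 16-gene core span of the M7 pigment locus:
#' nrow_span <- length(span_gene_names(reg, "mrpigA", "mrpigP"))
span_genes <- function(genome, from_gene, to_gene) {
  stopifnot(inherits(genome, "genome_table"))
  g <- genome$genes
  i <- match(from_gene, g$gene_id)
  j <- match(to_gene, g$gene_id)
  if (is.na(i)) stop("unknown gene: ", from_gene)
  if (is.na(j)) stop("unknown gene: ", to_gene)
  if (g$contig[i] != g$contig[j])
    stop("genes '", from_gene, "' and '", to_gene,
         "' lie on different contigs")
  if (g$order_index[i] > g$order_index[j])
    stop("'", from_gene, "' does not precede '", to_gene, "'")
  g[g$order_index >= g$order_index[i] & g$order_index <= g$order_index[j], ,
    drop = FALSE]
}

#' The canonical M7 azaphilone-pigment locus registry
#'
#' Ordered names of the 20-gene locus centred on the pigment polyketide
#' synthase: two upstream flanks, the 16 lettered cluster genes
#' `mrpigA`..`mrpigP`, and two downstream flanks, with short predicted
#' function annotations.
#'
#' @return object of class `locus_registry`: list with `genes` (ordered
#'   character vector of 20 names) and `annotation` (named character vector).
#' @export
locus_registry <- function() {
  core <- paste0("mrpig", LETTERS[1:16])
  genes <- c("mrpigAup2", "mrpigAup1", core, "mrpigPdown1", "mrpigPdown2")
  ann <- c(
    mrpigAup2   = "upstream flank; not part of the pigment cluster",
    mrpigAup1   = "upstream flank; regulator-responsive but dispensable",
    mrpigA      = "non-reducing polyketide synthase (pigment core scaffold)",
    mrpigB      = "pathway-specific Zn(II)2Cys6 transcriptional regulator",
    mrpigC      = "C11-ketoreductase",
    mrpigD      = "biosynthetic enzyme (pigment maturation)",
    mrpigE      = "biosynthetic enzyme (pigment maturation)",
    mrpigF      = "biosynthetic oxidase",
    mrpigG      = "biosynthetic enzyme",
    mrpigH      = "biosynthetic enzyme",
    mrpigI      = "transcription factor with no apparent pigment role",
    mrpigJ      = "fatty acid synthase subunit",
    mrpigK      = "fatty acid synthase subunit",
    mrpigL      = "ankyrin repeat protein; no pigment role",
    mrpigM      = "biosynthetic enzyme",
    mrpigN      = "biosynthetic enzyme",
    mrpigO      = "deacetylase directing azaphilone ring cyclization",
    mrpigP      = "MFS transporter (co-metabolite export)",
    mrpigPdown1 = "downstream flank; regulator-responsive but dispensable",
    mrpigPdown2 = "downstream flank; not part of the pigment cluster"
  )
  stopifnot(identical(genes, names(ann)))
  structure(list(genes = genes, annotation = ann), class = "locus_registry")
}

#' Names between two registry genes, inclusive
#'
#' @param registry a [locus_registry()].
#' @param from_gene,to_gene registry gene names.
#' @return character vector of names from `from_gene` to `to_gene`.
#' @export
span_gene_names <- function(registry, from_gene, to_gene) {
  stopifnot(inherits(registry, "locus_registry"))
  i <- match(from_gene, registry$genes)
  j <- match(to_gene, registry$genes)
  if (is.na(i) || is.na(j)) stop("gene name not in registry")
  if (i > j) stop("'", from_gene, "' does not precede '", to_gene, "'")
  registry$genes[i:j]
}
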