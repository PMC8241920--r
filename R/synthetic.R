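# Seeded generators for every input the pipeline consumes: genome pairs
# with planted orthology/synteny structure, qPCR CT tables with planted
# regulation classes, and knockout metabolite profiles. Every generator is
# a pure function of its config plus seed. Named fixtures emulate the
# M. ruber M7 azaphilone locus study conditions:
#   m7_atcc18224    syntenic partner cluster, three unpartnered interior
#                   genes (F, O, L), one partner split in two fragments
#   pm1_nonsyntenic block-shuffled partner cluster (14 genes) with one
#                   preserved 3-gene block for seeding
#   qpcr_panel      CT table with planted regulation classes
#   knockout_panel  knockout metabolite-profile panel (8 strains)

#' Random protein sequence
#'
#' Uniform draw over the 20 standard residues, using the current RNG state.
#'
#' @param len sequence length.
#' @return a single string.
#' @export
random_protein <- function(len) {
  paste(sample(AA_STANDARD, len, replace = TRUE), collapse = "")
}

#' Mutate a protein to a target percent identity
#'
#' Substitutes residues at uniformly chosen positions (each substitution
#' drawn from the 19 residues other than the original) so that the realized
#' identity is within 0.03 of the target. Length is always preserved.
#'
#' @param protein protein sequence (single string).
#' @param target_identity number in `[0.2, 1]`.
#' @param seed optional integer; when given, seeds the RNG first. Leave
#'   `NULL` inside larger generators to consume their stream.
#' @return the mutated sequence.
#' @export
mutate_to_identity <- function(protein, target_identity, seed = NULL) {
  stopifnot(target_identity >= 0.2, target_identity <= 1)
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(protein, "")[[1]]
  L <- length(chars)
  k <- round((1 - target_identity) * L)
  realized <- 1 - k / L
  if (abs(realized - target_identity) > 0.03)
    stop("sequence too short (", L, " aa) to reach identity ",
         target_identity, " within 0.03")
  if (k == 0L) return(protein)
  pos <- sample(L, k)
  for (p in pos)
    chars[p] <- sample(setdiff(AA_STANDARD, chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Genome-pair generator configuration
#'
#' @param cluster_layout data frame with columns `gene_a` (genome-A gene
#'   name), `partner` (`"none"`, `"single"` or `"split"`) and `identity`
#'   (planted identity in `[0.3, 1]`; ignored for `"none"`).
#' @param background_a,background_b number of unrelated background genes in
#'   each genome, split evenly around the cluster.
#' @param partner_order `"syntenic"`, or `"block_shuffled"` to permute the
#'   genome-B partner genes (split fragments travel together) while keeping
#'   `preserved_block` contiguous and in order.
#' @param preserved_block genome-A gene names whose partners stay a
#'   contiguous, ordered block under shuffling (the seeding anchor). Must
#'   name at least `min_seed_len` consecutive layout genes when shuffling.
#' @param protein_len_range inclusive range of protein lengths (default
#'   250..450).
#' @param partner_prefix prefix for genome-B gene ids (default `"tm_"`).
#' @param seed integer RNG seed.
#' @return list of class `genome_pair_config`.
#' @export
genome_pair_config <- function(cluster_layout,
                               background_a = 20, background_b = 20,
                               partner_order = c("syntenic",
                                                 "block_shuffled"),
                               preserved_block = NULL,
                               protein_len_range = c(250, 450),
                               partner_prefix = "tm_",
                               seed = 1) {
  partner_order <- match.arg(partner_order)
  stopifnot(all(c("gene_a", "partner", "identity") %in%
                  names(cluster_layout)),
            all(cluster_layout$partner %in% c("none", "single", "split")))
  with_p <- cluster_layout$partner != "none"
  stopifnot(all(cluster_layout$identity[with_p] >= 0.3),
            all(cluster_layout$identity[with_p] <= 1))
  if (partner_order == "block_shuffled") {
    if (is.null(preserved_block) || length(preserved_block) < 1L)
      stop("block_shuffled order requires a preserved_block")
    idx <- match(preserved_block, cluster_layout$gene_a)
    if (anyNA(idx) || any(diff(idx) != 1L))
      stop("preserved_block must name consecutive layout genes")
  }
  structure(list(cluster_layout = cluster_layout,
                 background_a = as.integer(background_a),
                 background_b = as.integer(background_b),
                 partner_order = partner_order,
                 preserved_block = preserved_block,
                 protein_len_range = protein_len_range,
                 partner_prefix = partner_prefix,
                 seed = as.integer(seed)),
            class = "genome_pair_config")
}

make_gene_df <- function(genome_id, contig, gene_ids, prot_ids, strands) {
  n <- length(gene_ids)
  starts <- 1L + (seq_len(n) - 1L) * 2000L
  data.frame(genome_id = genome_id, gene_id = gene_ids, contig = contig,
             start = starts, end = starts + 1200L, strand = strands,
             protein_id = prot_ids, stringsAsFactors = FALSE)
}

#' Generate a synthetic genome pair with planted orthology
#'
#' Genome A carries the cluster layout contiguously, bracketed by unrelated
#' background genes. Genome B carries one partner gene per `"single"`
#' layout entry (mutated to the planted identity) and two consecutive
#' fragment genes covering the front and back halves of the partner protein
#' per `"split"` entry, in syntenic or block-shuffled order, likewise
#' bracketed by background genes. Fully reproducible from the config seed.
#'
#' @param config a [genome_pair_config()].
#' @return list with `genome_a`, `genome_b` ([genome_table()]s) and `truth`
#'   (data frame of planted pairs: `gene_a`, `gene_b`, `identity`).
#' @export
generate_genome_pair <- function(config) {
  stopifnot(inherits(config, "genome_pair_config"))
  set.seed(config$seed)
  lay <- config$cluster_layout
  rng <- config$protein_len_range
  rlen <- function(n) sample(rng[1]:rng[2], n, replace = TRUE)

  # genome A: background halves around the cluster layout
  n_up <- config$background_a %/% 2L
  n_dn <- config$background_a - n_up
  bg_up <- sprintf("A_bg%02d", seq_len(n_up))
  bg_dn <- sprintf("A_bg%02d", n_up + seq_len(n_dn))
  ids_a <- c(bg_up, lay$gene_a, bg_dn)
  prot_a <- vapply(rlen(length(ids_a)), random_protein, character(1))
  names(prot_a) <- paste0(ids_a, "_p")
  genome_a <- genome_table(
    "genomeA",
    make_gene_df("genomeA", "chrA", ids_a, names(prot_a),
                 sample(c("+", "-"), length(ids_a), replace = TRUE)),
    prot_a)

  # genome B partner units (a split partner is one unit of two genes)
  units <- list()
  truth <- list()
  pref <- config$partner_prefix
  for (i in seq_len(nrow(lay))) {
    ga <- lay$gene_a[i]
    if (lay$partner[i] == "none") next
    parent <- prot_a[[paste0(ga, "_p")]]
    mut <- mutate_to_identity(parent, lay$identity[i])
    if (lay$partner[i] == "single") {
      gb <- paste0(pref, ga)
      units[[length(units) + 1L]] <- list(anchor = ga, genes = gb,
                                          prots = stats::setNames(
                                            list(mut), paste0(gb, "_p")))
      truth[[length(truth) + 1L]] <-
        data.frame(gene_a = ga, gene_b = gb, identity = lay$identity[i],
                   stringsAsFactors = FALSE)
    } else {
      half <- nchar(mut) %/% 2L
      gb <- paste0(pref, ga, c("_f1", "_f2"))
      frags <- c(substr(mut, 1L, half),
                 substr(mut, half + 1L, nchar(mut)))
      units[[length(units) + 1L]] <- list(anchor = ga, genes = gb,
                                          prots = stats::setNames(
                                            as.list(frags),
                                            paste0(gb, "_p")))
      truth[[length(truth) + 1L]] <-
        data.frame(gene_a = ga, gene_b = gb, identity = lay$identity[i],
                   stringsAsFactors = FALSE)
    }
  }

  if (config$partner_order == "block_shuffled") {
    anchors <- vapply(units, `[[`, character(1), "anchor")
    pres <- which(anchors %in% config$preserved_block)
    if (length(pres) > 0L && any(diff(pres) != 1L))
      stop("preserved_block partners are not consecutive units")
    # collapse the preserved block into one super-unit, then permute;
    # split-fragment units stay interior, mirroring the real locus where
    # the mis-annotated gene sits inside the cluster
    items <- c(list(unlist(pres)),
               as.list(setdiff(seq_along(units), pres)))
    items <- items[lengths(items) > 0L]
    is_split <- vapply(units, function(u) length(u$genes) > 1L, logical(1))
    for (try in 1:1000) {
      perm <- sample(length(items))
      ord <- unlist(items[perm])
      if (!is_split[ord[1L]] && !is_split[ord[length(ord)]]) break
      if (try == 1000L)
        stop("cannot place split-fragment units away from cluster ends")
    }
    units <- units[ord]
  }

  prot_b_cluster <- do.call(c, lapply(units, `[[`, "prots"))
  ids_b_cluster <- unlist(lapply(units, `[[`, "genes"))

  n_up_b <- config$background_b %/% 2L
  n_dn_b <- config$background_b - n_up_b
  bgb_up <- sprintf("B_bg%02d", seq_len(n_up_b))
  bgb_dn <- sprintf("B_bg%02d", n_up_b + seq_len(n_dn_b))
  bg_prots <- vapply(rlen(n_up_b + n_dn_b), random_protein, character(1))
  names(bg_prots) <- paste0(c(bgb_up, bgb_dn), "_p")
  ids_b <- c(bgb_up, ids_b_cluster, bgb_dn)
  prot_b <- c(bg_prots[paste0(bgb_up, "_p")],
              unlist(prot_b_cluster),
              bg_prots[paste0(bgb_dn, "_p")])
  genome_b <- genome_table(
    "genomeB",
    make_gene_df("genomeB", "chrB", ids_b, paste0(ids_b, "_p"),
                 sample(c("+", "-"), length(ids_b), replace = TRUE)),
    prot_b)

  list(genome_a = genome_a, genome_b = genome_b,
       truth = do.call(rbind, truth), config = config)
}

#' Expression-design configuration for CT-table generation
#'
#' @param genes data frame with columns `gene`, `true_fc` (planted fold
#'   change, case vs calibrator) and `not_expressed` (logical).
#' @param ref_gene reference gene name (planted fold change 1).
#' @param strain_case,strain_calibrator strain labels.
#' @param n_bio,n_tech biological / technical replicates (defaults 3, 3).
#' @param bio_sd sample-level biological noise, CT units (default 0.3):
#'   a per-(strain, biological replicate) offset shared by every gene in
#'   that cDNA sample — the component that reference-gene normalization
#'   removes.
#' @param tech_sd per-well technical noise, CT units (default 0.15).
#' @param ref_base_ct reference gene base CT (default 20).
#' @param target_base_range base CT range for target genes (default 22..26).
#' @param seed integer RNG seed.
#' @return list of class `expression_design`.
#' @export
expression_design <- function(genes, ref_gene = "GAPDH",
                              strain_case = "dmrpigB",
                              strain_calibrator = "M7",
                              n_bio = 3, n_tech = 3,
                              bio_sd = 0.3, tech_sd = 0.15,
                              ref_base_ct = 20,
                              target_base_range = c(22, 26),
                              seed = 1) {
  stopifnot(all(c("gene", "true_fc", "not_expressed") %in% names(genes)),
            n_bio >= 2, n_tech >= 1, bio_sd >= 0, tech_sd >= 0)
  structure(list(genes = genes, ref_gene = ref_gene,
                 strain_case = strain_case,
                 strain_calibrator = strain_calibrator,
                 n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
                 bio_sd = bio_sd, tech_sd = tech_sd,
                 ref_base_ct = ref_base_ct,
                 target_base_range = target_base_range,
                 seed = as.integer(seed)),
            class = "expression_design")
}

#' Generate a CT table from an expression design
#'
#' Calibrator-strain target CT is the gene's base CT plus the sample offset
#' plus well noise; the case strain adds `-log2(true_fc)` to the target
#' base. The reference gene has planted fold change 1. Genes flagged
#' `not_expressed` are undetermined (`NA`) in both strains.
#'
#' @param design an [expression_design()].
#' @return CT data frame with columns `strain`, `gene`, `bio_rep`,
#'   `tech_rep`, `ct`.
#' @export
generate_ct_table <- function(design) {
  stopifnot(inherits(design, "expression_design"))
  set.seed(design$seed)
  genes <- rbind(design$genes,
                 data.frame(gene = design$ref_gene, true_fc = 1,
                            not_expressed = FALSE, stringsAsFactors = FALSE))
  base <- stats::runif(nrow(genes), design$target_base_range[1],
                       design$target_base_range[2])
  base[genes$gene == design$ref_gene] <- design$ref_base_ct
  strains <- c(design$strain_calibrator, design$strain_case)
  offs <- matrix(stats::rnorm(2 * design$n_bio, 0, design$bio_sd),
                 nrow = 2, dimnames = list(strains, NULL))
  rows <- expand.grid(tech_rep = seq_len(design$n_tech),
                      bio_rep = seq_len(design$n_bio),
                      gene_i = seq_len(nrow(genes)),
                      strain = strains,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  shift <- ifelse(rows$strain == design$strain_case &
                    genes$gene[rows$gene_i] != design$ref_gene,
                  -log2(genes$true_fc[rows$gene_i]), 0)
  mu <- base[rows$gene_i] +
    offs[cbind(match(rows$strain, strains), rows$bio_rep)] + shift
  ct <- mu + stats::rnorm(nrow(rows), 0, design$tech_sd)
  ct[genes$not_expressed[rows$gene_i]] <- NA_real_
  out <- data.frame(strain = rows$strain, gene = genes$gene[rows$gene_i],
                    bio_rep = rows$bio_rep, tech_rep = rows$tech_rep,
                    ct = ct, stringsAsFactors = FALSE)
  out[order(out$strain, out$gene, out$bio_rep, out$tech_rep), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Generate a panel of knockout metabolite profiles
#'
#' Wild-type core amounts are fixed positive constants; each mutant strain
#' applies its planted phenotype template (per-compound multipliers and
#' shunt amounts) with multiplicative log-normal noise.
#'
#' @param config list with elements `wt_amounts` (named vector over
#'   compounds), `strains` (named list: strain -> named multiplier vector
#'   over compounds, absolute amounts for shunt compounds) and `noise_sd`
#'   (log-scale sd, default 0.05).
#' @param seed integer RNG seed.
#' @return list with `wt` (a [metabolite_profile()]) and `mutants` (named
#'   list of profiles).
#' @export
generate_knockout_profiles <- function(config, seed = 1) {
  set.seed(seed)
  reg <- compound_registry()
  noise_sd <- if (is.null(config$noise_sd)) 0.05 else config$noise_sd
  jitter <- function(x) x * exp(stats::rnorm(length(x), 0, noise_sd))
  wt <- metabolite_profile("M7", jitter(config$wt_amounts), reg)
  mutants <- lapply(names(config$strains), function(s) {
    spec <- config$strains[[s]]
    amt <- config$wt_amounts
    amt[] <- 0
    mult <- spec$mult
    amt[names(mult)] <- config$wt_amounts[names(mult)] * mult
    if (!is.null(spec$shunt)) amt[names(spec$shunt)] <- spec$shunt
    metabolite_profile(s, jitter(amt), reg)
  })
  list(wt = wt, mutants = stats::setNames(mutants, names(config$strains)))
}

# ---- named fixtures -------------------------------------------------------

m7_cluster_layout <- function() {
  reg <- locus_registry()
  partner <- stats::setNames(rep("single", 20), reg$genes)
  partner[c("mrpigAup2", "mrpigAup1", "mrpigF", "mrpigL", "mrpigO",
            "mrpigPdown1", "mrpigPdown2")] <- "none"
  partner["mrpigH"] <- "split"
  identity <- stats::setNames(rep(NA_real_, 20), reg$genes)
  # the seed block (G..K) is the most conserved stretch by construction;
  # the remaining partnered genes sit at moderate identity
  identity[c("mrpigG", "mrpigH", "mrpigI", "mrpigJ", "mrpigK")] <-
    c(0.88, 0.90, 0.85, 0.90, 0.87)
  identity[c("mrpigA", "mrpigB", "mrpigC", "mrpigD", "mrpigE")] <-
    c(0.75, 0.65, 0.72, 0.70, 0.68)
  identity[c("mrpigM", "mrpigN", "mrpigP")] <- c(0.75, 0.72, 0.70)
  data.frame(gene_a = reg$genes, partner = unname(partner[reg$genes]),
             identity = unname(identity[reg$genes]),
             stringsAsFactors = FALSE)
}

qpcr_panel_design <- function(seed) {
  reg <- locus_registry()
  abolished <- paste0("mrpig", c("A", "H", "M", "N", "O", "P"))
  down <- c(paste0("mrpig", c("D", "E", "F", "G")),
            "mrpigAup1", "mrpigPdown1")
  notexp <- "mrpigI"
  genes <- setdiff(reg$genes, "mrpigB")
  fc <- stats::setNames(rep(1, length(genes)), genes)
  fc[abolished] <- 0.02
  fc[down] <- 0.4
  expression_design(
    data.frame(gene = genes, true_fc = unname(fc),
               not_expressed = genes %in% notexp,
               stringsAsFactors = FALSE),
    seed = seed)
}

knockout_panel_config <- function() {
  core_mult <- function(m1, m2, m3, m4)
    list(mult = c(`1` = m1, `2` = m2, `3` = m3, `4` = m4))
  unchanged <- core_mult(1, 1, 1, 1)
  list(
    wt_amounts = c(`1` = 120, `2` = 100, `3` = 80, `4` = 90,
                   `5` = 0, `6` = 0),
    strains = list(
      dmrpigAup2   = unchanged,
      dmrpigAup1   = unchanged,
      dmrpigA      = core_mult(0, 0, 0, 0),
      dmrpigO      = c(core_mult(0, 0, 0, 0),
                       list(shunt = c(`5` = 30, `6` = 25))),
      dmrpigP      = core_mult(2.2, 0.45, 2.2, 0.45),
      dmrpigPdown1 = unchanged,
      dmrpigPdown2 = unchanged),
    noise_sd = 0.05)
}

#' Named synthetic fixtures emulating the study conditions
#'
#' \describe{
#'   \item{`m7_atcc18224`}{genome pair: the 20-gene locus (plus 20
#'     background genes) in genome A; syntenic partners in genome B for the
#'     lettered cluster genes except `mrpigF`, `mrpigO`, `mrpigL`; the
#'     `mrpigH` partner split into two fragment genes; flanks unpartnered.}
#'   \item{`pm1_nonsyntenic`}{same layout, but the 14 genome-B cluster
#'     genes are block-shuffled with the `mrpigI`..`mrpigK` partner block
#'     preserved for seeding.}
#'   \item{`qpcr_panel`}{CT table with planted classes: 6 abolished (fc 0.02:
#'     A, H, M, N, O, P), 6 downregulated (fc 0.4: D, E, F, G, Aup1,
#'     Pdown1), 6 unchanged (Aup2, C, J, K, L, Pdown2), `mrpigI` not
#'     expressed.}
#'   \item{`knockout_panel`}{knockout profile panel: wild type plus 7 mutants
#'     (abolished dmrpigA; shunt dmrpigO; ratio-shift dmrpigP; four
#'     unchanged border knockouts).}
#' }
#'
#' @param name fixture name.
#' @param seed integer RNG seed.
#' @return fixture contents; see each description.
#' @export
bgc_fixture <- function(name = c("m7_atcc18224", "pm1_nonsyntenic",
                                 "qpcr_panel", "knockout_panel"), seed = 42) {
  name <- match.arg(name)
  switch(name,
    m7_atcc18224 = generate_genome_pair(genome_pair_config(
      m7_cluster_layout(), background_a = 20, background_b = 20,
      partner_order = "syntenic", seed = seed)),
    pm1_nonsyntenic = generate_genome_pair(genome_pair_config(
      m7_cluster_layout(), background_a = 20, background_b = 20,
      partner_order = "block_shuffled",
      preserved_block = c("mrpigI", "mrpigJ", "mrpigK"), seed = seed)),
    qpcr_panel = {
      d <- qpcr_panel_design(seed)
      list(ct_table = generate_ct_table(d), design = d)
    },
    knockout_panel = c(generate_knockout_profiles(knockout_panel_config(), seed),
             list(config = knockout_panel_config())))
}

#' Write a fixture's standard input files to a directory
#'
#' Genome pairs become gene TSVs + protein FASTAs; `qpcr_panel` a CT CSV;
#' `knockout_panel` a profiles CSV.
#'
#' @param name fixture name, as in [bgc_fixture()].
#' @param seed integer RNG seed.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
simulate_fixture <- function(name, seed, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- bgc_fixture(name, seed)
  paths <- character(0)
  if (name %in% c("m7_atcc18224", "pm1_nonsyntenic")) {
    pa <- file.path(dir, c("genome_a.tsv", "genome_a.faa"))
    pb <- file.path(dir, c("genome_b.tsv", "genome_b.faa"))
    write_genome(fx$genome_a, pa[1], pa[2])
    write_genome(fx$genome_b, pb[1], pb[2])
    paths <- c(pa, pb)
  } else if (name == "qpcr_panel") {
    p <- file.path(dir, "ct_table.csv")
    write_ct_table(fx$ct_table, p)
    paths <- p
  } else {
    p <- file.path(dir, "profiles.csv")
    write_metabolite_profiles(c(list(fx$wt), unname(fx$mutants)), p)
    paths <- p
  }
  invisible(paths)
}
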