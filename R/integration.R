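# Consensus boundary calling: combine the comparative-genomics span, the
# expression classes and the knockout phenotypes into one contiguous
# cluster call with per-gene evidence. Evidence precedence is
# knockout > comparative genomics > transcription: a neutral knockout
# overrules regulator responsiveness at the borders, and interior genes are
# retained even when the regulator does not control them.

KO_SUPPORTING <- c("abolished", "shunt", "ratio_shift")
REGULATED <- c("abolished", "downregulated", "upregulated")

#' Assemble a per-gene evidence table
#'
#' @param genes ordered character vector of locus gene names.
#' @param cg_span character vector of genes inside the comparative-genomics
#'   span (must form one contiguous run within `genes`).
#' @param reg_class named character vector of expression classes (missing
#'   genes get `NA`; missing evidence is never treated as "unchanged").
#' @param ko_category named character vector of knockout categories
#'   (likewise optional per gene).
#' @return data frame of class `evidence_table` with columns `gene`,
#'   `in_cg_span`, `reg_class`, `ko_category`.
#' @export
evidence_table <- function(genes, cg_span, reg_class = NULL,
                           ko_category = NULL) {
  stopifnot(is.character(genes), !anyDuplicated(genes))
  in_span <- genes %in% cg_span
  if (sum(in_span) > 0L) {
    run <- range(which(in_span))
    if (!all(in_span[run[1]:run[2]]))
      stop("cg_span genes do not form a contiguous run in the locus")
  }
  tab <- data.frame(gene = genes, in_cg_span = in_span,
                    reg_class = NA_character_,
                    ko_category = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(reg_class)) {
    known <- intersect(names(reg_class), genes)
    tab$reg_class[match(known, tab$gene)] <- unname(reg_class[known])
  }
  if (!is.null(ko_category)) {
    known <- intersect(names(ko_category), genes)
    tab$ko_category[match(known, tab$gene)] <- unname(ko_category[known])
  }
  class(tab) <- c("evidence_table", "data.frame")
  tab
}

#' Call the consensus cluster from an evidence table
#'
#' Rules, applied in order:
#' \describe{
#'   \item{R1}{members start as the comparative-genomics span;}
#'   \item{R2}{outward walk: a gene adjacent to the span joins only when
#'     its knockout category is supporting (`abolished`, `shunt` or
#'     `ratio_shift`); transcriptional downregulation alone never admits a
#'     gene; walking stops at the first non-admitted gene per side;}
#'   \item{R3}{inward trim: an edge member is removed only when its
#'     knockout is `unchanged` *and* its expression class is `unchanged` or
#'     `not_expressed`; repeated until stable;}
#'   \item{R4}{interior members are always retained regardless of
#'     evidence.}
#' }
#'
#' @param evidence an [evidence_table()].
#' @return object of class `bgc_call`: list with `members` (contiguous
#'   ordered gene vector), `first_gene`, `last_gene`, `n_genes`,
#'   `excluded` (data frame `gene`, `reason` for non-member locus genes),
#'   and `evidence` (the input table with per-gene confidence `tier`
#'   added: `strong`, `weak`, `retained-interior`, or `excluded`).
#' @export
call_bgc <- function(evidence) {
  stopifnot(inherits(evidence, "evidence_table"))
  ev <- as.data.frame(evidence)
  n <- nrow(ev)
  if (!any(ev$in_cg_span))
    stop("no comparative-genomics span in the evidence table; ",
         "run the boundary stage first")
  lo <- min(which(ev$in_cg_span)); hi <- max(which(ev$in_cg_span))

  ko_supports <- function(i) !is.na(ev$ko_category[i]) &&
    ev$ko_category[i] %in% KO_SUPPORTING
  # R2: outward walk
  while (lo > 1L && ko_supports(lo - 1L)) lo <- lo - 1L
  while (hi < n && ko_supports(hi + 1L)) hi <- hi + 1L
  # R3: inward trim at the edges, repeated until stable
  removable <- function(i) !is.na(ev$ko_category[i]) &&
    ev$ko_category[i] == "unchanged" &&
    !is.na(ev$reg_class[i]) &&
    ev$reg_class[i] %in% c("unchanged", "not_expressed")
  repeat {
    changed <- FALSE
    if (lo < hi && removable(lo)) { lo <- lo + 1L; changed <- TRUE }
    if (hi > lo && removable(hi)) { hi <- hi - 1L; changed <- TRUE }
    if (!changed) break
  }

  member <- seq_len(n) %in% lo:hi
  tier <- character(n)
  for (i in seq_len(n)) {
    if (!member[i]) { tier[i] <- "excluded"; next }
    ko <- ev$ko_category[i]; rc <- ev$reg_class[i]
    tier[i] <-
      if (!is.na(ko) && ko %in% c("abolished", "shunt")) "strong"
      else if (!is.na(rc) && rc %in% REGULATED) "strong"
      else if (!is.na(ko) && ko == "ratio_shift") "weak"
      else "retained-interior"
  }
  ev$tier <- tier

  reason_for <- function(i) {
    ko <- ev$ko_category[i]; rc <- ev$reg_class[i]
    if (!is.na(rc) && rc %in% REGULATED &&
        !is.na(ko) && ko == "unchanged") "regulated-but-ko-neutral"
    else if (ev$in_cg_span[i]) "trimmed-ko-neutral-unregulated"
    else "no-supporting-evidence"
  }
  excl_idx <- which(!member)
  excluded <- data.frame(
    gene = ev$gene[excl_idx],
    reason = vapply(excl_idx, reason_for, character(1)),
    stringsAsFactors = FALSE)

  structure(list(members = ev$gene[lo:hi],
                 first_gene = ev$gene[lo], last_gene = ev$gene[hi],
                 n_genes = hi - lo + 1L,
                 excluded = excluded, evidence = ev),
            class = "bgc_call")
}

#' @export
print.bgc_call <- function(x, ...) {
  cat("bgc_call: ", x$n_genes, " genes, ", x$first_gene, "..",
      x$last_gene, "\n", sep = "")
  notable <- x$excluded[x$excluded$reason != "no-supporting-evidence", ,
                        drop = FALSE]
  if (nrow(notable) > 0L) {
    cat("excluded:\n")
    for (i in seq_len(nrow(notable)))
      cat("  ", notable$gene[i], " (", notable$reason[i], ")\n", sep = "")
  }
  plain <- nrow(x$excluded) - nrow(notable)
  if (plain > 0L)
    cat("  ... and ", plain, " gene(s) with no supporting evidence\n",
        sep = "")
  invisible(x)
}

#' Render the final consensus report
#'
#' Writes a machine-readable JSON report (and a human-readable text
#' rendition alongside, `.txt`) with the call, the exclusions and the
#' per-gene evidence matrix.
#'
#' @param call a [call_bgc()] result.
#' @param path output JSON path.
#' @param boundary optional [predict_cluster()] result, embedded for
#'   provenance.
#' @param expression optional `expression_results` data frame.
#' @param phenotypes optional named list of `knockout_phenotype`s.
#' @param params optional list of resolved parameters to embed.
#' @return invisibly, `path`.
#' @export
render_report <- function(call, path, boundary = NULL, expression = NULL,
                          phenotypes = NULL, params = NULL) {
  stopifnot(inherits(call, "bgc_call"))
  known <- call$evidence$gene
  orphan <- character(0)
  if (!is.null(expression))
    orphan <- c(orphan, setdiff(expression$gene, c(known, NA)))
  if (length(orphan) > 0L)
    stop("evidence refers to genes outside the call's namespace: ",
         paste(unique(orphan), collapse = ", "))

  ev_list <- lapply(seq_len(nrow(call$evidence)), function(i) {
    r <- call$evidence[i, ]
    list(in_cg_span = r$in_cg_span,
         reg_class = if (is.na(r$reg_class)) NULL else r$reg_class,
         ko_category = if (is.na(r$ko_category)) NULL else r$ko_category,
         tier = r$tier)
  })
  names(ev_list) <- call$evidence$gene
  rep <- list(
    call = list(first_gene = call$first_gene, last_gene = call$last_gene,
                n_genes = call$n_genes, members = call$members),
    excluded = lapply(seq_len(nrow(call$excluded)), function(i)
      list(gene = call$excluded$gene[i],
           reason = call$excluded$reason[i])),
    evidence = ev_list)
  if (!is.null(boundary) && boundary$status == "ok")
    rep$boundary <- list(i_begin = boundary$call$i_begin,
                         i_end = boundary$call$i_end,
                         j_begin = boundary$call$j_begin,
                         j_end = boundary$call$j_end,
                         cb_score = boundary$call$cb_score)
  if (!is.null(params)) rep$params <- params
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  txt <- c(sprintf("Consensus cluster call: %d genes, %s .. %s",
                   call$n_genes, call$first_gene, call$last_gene),
           "",
           sprintf("%-14s %-8s %-14s %-12s %s", "gene", "cg_span",
                   "reg_class", "ko", "tier"),
           vapply(seq_len(nrow(call$evidence)), function(i) {
             r <- call$evidence[i, ]
             sprintf("%-14s %-8s %-14s %-12s %s", r$gene,
                     ifelse(r$in_cg_span, "yes", "-"),
                     ifelse(is.na(r$reg_class), "-", r$reg_class),
                     ifelse(is.na(r$ko_category), "-", r$ko_category),
                     r$tier)
           }, character(1)))
  writeLines(txt, sub("\\.json$", ".txt", path))
  invisible(path)
}

#' Read a consensus report back from JSON
#'
#' @param path JSON path written by [render_report()].
#' @return list mirroring the report structure; `$call$members` is a
#'   character vector.
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  rep$call$members <- as.character(unlist(rep$call$members))
  rep
}
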