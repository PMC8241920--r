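# Comparative-CT (delta-delta-CT) relative expression of locus genes in a
# regulator-knockout strain vs wild type, with one-way ANOVA significance
# and per-gene regulation classes. Amplification efficiency is assumed to
# be exactly 2 (no Pfaffl correction); undetermined CT values are carried
# as a detection flag and never imputed.

#' Regulation-class thresholds
#'
#' Fold-change cutoffs mapping qualitative regulation descriptions onto
#' classes: `abolished` at fold change <= `abolished_max`, `downregulated`
#' up to `down_max`, `upregulated` from `up_min`, all requiring `p < alpha`;
#' anything else is `unchanged`. Undetected-in-calibrator genes are
#' `not_expressed`.
#'
#' @param abolished_max upper fold-change bound for `abolished`
#'   (default 0.1).
#' @param down_max upper fold-change bound for `downregulated`
#'   (default 2/3).
#' @param up_min lower fold-change bound for `upregulated` (default 1.5).
#' @param alpha significance level (default 0.05).
#' @return list of class `expression_thresholds`.
#' @export
expression_thresholds <- function(abolished_max = 0.1, down_max = 2 / 3,
                                  up_min = 1.5, alpha = 0.05) {
  stopifnot(abolished_max > 0, down_max > abolished_max, up_min > down_max,
            alpha > 0, alpha < 1)
  structure(list(abolished_max = abolished_max, down_max = down_max,
                 up_min = up_min, alpha = alpha),
            class = "expression_thresholds")
}

check_ct_table <- function(ct_table) {
  req <- c("strain", "gene", "bio_rep", "tech_rep", "ct")
  miss <- setdiff(req, names(ct_table))
  if (length(miss) > 0L)
    stop("CT table is missing column(s): ", paste(miss, collapse = ", "))
  bad <- !is.na(ct_table$ct) & (ct_table$ct <= 0 | ct_table$ct > 45)
  if (any(bad)) stop("determined CT values must lie in (0, 45]")
  ct_table
}

# Mean CT over technical replicates, per (strain, gene, bio_rep).
# Returns NA for a biological replicate whose wells are all undetermined.
tech_means <- function(ct_table, strain, gene) {
  rows <- ct_table[ct_table$strain == strain & ct_table$gene == gene, ,
                   drop = FALSE]
  if (nrow(rows) == 0L) return(numeric(0))
  means <- tapply(rows$ct, rows$bio_rep,
                  function(v) if (all(is.na(v))) NA_real_
                              else mean(v, na.rm = TRUE))
  as.numeric(means)[order(as.numeric(names(means)))]
}

#' Comparative-CT relative expression of one gene
#'
#' Technical replicates are averaged first; per biological replicate
#' `dCT = CT_gene - CT_ref`; `ddCT = mean dCT(case) - mean dCT(calibrator)`;
#' `fold_change = 2^-ddCT`. Per-replicate relative values
#' `2^-(dCT - mean dCT calibrator)` are returned for both strains so the
#' significance test can run on biological replicates.
#'
#' @param ct_table data frame with columns `strain`, `gene`, `bio_rep`,
#'   `tech_rep`, `ct` (`NA` = undetermined well).
#' @param gene target gene.
#' @param ref_gene reference (normalizer) gene; must be determined in every
#'   biological replicate of both strains.
#' @param strain_case,strain_calibrator strain labels; fold change is case
#'   relative to calibrator.
#' @return list with `fold_change`, `detected` (logical: determined in the
#'   calibrator strain), `rel_case`, `rel_calibrator` (per-biological-
#'   replicate relative values), `ddct`.
#' @export
#' @examples
#' ct <- expand.grid(strain = c("wt", "mut"), bio_rep = 1:3, tech_rep = 1)
#' ct <- rbind(transform(ct, gene = "ref", ct = 20),
#'             transform(ct, gene = "tgt",
#'                       ct = ifelse(ct$strain == "wt", 24, 28)))
#' relative_expression(ct, "tgt", "ref", "mut", "wt")$fold_change  # 0.0625
relative_expression <- function(ct_table, gene, ref_gene, strain_case,
                                strain_calibrator) {
  ct_table <- check_ct_table(ct_table)
  ref_case <- tech_means(ct_table, strain_case, ref_gene)
  ref_cal <- tech_means(ct_table, strain_calibrator, ref_gene)
  if (length(ref_case) == 0L || length(ref_cal) == 0L)
    stop("reference gene '", ref_gene, "' absent from the CT table")
  if (anyNA(ref_case) || anyNA(ref_cal))
    stop("reference gene '", ref_gene,
         "' undetermined in at least one biological replicate")
  tgt_case <- tech_means(ct_table, strain_case, gene)
  tgt_cal <- tech_means(ct_table, strain_calibrator, gene)
  if (length(tgt_case) == 0L || length(tgt_cal) == 0L)
    stop("gene '", gene, "' absent from the CT table")
  if (all(is.na(tgt_cal)))
    return(list(fold_change = NA_real_, detected = FALSE,
                rel_case = NULL, rel_calibrator = NULL, ddct = NA_real_))
  dct_case <- tgt_case - ref_case
  dct_cal <- tgt_cal - ref_cal
  ddct <- mean(dct_case, na.rm = TRUE) - mean(dct_cal, na.rm = TRUE)
  base <- mean(dct_cal, na.rm = TRUE)
  list(fold_change = 2^(-ddct), detected = TRUE,
       rel_case = 2^(-(dct_case - base)),
       rel_calibrator = 2^(-(dct_cal - base)),
       ddct = ddct)
}

#' One-way ANOVA p-value for two groups of relative values
#'
#' Fixed-effects one-way ANOVA across the two strains' per-biological-
#' replicate relative expression values. With two groups this is equivalent
#' to the pooled-variance two-sided t-test (t^2 = F). Degenerate input with
#' zero variance in both groups and equal means returns p = 1.
#'
#' @param values_case,values_calibrator numeric vectors (>= 2 values each).
#' @return p-value in `[0, 1]`.
#' @export
anova_p <- function(values_case, values_calibrator) {
  stopifnot(length(values_case) >= 2L, length(values_calibrator) >= 2L)
  v <- c(values_case, values_calibrator)
  g <- factor(rep(c("case", "calibrator"),
                  c(length(values_case), length(values_calibrator))))
  if (stats::var(v) == 0) return(1.0)
  # zero within-group variance makes lm's F-test warn about a perfect fit;
  # that case is resolved explicitly below
  fit <- suppressWarnings(stats::anova(stats::lm(v ~ g)))
  p <- fit[["Pr(>F)"]][1L]
  if (is.na(p)) {
    # zero within-group variance, unequal means: infinitely significant
    p <- if (mean(values_case) == mean(values_calibrator)) 1.0 else 0.0
  }
  p
}

#' Classify a gene's regulation
#'
#' Maps (fold change, p-value, detection status) onto one regulation class.
#' The classes partition the input space: `not_expressed` when undetected in
#' the calibrator strain; otherwise `abolished`, `downregulated` or
#' `upregulated` by the fold-change cutoffs when `p < alpha`; `unchanged`
#' for everything else.
#'
#' @param fold_change positive number (mutant relative to wild type), or
#'   `NA` when undetected.
#' @param p_value number in `[0, 1]`, or `NA` when undetected.
#' @param detected logical: was the gene determined in the calibrator
#'   strain?
#' @param thresholds an [expression_thresholds()].
#' @return one of `"abolished"`, `"downregulated"`, `"unchanged"`,
#'   `"upregulated"`, `"not_expressed"`.
#' @export
classify_gene <- function(fold_change, p_value, detected = TRUE,
                          thresholds = expression_thresholds()) {
  if (!detected) return("not_expressed")
  stopifnot(is.finite(fold_change), fold_change > 0,
            is.finite(p_value), p_value >= 0, p_value <= 1)
  th <- thresholds
  if (p_value < th$alpha) {
    if (fold_change <= th$abolished_max) return("abolished")
    if (fold_change <= th$down_max) return("downregulated")
    if (fold_change >= th$up_min) return("upregulated")
  }
  "unchanged"
}

#' Delta-delta-CT analysis of every assayed gene in a CT table
#'
#' Runs [relative_expression()], [anova_p()] and [classify_gene()] for each
#' gene in the table (the reference gene itself is excluded). The ANOVA is
#' computed on the log2 relative values, the scale on which qPCR replicate
#' noise is homoscedastic and near-normal. Deterministic given the table.
#'
#' @inheritParams relative_expression
#' @param thresholds an [expression_thresholds()].
#' @return data frame of class `expression_results` with columns `gene`,
#'   `fold_change`, `p_value`, `reg_class`, ordered as genes appear in the
#'   table.
#' @export
analyze_locus <- function(ct_table, ref_gene, strain_case,
                          strain_calibrator,
                          thresholds = expression_thresholds()) {
  ct_table <- check_ct_table(ct_table)
  genes <- setdiff(unique(ct_table$gene), ref_gene)
  if (!ref_gene %in% ct_table$gene)
    stop("reference gene '", ref_gene, "' absent from the CT table")
  rows <- lapply(genes, function(g) {
    rel <- relative_expression(ct_table, g, ref_gene, strain_case,
                               strain_calibrator)
    if (!rel$detected) {
      data.frame(gene = g, fold_change = NA_real_, p_value = NA_real_,
                 reg_class = "not_expressed", stringsAsFactors = FALSE)
    } else {
      # the test runs on the log2 relative values (equivalently, on the
      # per-replicate dCT differences): CT data are log-scale measurements,
      # and the F-test's normality assumption holds there, not on the
      # exponentiated fold-change scale
      p <- anova_p(log2(rel$rel_case), log2(rel$rel_calibrator))
      data.frame(gene = g, fold_change = rel$fold_change, p_value = p,
                 reg_class = classify_gene(rel$fold_change, p, TRUE,
                                           thresholds),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("expression_results", "data.frame")
  out
}

#' Read / write CT tables and expression results
#'
#' CT tables are CSV with columns `strain`, `gene`, `bio_rep`, `tech_rep`,
#' `ct` (blank = undetermined). Expression results are TSV with columns
#' `gene`, `fold_change`, `p_value`, `reg_class`.
#'
#' @param path file path.
#' @return the table (data frame), or invisibly `path` for writers.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_ct_table(tab)
}

#' @rdname read_ct_table
#' @param ct_table a CT data frame.
#' @export
write_ct_table <- function(ct_table, path) {
  utils::write.csv(ct_table, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname read_ct_table
#' @param results an `expression_results` data frame.
#' @export
write_expression_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
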