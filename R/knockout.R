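# Knockout metabolite-profile evidence: classify each mutant strain's
# compound profile against wild type into the phenotype categories used to
# validate cluster boundaries. Profiles enter as already-quantified compound
# tables; the published evidence is qualitative (HPLC traces, colony
# color), so the absence floor and fold tolerances here are explicit,
# configurable quantifications chosen with wide margins.

#' The azaphilone pigment compound registry
#'
#' Compounds 1-4 are the core pigments (monascin, rubropunctatin,
#' ankaflavin, monascorubrin); 5-6 are the shunt (derailment) products
#' (acetyl-monasfluol A and B) that accumulate when ring cyclization is
#' blocked.
#'
#' @return data frame with columns `compound`, `name`, `role`.
#' @export
compound_registry <- function() {
  data.frame(
    compound = as.character(1:6),
    name = c("monascin", "rubropunctatin", "ankaflavin", "monascorubrin",
             "acetyl-monasfluol A", "acetyl-monasfluol B"),
    role = c(rep("core", 4), rep("shunt", 2)),
    stringsAsFactors = FALSE)
}

#' Knockout phenotype thresholds
#'
#' @param absence_frac a core compound is "absent" in the mutant below this
#'   fraction of the wild-type amount (default 0.05).
#' @param fold_tol amount and pairwise-ratio tolerance: deviations beyond
#'   `fold_tol`-fold count as changed (default 2; comparisons inclusive, so
#'   exactly 2-fold is still within tolerance).
#' @param shunt_floor_frac detection floor for shunt compounds, as a
#'   fraction of the mean wild-type core amount (default 0.05). Scaling the
#'   floor by the wild-type profile keeps classification invariant under a
#'   common rescaling of both profiles.
#' @return list of class `knockout_thresholds`.
#' @export
knockout_thresholds <- function(absence_frac = 0.05, fold_tol = 2,
                                shunt_floor_frac = 0.05) {
  stopifnot(absence_frac > 0, absence_frac < 1, fold_tol > 1,
            shunt_floor_frac > 0)
  structure(list(absence_frac = absence_frac, fold_tol = fold_tol,
                 shunt_floor_frac = shunt_floor_frac),
            class = "knockout_thresholds")
}

#' Construct a metabolite profile
#'
#' @param strain strain label.
#' @param amounts named non-negative numeric vector keyed by compound id
#'   (`"1"`..`"6"`); missing compounds are taken as 0.
#' @param registry a [compound_registry()]-shaped data frame.
#' @return list of class `metabolite_profile`.
#' @export
metabolite_profile <- function(strain, amounts,
                               registry = compound_registry()) {
  stopifnot(is.character(strain), length(strain) == 1L)
  full <- stats::setNames(numeric(nrow(registry)), registry$compound)
  known <- intersect(names(amounts), registry$compound)
  if (length(known) < length(amounts))
    stop("unknown compound id(s): ",
         paste(setdiff(names(amounts), registry$compound), collapse = ", "))
  full[known] <- amounts[known]
  if (any(full < 0)) stop("compound amounts must be non-negative")
  structure(list(strain = strain, amounts = full, registry = registry),
            class = "metabolite_profile")
}

#' Classify a knockout strain's metabolite profile against wild type
#'
#' Rules applied in order, first match wins:
#' \describe{
#'   \item{abolished}{all core compounds absent and no shunt compound
#'     present;}
#'   \item{shunt}{any shunt compound present above the detection floor;}
#'   \item{ratio_shift}{all core compounds present but some pairwise core
#'     ratio deviates more than `fold_tol`-fold from wild type;}
#'   \item{unchanged}{everything else.}
#' }
#' A partial core loss without shunt products therefore falls through to
#' `unchanged`; no published phenotype exercises that corner.
#'
#' @param wt,mutant [metabolite_profile()] objects sharing a registry. All
#'   wild-type core amounts must be positive (ratios must be defined).
#' @param thresholds a [knockout_thresholds()].
#' @return list of class `knockout_phenotype`: `strain`, `category`,
#'   `details` (per-core fold vs wild type and shunt amounts).
#' @export
compare_profiles <- function(wt, mutant,
                             thresholds = knockout_thresholds()) {
  stopifnot(inherits(wt, "metabolite_profile"),
            inherits(mutant, "metabolite_profile"))
  if (!identical(wt$registry, mutant$registry))
    stop("wild-type and mutant profiles use different compound registries")
  reg <- wt$registry
  core <- reg$compound[reg$role == "core"]
  shunt <- reg$compound[reg$role == "shunt"]
  w <- wt$amounts; m <- mutant$amounts
  if (any(w[core] <= 0))
    stop("wild-type core compound amount of 0: ratios undefined")
  th <- thresholds

  core_absent <- m[core] < th$absence_frac * w[core]
  floor <- th$shunt_floor_frac * mean(w[core])
  shunt_present <- m[shunt] >= floor

  ratio_dev <- 0
  if (!any(core_absent)) {
    for (i in seq_along(core)[-length(core)])
      for (j in (i + 1):length(core)) {
        d <- abs(log2((m[core[i]] / m[core[j]]) /
                      (w[core[i]] / w[core[j]])))
        ratio_dev <- max(ratio_dev, d)
      }
  }

  category <-
    if (all(core_absent) && !any(shunt_present)) "abolished"
    else if (any(shunt_present)) "shunt"
    else if (!any(core_absent) && ratio_dev > log2(th$fold_tol)) "ratio_shift"
    else "unchanged"

  structure(list(strain = mutant$strain, category = category,
                 details = list(core_fold = m[core] / w[core],
                                shunt_amount = m[shunt],
                                shunt_floor = floor,
                                max_ratio_dev_log2 = ratio_dev)),
            class = "knockout_phenotype")
}

#' Classify a panel of knockout strains
#'
#' @param wt wild-type [metabolite_profile()].
#' @param mutants list of mutant profiles.
#' @param thresholds a [knockout_thresholds()].
#' @return named list of `knockout_phenotype` objects, keyed by strain.
#' @export
evaluate_knockout_panel <- function(wt, mutants,
                                    thresholds = knockout_thresholds()) {
  res <- lapply(mutants, compare_profiles, wt = wt, thresholds = thresholds)
  stats::setNames(res, vapply(res, `[[`, character(1), "strain"))
}

#' Read / write metabolite profiles and phenotype calls
#'
#' Profiles are CSV with columns `strain`, `compound`, `amount`.
#'
#' @param path file path.
#' @param registry a [compound_registry()]-shaped data frame.
#' @return list of [metabolite_profile()]s keyed by strain (reader), or
#'   invisibly `path` (writers).
#' @export
read_metabolite_profiles <- function(path, registry = compound_registry()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(compound = "character"))
  lapply(split(tab, tab$strain), function(d)
    metabolite_profile(d$strain[1],
                       stats::setNames(d$amount, d$compound), registry))
}

#' @rdname read_metabolite_profiles
#' @param profiles list of [metabolite_profile()]s.
#' @export
write_metabolite_profiles <- function(profiles, path) {
  tab <- do.call(rbind, lapply(profiles, function(p)
    data.frame(strain = p$strain, compound = names(p$amounts),
               amount = unname(p$amounts), stringsAsFactors = FALSE)))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_metabolite_profiles
#' @param phenotypes named list of `knockout_phenotype`s.
#' @export
write_knockout_phenotypes <- function(phenotypes, path) {
  tab <- do.call(rbind, lapply(phenotypes, function(p)
    data.frame(strain = p$strain, category = p$category,
               core_fold = paste(sprintf("%s:%.3g",
                                         names(p$details$core_fold),
                                         p$details$core_fold),
                                 collapse = ";"),
               stringsAsFactors = FALSE)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
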