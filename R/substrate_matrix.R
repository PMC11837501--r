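# Completeness-normalized substrate-degradation copy matrix: the per-MAG
# feature table behind the ordination and the per-diet comparisons.

#' Normalize a gene copy total by genome completeness
#'
#' Converts a raw copy total into copies per complete-genome equivalent:
#' `raw * 100 / completeness`. An incomplete genome under-counts its genes;
#' dividing by the estimated completeness corrects the total upward (a MAG at
#' 50% completeness has its counts doubled; at 100% they are unchanged).
#'
#' @param raw non-negative copy total(s).
#' @param completeness genome completeness percentage(s) in (0, 100].
#' @return normalized copy total(s).
#' @export
normalize_copies <- function(raw, completeness) {
  if (any(raw < 0)) md_error("magdiet_validation_error", "raw counts must be >= 0")
  if (any(completeness <= 0)) {
    md_error("magdiet_domain_error",
             "completeness must be > 0 (MAG should have been filtered)")
  }
  raw * 100 / completeness
}

#' Build per-MAG substrate profiles
#'
#' For every MAG: the copy total over each substrate class's configured
#' family list, normalized to genome completeness, plus the binary
#' beta-oxidation capability. Hemicellulose is one axis (the union of the
#' xylan, mannan and xyloglucan family lists, each family counted once).
#'
#' @param mat an `annotation_matrix`.
#' @param mags a `mag_table` covering every row of `mat` with
#'   completeness > 0.
#' @param substrate_config output of [read_substrate_config()].
#' @param defs `pathway_defs` containing a `beta_oxidation` definition.
#' @return data.frame of class `substrate_profiles`: `mag_id`, one numeric
#'   column per substrate class, and `fatty_acid` (0/1).
#' @export
build_profile_matrix <- function(mat, mags, substrate_config,
                                 defs = read_pathway_defs()) {
  check_annotation_join(mat, mags)
  comp <- stats::setNames(mags$completeness, mags$mag_id)[rownames(mat)]
  if (any(comp <= 0)) {
    md_error("magdiet_domain_error", "completeness must be > 0 for profiling")
  }
  out <- data.frame(mag_id = rownames(mat), stringsAsFactors = FALSE)
  for (cls in names(substrate_config$substrate_classes)) {
    fams <- substrate_config$substrate_classes[[cls]]
    keep <- fams[fams %in% colnames(mat)]
    raw <- if (length(keep)) rowSums(mat[, keep, drop = FALSE]) else
      stats::setNames(rep(0, nrow(mat)), rownames(mat))
    out[[cls]] <- as.numeric(normalize_copies(raw, comp))
  }
  beta_def <- defs[["beta_oxidation"]]
  out$fatty_acid <- vapply(rownames(mat), function(m)
    beta_oxidation_flag(mat[m, ], beta_def), 0L)
  rownames(out) <- NULL
  class(out) <- c("substrate_profiles", "data.frame")
  out
}

#' Fold change of mean normalized copies between two diets
#'
#' Ratio of the arithmetic group means of a substrate's normalized copy
#' totals ("gene copies per MAG").
#'
#' @param profiles a `substrate_profiles` data.frame.
#' @param design diet labels (named vector or `mag_id`/`diet` data.frame).
#' @param substrate substrate column name.
#' @param numerator,denominator diet labels.
#' @return positive real; errors when the denominator group mean is 0.
#' @export
fold_change <- function(profiles, design, substrate, numerator, denominator) {
  labels <- as_diet_labels(design)
  vals <- stats::setNames(profiles[[substrate]], profiles$mag_id)
  num <- vals[names(labels)[labels == numerator]]
  den <- vals[names(labels)[labels == denominator]]
  num <- num[!is.na(num)]; den <- den[!is.na(den)]
  if (!length(num) || !length(den)) {
    md_error("magdiet_design_error", "empty diet group in fold change")
  }
  if (mean(den) == 0) {
    md_error("magdiet_undefined_ratio_error",
             "denominator group mean is zero for substrate '%s'", substrate)
  }
  mean(num) / mean(den)
}
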