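# Marker-gene community profiles and MAG QC summaries.

#' Marker-gene coverage community profile
#'
#' Relative abundance of each taxon as its share of total marker (e.g. rps3)
#' read coverage; single-copy ribosomal protein coverage proxies taxon
#' abundance in the assembly. A taxon is flagged `binned` when any of its
#' contributing markers belongs to a MAG, which is what makes the
#' assembly-vs-MAG representation comparison possible.
#'
#' @param markers data.frame from [read_marker_table()] (`gene_id`,
#'   `taxonomy`, `coverage`, `mag_id`).
#' @param rank lineage position used as the taxon label: an index into the
#'   semicolon-separated taxonomy string, a rank name
#'   (domain/phylum/class/order/family/genus/species), or `"full"` for the
#'   whole string.
#' @return data.frame of class `community_profile`: `taxon`, `abundance`
#'   (fractions summing to 1), `coverage`, `binned`.
#' @export
marker_profile <- function(markers, rank = "full") {
  if (!nrow(markers)) md_error("magdiet_domain_error", "no marker records")
  total <- sum(markers$coverage)
  if (total <= 0) {
    md_error("magdiet_degenerate_error", "total marker coverage is zero")
  }
  taxon <- taxon_at_rank(markers$taxonomy, rank)
  cov <- tapply(markers$coverage, taxon, sum)
  binned <- tapply(!is.na(markers$mag_id), taxon, any)
  out <- data.frame(taxon = names(cov),
                    abundance = as.numeric(cov) / total,
                    coverage = as.numeric(cov),
                    binned = as.logical(binned),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abundance, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("community_profile", "data.frame")
  out
}

taxon_at_rank <- function(taxonomy, rank) {
  if (identical(rank, "full")) return(trimws(taxonomy))
  idx <- if (is.numeric(rank)) as.integer(rank) else match(rank, LINEAGE_RANKS)
  if (is.na(idx)) md_error("magdiet_config_error", "unknown rank '%s'", rank)
  vapply(strsplit(taxonomy, ";", fixed = TRUE), function(p) {
    v <- if (length(p) >= idx) trimws(p[idx]) else ""
    if (v == "") "unclassified" else v
  }, "")
}

#' MAG quality and novelty summary
#'
#' Group-level summary of a MAG table: mean completeness and contamination
#' (full precision, with half-even 2-decimal display rounding), taxonomic
#' class counts (empty class rank grouped as "unclassified"), and the
#' known-species tally — records whose ANI to the nearest reference exceeds
#' the threshold (strict `>`, default 95%, the conventional bacterial species
#' boundary). MAGs placed by RED only never count as known species.
#'
#' @param mags a `mag_table` (one group; split beforehand for per-treatment
#'   summaries, or use [qc_summary_by()]).
#' @param ani_known_threshold ANI percentage above which a MAG is considered
#'   a known species.
#' @param label optional group label.
#' @return list of class `qc_summary`: `label`, `n_mags`,
#'   `mean_completeness`, `mean_contamination` (unrounded), the rounded
#'   display values, `class_counts`, `n_known_species`, `fraction_known`.
#' @export
qc_summary <- function(mags, ani_known_threshold = 95, label = "all") {
  if (!nrow(mags)) md_error("magdiet_domain_error", "empty MAG table")
  cls <- mags$class
  cls[is.na(cls) | cls == ""] <- "unclassified"
  class_counts <- table(cls)
  n_known <- sum(!is.na(mags$ani_nearest) &
                   mags$ani_nearest > ani_known_threshold)
  structure(list(
    label = label,
    n_mags = nrow(mags),
    mean_completeness = mean(mags$completeness),
    mean_contamination = mean(mags$contamination),
    mean_completeness_2dp = round(mean(mags$completeness), 2),
    mean_contamination_2dp = round(mean(mags$contamination), 2),
    class_counts = as.list(class_counts),
    n_classes = length(class_counts),
    n_known_species = n_known,
    fraction_known = n_known / nrow(mags)
  ), class = "qc_summary")
}

#' @rdname qc_summary
#' @param groups named character vector or `mag_id`/`diet` data.frame
#'   assigning each MAG to a group.
#' @export
qc_summary_by <- function(mags, groups, ani_known_threshold = 95) {
  labels <- as_diet_labels(groups)
  missing <- setdiff(mags$mag_id, names(labels))
  if (length(missing)) {
    md_error("magdiet_labeling_error", "unlabeled MAG(s): %s",
             paste(missing, collapse = ", "))
  }
  g <- labels[mags$mag_id]
  lapply(split(seq_len(nrow(mags)), g), function(idx) {
    qc_summary(mags[idx, , drop = FALSE], ani_known_threshold,
               label = g[idx[1L]])
  })
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf("QC summary [%s]: %d MAGs\n", x$label, x$n_mags))
  cat(sprintf("  mean completeness  %.2f%%\n", x$mean_completeness))
  cat(sprintf("  mean contamination %.2f%%\n", x$mean_contamination))
  cat(sprintf("  classes (%d): %s\n", x$n_classes,
              paste(sprintf("%s=%d", names(x$class_counts),
                            unlist(x$class_counts)), collapse = ", ")))
  cat(sprintf("  known species (ANI rule): %d/%d (%.1f%%)\n",
              x$n_known_species, x$n_mags, 100 * x$fraction_known))
  invisible(x)
}
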