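# Pathway evaluation: turn one MAG's gene-family copy counts into
# complete / partial / absent calls under the declarative rules.
#
# Status lattice: absent (fraction 0) < partial < complete. Adding gene
# copies can only move a call up the lattice (monotone in the counts).

step_satisfied <- function(counts, step) {
  hit <- step$alternatives[step$alternatives %in% names(counts)]
  length(hit) > 0L && any(counts[hit] >= 1)
}

status_from_fraction <- function(fraction, complete) {
  if (fraction == 0) "absent" else if (complete) "complete" else "partial"
}

#' Evaluate one pathway against one MAG's annotations
#'
#' Computes the satisfied-step fraction and the resulting status.
#' `degradation_chain` and `gene_set_all` pathways are complete only when
#' every step is satisfied; `enzyme_fraction` pathways are complete when the
#' fraction reaches the threshold (closed inequality, so a 10-step pathway at
#' threshold 0.8 is complete with exactly 8 satisfied steps); a `marker` is
#' complete when its single step is satisfied; an `any_of_pathways` is
#' complete when any member is complete, partial when some member is partial,
#' and carries the maximum member fraction.
#'
#' @param counts named numeric vector of gene copy counts for one MAG; names
#'   are canonical `"NAMESPACE:FAMILY"` keys (one row of an
#'   [as_annotation_matrix()] matrix).
#' @param def a `pathway_def`.
#' @param defs the full `pathway_defs` set; required to resolve
#'   `any_of_pathways` members.
#' @return list of class `pathway_call` with `pathway_id`, `status`,
#'   `fraction`, `steps_present`.
#' @export
evaluate_pathway <- function(counts, def, defs = NULL) {
  if (any(counts < 0)) md_error("magdiet_validation_error", "negative copy counts")
  if (def$category == "any_of_pathways") {
    if (is.null(defs)) {
      md_error("magdiet_definition_error",
               "evaluating '%s' requires the full definition set", def$pathway_id)
    }
    member_calls <- lapply(def$members, function(m) {
      evaluate_pathway(counts, defs[[m]], defs)
    })
    fractions <- vapply(member_calls, `[[`, 0, "fraction")
    statuses <- vapply(member_calls, `[[`, "", "status")
    fraction <- max(fractions)
    complete <- any(statuses == "complete")
    call <- list(pathway_id = def$pathway_id,
                 status = status_from_fraction(fraction, complete),
                 fraction = fraction,
                 steps_present = unique(unlist(lapply(member_calls, `[[`,
                                                      "steps_present"))))
  } else {
    sat <- vapply(def$steps, function(st) step_satisfied(counts, st), TRUE)
    fraction <- sum(sat) / length(sat)
    complete <- switch(def$category,
      degradation_chain = , gene_set_all = , marker = all(sat),
      enzyme_fraction = fraction >= def$threshold - 1e-12)
    call <- list(pathway_id = def$pathway_id,
                 status = status_from_fraction(fraction, complete),
                 fraction = fraction,
                 steps_present = vapply(def$steps, `[[`, "", "step_id")[sat])
  }
  structure(call, class = "pathway_call")
}

#' Evaluate many pathways over an annotation matrix
#'
#' @param mat an `annotation_matrix`.
#' @param defs a `pathway_defs` set.
#' @param pathway_ids subset of pathway ids to evaluate (default: all).
#' @return long-format data.frame with columns `mag_id`, `pathway_id`,
#'   `status`, `fraction`.
#' @export
evaluate_pathways <- function(mat, defs, pathway_ids = names(defs)) {
  rows <- expand.grid(mag_id = rownames(mat), pathway_id = pathway_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- mapply(function(m, p) {
    call <- evaluate_pathway(mat[m, ], defs[[p]], defs)
    c(call$status, call$fraction)
  }, rows$mag_id, rows$pathway_id)
  rows$status <- res[1L, ]
  rows$fraction <- as.numeric(res[2L, ])
  rows
}

#' Classify complete and partial substrate degraders
#'
#' Evaluates every substrate-class-tagged pathway for every MAG. Complete
#' degraders of a substrate encode every step of the chain; partial degraders
#' satisfy at least one step but not all.
#'
#' @param mat an `annotation_matrix`.
#' @param defs a `pathway_defs` set.
#' @return data.frame `mag_id`, `pathway_id`, `substrate_class`, `status`,
#'   `fraction`.
#' @export
classify_degraders <- function(mat, defs) {
  tagged <- names(defs)[!vapply(defs, function(d) is.null(d$substrate_class), TRUE)]
  if (!length(tagged)) {
    md_error("magdiet_definition_error", "no substrate_class-tagged pathways")
  }
  out <- evaluate_pathways(mat, defs, tagged)
  out$substrate_class <- vapply(defs[out$pathway_id], `[[`, "", "substrate_class")
  out[, c("mag_id", "pathway_id", "substrate_class", "status", "fraction")]
}

#' Beta-oxidation capability flag
#'
#' Fatty-acid degradation is screened as a binary: 1 when the MAG encodes all
#' four enzymes of the beta-oxidation cycle (acyl-CoA dehydrogenase,
#' enoyl-CoA hydratase, 3-hydroxyacyl-CoA dehydrogenase, acetyl-CoA
#' acyltransferase), else 0.
#'
#' @param counts named copy-count vector for one MAG.
#' @param beta_def the beta-oxidation `gene_set_all` definition (exactly 4
#'   steps).
#' @return integer 0 or 1.
#' @export
beta_oxidation_flag <- function(counts, beta_def) {
  if (beta_def$category != "gene_set_all" || length(beta_def$steps) != 4L) {
    md_error("magdiet_definition_error",
             "beta-oxidation definition must be gene_set_all with exactly 4 steps")
  }
  call <- evaluate_pathway(counts, beta_def)
  as.integer(call$status == "complete")
}

#' Summarize the biochemical functions of one MAG
#'
#' Applies the substrate-listing rules: each carbohydrate whose degradation
#' chain is complete is listed; starch is listed when the amylase copy total
#' strictly exceeds the configured cutoff (default 5); proteins when the
#' exopeptidase copy total strictly exceeds its cutoff (default 10); fatty
#' acids when the beta-oxidation screen is complete; and "simple saccharides"
#' when nothing else qualifies but a beta-glucosidase family is present.
#' Energy pathways are listed when complete, or flagged `(p)` when at least
#' one step is satisfied but the pathway is not complete. Vitamins are listed
#' iff the corresponding biosynthesis call is complete.
#'
#' @param mag_id MAG identifier.
#' @param counts named copy-count vector for that MAG.
#' @param defs a `pathway_defs` set.
#' @param substrate_config output of [read_substrate_config()].
#' @param energy_pathways,vitamin_pathways pathway ids making up the energy
#'   and vitamin panels; vitamin ids must be named by vitamin label.
#' @return list of class `function_summary` with `mag_id`, `substrates`,
#'   `energy_pathways` (data.frame pathway/partial), `vitamins`, `benefits`.
#' @export
summarize_functions <- function(mag_id, counts, defs, substrate_config,
                                energy_pathways = c("glycolysis",
                                                    "pyruvate_oxidation",
                                                    "tca_cycle",
                                                    "beta_oxidation",
                                                    "nitrate_reduction",
                                                    "lactate_fermentation",
                                                    "formate_fermentation",
                                                    "h2_fermentation",
                                                    "acetogenesis"),
                                vitamin_pathways = c(B1 = "vitamin_b1",
                                                     B2 = "vitamin_b2",
                                                     B7 = "vitamin_b7",
                                                     B9 = "vitamin_b9",
                                                     B12 = "vitamin_b12")) {
  thr <- substrate_config$thresholds
  if (is.null(thr$amylase_min) || is.null(thr$exopeptidase_min)) {
    md_error("magdiet_config_error", "missing amylase/exopeptidase thresholds")
  }
  total_over <- function(fams) {
    keep <- fams[fams %in% names(counts)]
    if (length(keep)) sum(counts[keep]) else 0
  }
  substrates <- character(0)
  # complete carbohydrate chains (one listing per substrate class)
  carb_classes <- c("cellulose", "hemicellulose", "chitin")
  for (cls in carb_classes) {
    ids <- names(defs)[vapply(defs, function(d)
      identical(d$substrate_class, cls), TRUE)]
    # prefer the umbrella any_of when present to avoid double listing
    any_of <- ids[vapply(defs[ids], function(d) d$category == "any_of_pathways", TRUE)]
    ids_use <- if (length(any_of)) any_of else ids
    complete <- any(vapply(ids_use, function(p)
      evaluate_pathway(counts, defs[[p]], defs)$status == "complete", TRUE))
    if (complete) substrates <- c(substrates, cls)
  }
  if (total_over(substrate_config$amylase_families) > thr$amylase_min) {
    substrates <- c(substrates, "starch")
  }
  if (total_over(substrate_config$exopeptidase_families) > thr$exopeptidase_min) {
    substrates <- c(substrates, "protein")
  }
  beta_def <- defs[["beta_oxidation"]]
  if (!is.null(beta_def) && beta_oxidation_flag(counts, beta_def) == 1L) {
    substrates <- c(substrates, "fatty_acid")
  }
  if (!length(substrates) &&
      total_over(substrate_config$beta_glucosidase_families) >= 1) {
    substrates <- "simple_saccharides"
  }
  energy <- do.call(rbind, lapply(energy_pathways, function(p) {
    call <- evaluate_pathway(counts, defs[[p]], defs)
    if (call$status == "absent") return(NULL)
    data.frame(pathway = p, partial = call$status == "partial",
               stringsAsFactors = FALSE)
  }))
  if (is.null(energy)) {
    energy <- data.frame(pathway = character(0), partial = logical(0))
  }
  vitamins <- names(vitamin_pathways)[vapply(vitamin_pathways, function(p)
    evaluate_pathway(counts, defs[[p]], defs)$status == "complete", TRUE)]
  benefits <- character(0)
  if ("protein" %in% substrates) benefits <- c(benefits, "protein degradation")
  if (any(c("cellulose", "hemicellulose", "starch", "chitin") %in% substrates)) {
    benefits <- c(benefits, "plant matter degradation")
  }
  if (length(vitamins)) benefits <- c(benefits, "vitamin production")
  structure(list(mag_id = mag_id, substrates = substrates,
                 energy_pathways = energy, vitamins = vitamins,
                 benefits = benefits),
            class = "function_summary")
}

#' Per-group counts of complete and partial MAGs per pathway
#'
#' @param calls long-format call table (`mag_id`, `pathway_id`, `status`), as
#'   from [evaluate_pathways()] or [classify_degraders()].
#' @param groups named character vector or data.frame (`mag_id`, `diet`)
#'   labeling every MAG in `calls`.
#' @return data.frame `pathway_id`, `diet`, `n_complete`, `n_partial`,
#'   `n_absent`, `n_total`; counts partition the group size per pathway.
#' @export
count_by_pathway <- function(calls, groups) {
  labels <- as_diet_labels(groups)
  unlabeled <- setdiff(unique(calls$mag_id), names(labels))
  if (length(unlabeled)) {
    md_error("magdiet_labeling_error", "unlabeled MAG(s): %s",
             paste(unlabeled, collapse = ", "))
  }
  calls$diet <- labels[calls$mag_id]
  grid <- expand.grid(pathway_id = unique(calls$pathway_id),
                      diet = unique(labels),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tally <- function(p, d, s) {
    sum(calls$pathway_id == p & calls$diet == d & calls$status == s)
  }
  grid$n_complete <- mapply(tally, grid$pathway_id, grid$diet, "complete")
  grid$n_partial  <- mapply(tally, grid$pathway_id, grid$diet, "partial")
  grid$n_absent   <- mapply(tally, grid$pathway_id, grid$diet, "absent")
  grid$n_total    <- grid$n_complete + grid$n_partial + grid$n_absent
  grid
}

# normalize diet labels to a named character vector mag_id -> diet
as_diet_labels <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("mag_id", "diet") %in% names(groups))) {
      md_error("magdiet_schema_error", "diet design needs mag_id and diet columns")
    }
    labels <- stats::setNames(as.character(groups$diet), groups$mag_id)
  } else {
    labels <- groups
  }
  if (is.null(names(labels)) || anyDuplicated(names(labels))) {
    md_error("magdiet_labeling_error",
             "diet labels must be uniquely named by mag_id")
  }
  labels
}
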