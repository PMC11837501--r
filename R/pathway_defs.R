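# Pathway definitions: declarative rules evaluated against a MAG's gene
# families. Categories:
#   degradation_chain : polymer -> monomer chain, complete only if every step
#                       is satisfied (start-to-finish hydrolysis)
#   enzyme_fraction   : complete when >= threshold of the steps are satisfied
#                       (default 0.8, the "at least 80% of the enzymes" rule)
#   gene_set_all      : complete only when all genes are present
#   marker            : a single diagnostic step
#   any_of_pathways   : complete when any member pathway is complete

PATHWAY_CATEGORIES <- c("degradation_chain", "enzyme_fraction", "gene_set_all",
                        "marker", "any_of_pathways")
SUBSTRATE_CLASSES <- c("cellulose", "hemicellulose", "starch", "chitin",
                       "protein", "fatty_acid", "other")

new_pathway_def <- function(pathway_id, category, steps = NULL,
                            threshold = NULL, members = NULL,
                            substrate_class = NULL, name = pathway_id) {
  def <- structure(
    list(pathway_id = pathway_id, name = name, category = category,
         steps = steps, threshold = threshold, members = members,
         substrate_class = substrate_class),
    class = "pathway_def")
  validate_pathway_def(def)
  def
}

validate_pathway_def <- function(def) {
  if (!(def$category %in% PATHWAY_CATEGORIES)) {
    md_error("magdiet_definition_error", "pathway '%s': unknown category '%s'",
             def$pathway_id, def$category)
  }
  if (!is.null(def$substrate_class) &&
      !(def$substrate_class %in% SUBSTRATE_CLASSES)) {
    md_error("magdiet_definition_error",
             "pathway '%s': unknown substrate_class '%s'",
             def$pathway_id, def$substrate_class)
  }
  nsteps <- length(def$steps)
  min_steps <- switch(def$category,
                      degradation_chain = 1L, gene_set_all = 1L,
                      enzyme_fraction = 2L, marker = 1L, any_of_pathways = 0L)
  if (def$category == "any_of_pathways") {
    if (nsteps > 0L) {
      md_error("magdiet_definition_error",
               "pathway '%s': any_of_pathways cannot carry steps", def$pathway_id)
    }
    if (length(def$members) < 2L) {
      md_error("magdiet_definition_error",
               "pathway '%s': any_of_pathways needs >= 2 members", def$pathway_id)
    }
  } else {
    if (nsteps < min_steps) {
      md_error("magdiet_definition_error",
               "pathway '%s': category %s needs >= %d step(s), got %d",
               def$pathway_id, def$category, min_steps, nsteps)
    }
    if (def$category == "marker" && nsteps != 1L) {
      md_error("magdiet_definition_error",
               "pathway '%s': marker must have exactly 1 step", def$pathway_id)
    }
    for (st in def$steps) {
      if (is.null(st$step_id) || !length(st$alternatives)) {
        md_error("magdiet_definition_error",
                 "pathway '%s': step without id or alternatives", def$pathway_id)
      }
    }
  }
  if (!is.null(def$threshold)) {
    if (def$category != "enzyme_fraction") {
      md_error("magdiet_definition_error",
               "pathway '%s': threshold only allowed for enzyme_fraction",
               def$pathway_id)
    }
    if (def$threshold <= 0 || def$threshold > 1) {
      md_error("magdiet_definition_error",
               "pathway '%s': threshold must lie in (0, 1]", def$pathway_id)
    }
  }
  if (def$category == "enzyme_fraction" && is.null(def$threshold)) {
    md_error("magdiet_definition_error",
             "pathway '%s': enzyme_fraction requires a threshold", def$pathway_id)
  }
  invisible(def)
}

#' Read pathway definitions
#'
#' Parses a YAML pathway file into validated definitions. The shipped default
#' ([default_pathway_file()]) covers polysaccharide degradation chains
#' (cellulose, xylan, mannan, xyloglucan, chitin by two routes), starch,
#' central carbon and fermentation pathways, hydrogenase markers, and B
#' vitamin biosynthesis. Missing `threshold` on an `enzyme_fraction` pathway
#' is filled with the default 0.8; member references of `any_of_pathways`
#' must resolve without cycles.
#'
#' @param path YAML file; defaults to the shipped set.
#' @param default_threshold fraction filled in for `enzyme_fraction`
#'   definitions that omit one.
#' @return named list of `pathway_def` objects, class `pathway_defs`.
#' @export
read_pathway_defs <- function(path = default_pathway_file(),
                              default_threshold = 0.8) {
  if (!file.exists(path)) md_error("magdiet_io_error", "file not found: %s", path)
  doc <- yaml::read_yaml(path)
  entries <- doc$pathways
  if (is.null(entries)) md_error("magdiet_schema_error", "no 'pathways' key in %s", path)
  defs <- lapply(entries, function(e) {
    steps <- NULL
    if (!is.null(e$steps)) {
      steps <- lapply(e$steps, function(st) {
        alts <- unlist(st$alternatives, use.names = FALSE)
        fam <- split_family_key(toupper(alts))
        list(step_id = st$step_id,
             alternatives = family_key(fam$namespace, fam$family_id))
      })
    }
    thr <- e$threshold
    if (identical(e$category, "enzyme_fraction") && is.null(thr)) {
      thr <- default_threshold
    }
    new_pathway_def(
      pathway_id = e$pathway_id,
      name = if (is.null(e$name)) e$pathway_id else e$name,
      category = e$category,
      steps = steps,
      threshold = thr,
      members = if (is.null(e$members)) NULL else unlist(e$members),
      substrate_class = e$substrate_class)
  })
  names(defs) <- vapply(defs, `[[`, "", "pathway_id")
  if (anyDuplicated(names(defs))) {
    md_error("magdiet_definition_error", "duplicate pathway_id in %s", path)
  }
  resolve_members(defs)
  structure(defs, class = "pathway_defs")
}

# check that any_of members resolve and contain no cycles (transitively)
resolve_members <- function(defs) {
  visit <- function(id, stack) {
    if (id %in% stack) {
      md_error("magdiet_cycle_error", "cycle in any_of_pathways members: %s",
               paste(c(stack, id), collapse = " -> "))
    }
    def <- defs[[id]]
    if (is.null(def)) {
      md_error("magdiet_reference_error", "dangling member pathway_id '%s'", id)
    }
    if (def$category == "any_of_pathways") {
      for (m in def$members) visit(m, c(stack, id))
    }
  }
  for (def in defs) {
    if (def$category == "any_of_pathways") for (m in def$members) visit(m, def$pathway_id)
  }
  invisible(TRUE)
}

#' @export
print.pathway_defs <- function(x, ...) {
  cat(sprintf("pathway_defs: %d definitions\n", length(x)))
  for (def in x) {
    extra <- if (def$category == "any_of_pathways") {
      sprintf("members: %s", paste(def$members, collapse = ", "))
    } else {
      sprintf("%d step(s)%s", length(def$steps),
              if (!is.null(def$threshold)) sprintf(", threshold %.2f", def$threshold) else "")
    }
    cat(sprintf("  %-32s %-17s %s\n", def$pathway_id, def$category, extra))
  }
  invisible(x)
}

#' Read the substrate family configuration
#'
#' Family membership per substrate class (used for copy totals in the profile
#' matrix) plus the amylase/exopeptidase/beta-glucosidase lists and
#' strict-inequality thresholds behind the substrate-listing rules.
#'
#' @param path YAML file; defaults to the shipped configuration.
#' @return list with elements `substrate_classes` (named list of canonical
#'   family keys), `amylase_families`, `exopeptidase_families`,
#'   `beta_glucosidase_families`, and `thresholds`.
#' @export
read_substrate_config <- function(path = default_substrate_file()) {
  if (!file.exists(path)) md_error("magdiet_io_error", "file not found: %s", path)
  doc <- yaml::read_yaml(path)
  canon <- function(x) {
    fam <- split_family_key(unlist(x, use.names = FALSE))
    unique(family_key(fam$namespace, fam$family_id))
  }
  cfg <- list(
    substrate_classes = lapply(doc$substrate_classes, canon),
    amylase_families = canon(doc$amylase_families),
    exopeptidase_families = canon(doc$exopeptidase_families),
    beta_glucosidase_families = canon(doc$beta_glucosidase_families),
    thresholds = doc$thresholds
  )
  if (is.null(cfg$thresholds$amylase_min)) cfg$thresholds$amylase_min <- 5
  if (is.null(cfg$thresholds$exopeptidase_min)) cfg$thresholds$exopeptidase_min <- 10
  cfg
}
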