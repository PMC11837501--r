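# Synthetic gut-community generator: annotation matrices, MAG metadata,
# diet designs and marker tables with the statistical structure the analysis
# assumes, plus ground-truth labels for recovery testing.
#
# Copy counts are shifted-Poisson (1 + Poisson(lambda)) so a "present"
# family always has >= 1 copy, matching the presence/absence semantics of
# the pathway rules. Ground-truth degrader status is recomputed from the
# emitted presence pattern by a deliberately independent inline tally (not
# by calling the pathway engine), so generator and engine act as mutual
# oracles.

#' Build and validate a simulation configuration
#'
#' @param groups group (diet) labels.
#' @param mags_per_group integer vector (recycled) of MAGs per group.
#' @param completeness_range genome completeness percentage range, within
#'   (50, 100].
#' @param contamination_range contamination percentage range, within [0, 20].
#' @param base_rate baseline mean copy count per present family (> 0); a
#'   present family receives `1 + Poisson(base_rate * factor - 1)` copies
#'   (intensity floored at 0).
#' @param step_presence baseline per-step Bernoulli presence probability.
#' @param enrichment named list: group -> named numeric vector of
#'   multiplicative copy-rate factors per substrate class (unlisted factors
#'   are 1).
#' @param step_presence_overrides named list: group -> named numeric vector
#'   of per-pathway presence probabilities overriding `step_presence`.
#' @param seed integer RNG seed.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(groups = c("piscivorous", "herbivorous",
                                         "invertivorous"),
                              mags_per_group = c(18L, 18L, 7L),
                              completeness_range = c(70, 100),
                              contamination_range = c(0, 10),
                              base_rate = 3,
                              step_presence = 0.7,
                              enrichment = list(
                                herbivorous = c(cellulose = 2, hemicellulose = 2,
                                                chitin = 2, starch = 2),
                                piscivorous = c(protein = 2),
                                invertivorous = c(protein = 2)),
                              step_presence_overrides = list(
                                piscivorous = c(beta_oxidation = 0.85),
                                invertivorous = c(beta_oxidation = 0.85),
                                herbivorous = c(beta_oxidation = 0.5)),
                              seed = 1L) {
  if (length(groups) < 2L) {
    md_error("magdiet_config_error", "config field 'groups': need >= 2 groups")
  }
  # the shipped defaults are keyed by the default diet labels; with custom
  # groups, default entries for absent groups are dropped rather than flagged
  if (missing(enrichment)) enrichment <- enrichment[names(enrichment) %in% groups]
  if (missing(step_presence_overrides)) {
    step_presence_overrides <-
      step_presence_overrides[names(step_presence_overrides) %in% groups]
  }
  mags_per_group <- rep_len(as.integer(mags_per_group), length(groups))
  if (any(mags_per_group < 2L)) {
    md_error("magdiet_config_error",
             "config field 'mags_per_group': need >= 2 MAGs per group")
  }
  chk_range <- function(r, lo, hi, field) {
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < lo || r[2L] > hi) {
      md_error("magdiet_config_error",
               "config field '%s': must be an ordered range within [%g, %g]",
               field, lo, hi)
    }
  }
  chk_range(completeness_range, 50, 100, "completeness_range")
  chk_range(contamination_range, 0, 20, "contamination_range")
  if (base_rate <= 0) {
    md_error("magdiet_config_error", "config field 'base_rate': must be > 0")
  }
  if (step_presence < 0 || step_presence > 1) {
    md_error("magdiet_config_error",
             "config field 'step_presence': must lie in [0, 1]")
  }
  for (g in names(enrichment)) {
    if (!(g %in% groups)) {
      md_error("magdiet_config_error",
               "config field 'enrichment': unknown group '%s'", g)
    }
    if (any(enrichment[[g]] < 0)) {
      md_error("magdiet_config_error",
               "config field 'enrichment': factors must be >= 0")
    }
  }
  for (g in names(step_presence_overrides)) {
    p <- step_presence_overrides[[g]]
    if (any(p < 0 | p > 1)) {
      md_error("magdiet_config_error",
               "config field 'step_presence_overrides': probabilities in [0, 1]")
    }
  }
  structure(list(groups = groups, mags_per_group = mags_per_group,
                 completeness_range = completeness_range,
                 contamination_range = contamination_range,
                 base_rate = base_rate, step_presence = step_presence,
                 enrichment = enrichment,
                 step_presence_overrides = step_presence_overrides,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

copy_intensity <- function(base_rate, factor) max(base_rate * factor - 1, 0)

#' Simulate a diet-structured gut community
#'
#' Draws MAG metadata (completeness and contamination uniform within the
#' configured ranges), per-MAG gene-family copy counts (per-step Bernoulli
#' presence over the pathway definitions, with one alternative family chosen
#' per satisfied step, plus per-family presence over the substrate-class
#' family pools), and a diet design. Enrichment factors multiply the copy
#' intensity of families belonging to the enriched substrate class in the
#' enriched group.
#'
#' @param config a [simulation_config()].
#' @param defs pathway definitions used as the gene-content template.
#' @param substrate_config substrate family configuration (free family pools
#'   and class membership for enrichment).
#' @return list of class `simulated_community`: `mags` (a `mag_table`),
#'   `annotations` (an `annotation_matrix`), `design` (`mag_id`/`diet`
#'   data.frame), and `truth` (per-MAG degrader status per substrate-tagged
#'   pathway, beta-oxidation flags, and the configured enrichment factors).
#' @export
simulate_community <- function(config = simulation_config(),
                               defs = read_pathway_defs(),
                               substrate_config = read_substrate_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  step_defs <- defs[vapply(defs, function(d) d$category != "any_of_pathways",
                           TRUE)]
  # substrate class per family key (for enrichment lookup)
  fam_class <- list()
  for (cls in names(substrate_config$substrate_classes)) {
    for (f in substrate_config$substrate_classes[[cls]]) {
      fam_class[[f]] <- c(fam_class[[f]], cls)
    }
  }
  def_families <- unique(unlist(lapply(step_defs, function(d)
    unlist(lapply(d$steps, `[[`, "alternatives")))))
  pool_families <- setdiff(unlist(substrate_config$substrate_classes),
                           def_families)

  diets <- rep(config$groups, config$mags_per_group)
  mag_ids <- unlist(lapply(seq_along(config$groups), function(gi) {
    sprintf("SIM%d.%03d", gi, seq_len(config$mags_per_group[gi]))
  }))
  n <- length(mag_ids)

  presence_p <- function(group, pathway_id) {
    ov <- config$step_presence_overrides[[group]]
    if (!is.null(ov) && pathway_id %in% names(ov)) ov[[pathway_id]]
    else config$step_presence
  }
  enrich_factor <- function(group, fam) {
    e <- config$enrichment[[group]]
    if (is.null(e)) return(1)
    cls <- fam_class[[fam]]
    if (is.null(cls)) return(1)
    f <- e[names(e) %in% cls]
    if (length(f)) max(f) else 1
  }

  long <- vector("list", n)
  for (i in seq_len(n)) {
    g <- diets[i]
    fams <- character(0); counts <- integer(0)
    for (d in step_defs) {
      p <- presence_p(g, d$pathway_id)
      for (st in d$steps) {
        if (stats::runif(1) < p) {
          fam <- st$alternatives[sample.int(length(st$alternatives), 1L)]
          lam <- copy_intensity(config$base_rate, enrich_factor(g, fam))
          fams <- c(fams, fam)
          counts <- c(counts, 1L + stats::rpois(1L, lam))
        }
      }
    }
    for (fam in pool_families) {
      if (stats::runif(1) < config$step_presence) {
        lam <- copy_intensity(config$base_rate, enrich_factor(g, fam))
        fams <- c(fams, fam)
        counts <- c(counts, 1L + stats::rpois(1L, lam))
      }
    }
    long[[i]] <- if (length(fams)) {
      fk <- split_family_key(fams)
      data.frame(mag_id = mag_ids[i], namespace = fk$namespace,
                 family_id = fk$family_id, count = counts,
                 stringsAsFactors = FALSE)
    } else NULL
  }
  annotations <- as_annotation_matrix(do.call(rbind, long), all_mags = mag_ids)
  annotations <- annotations[mag_ids, , drop = FALSE]
  class(annotations) <- c("annotation_matrix", "matrix", "array")

  mags <- data.frame(mag_id = mag_ids, stringsAsFactors = FALSE)
  for (rank in LINEAGE_RANKS) mags[[rank]] <- ""
  mags$domain <- "Bacteria"
  mags$completeness <- stats::runif(n, config$completeness_range[1L],
                                    config$completeness_range[2L])
  mags$contamination <- stats::runif(n, config$contamination_range[1L],
                                     config$contamination_range[2L])
  mags$coverage <- stats::rlnorm(n, meanlog = 2.5, sdlog = 1)
  mags$ani_nearest <- NA_real_
  mags$red <- NA_real_
  mags$neighbor_accession <- NA_character_
  class(mags) <- c("mag_table", "data.frame")

  truth <- list(
    degraders = truth_degrader_table(annotations, defs),
    beta_oxidation = truth_beta_flags(annotations, defs[["beta_oxidation"]]),
    enrichment = config$enrichment
  )
  structure(list(mags = mags, annotations = annotations,
                 design = data.frame(mag_id = mag_ids, diet = diets,
                                     stringsAsFactors = FALSE),
                 truth = truth, config = config),
            class = "simulated_community")
}

# ---- independent ground-truth tally ----------------------------------------
# Same rules as the pathway engine, coded independently over the emitted
# presence pattern: plain loops, presence = copy count >= 1.

truth_status_one <- function(present_families, def, defs) {
  if (def$category == "any_of_pathways") {
    best <- 0
    any_complete <- FALSE
    for (m in def$members) {
      sub <- truth_status_one(present_families, defs[[m]], defs)
      if (sub$fraction > best) best <- sub$fraction
      if (sub$status == "complete") any_complete <- TRUE
    }
    status <- if (best == 0) "absent" else if (any_complete) "complete" else "partial"
    return(list(status = status, fraction = best))
  }
  n_sat <- 0L
  for (st in def$steps) {
    hit <- FALSE
    for (alt in st$alternatives) {
      if (alt %in% present_families) { hit <- TRUE; break }
    }
    if (hit) n_sat <- n_sat + 1L
  }
  frac <- n_sat / length(def$steps)
  complete <- if (def$category == "enzyme_fraction") {
    frac >= def$threshold - 1e-12
  } else {
    n_sat == length(def$steps)
  }
  status <- if (n_sat == 0L) "absent" else if (complete) "complete" else "partial"
  list(status = status, fraction = frac)
}

truth_degrader_table <- function(annotations, defs) {
  tagged <- names(defs)[!vapply(defs, function(d) is.null(d$substrate_class),
                                TRUE)]
  rows <- list()
  for (m in rownames(annotations)) {
    present <- colnames(annotations)[annotations[m, ] >= 1]
    for (p in tagged) {
      ts <- truth_status_one(present, defs[[p]], defs)
      rows[[length(rows) + 1L]] <- data.frame(
        mag_id = m, pathway_id = p, status = ts$status,
        fraction = ts$fraction, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

truth_beta_flags <- function(annotations, beta_def) {
  vapply(rownames(annotations), function(m) {
    present <- colnames(annotations)[annotations[m, ] >= 1]
    ok <- TRUE
    for (st in beta_def$steps) {
      if (!any(st$alternatives %in% present)) { ok <- FALSE; break }
    }
    as.integer(ok)
  }, 0L)
}

#' Simulate a community with no diet effect
#'
#' Same generative process as [simulate_community()] with every enrichment
#' factor equal to 1 and no per-group presence overrides, so the group
#' distributions are identical (exchangeable labels). Drives type-I error
#' calibration of the permutation tests.
#'
#' @param config a [simulation_config()]; its `enrichment` and
#'   `step_presence_overrides` are discarded.
#' @inheritParams simulate_community
#' @return as [simulate_community()].
#' @export
simulate_null <- function(config = simulation_config(),
                          defs = read_pathway_defs(),
                          substrate_config = read_substrate_config()) {
  config$enrichment <- list()
  config$step_presence_overrides <- list()
  simulate_community(config, defs, substrate_config)
}

#' Simulate marker-gene coverage records
#'
#' Coverages proportional to the target abundances times a depth scale, with
#' multiplicative log-normal noise. [marker_profile()] on the output recovers
#' the input abundances, with error shrinking as depth grows relative to the
#' noise.
#'
#' @param abundances named non-negative fractions summing to 1 (taxon ->
#'   target relative abundance).
#' @param depth total coverage scale.
#' @param noise_sd log-normal sdlog of the multiplicative noise (0 = exact).
#' @param markers_per_taxon marker records per taxon (coverage split evenly
#'   before noise).
#' @param seed optional RNG seed.
#' @return data.frame in [read_marker_table()] layout.
#' @export
simulate_markers <- function(abundances, depth = 100, noise_sd = 0,
                             markers_per_taxon = 1L, seed = NULL) {
  if (any(abundances < 0) || abs(sum(abundances) - 1) > 1e-8) {
    md_error("magdiet_validation_error",
             "abundances must be >= 0 and sum to 1")
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (tax in names(abundances)) {
    base <- abundances[[tax]] * depth / markers_per_taxon
    for (j in seq_len(markers_per_taxon)) {
      noise <- if (noise_sd > 0) stats::rlnorm(1L, 0, noise_sd) else 1
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("rps3_%s_%d", tax, j), taxonomy = tax,
        coverage = base * noise, mag_id = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a simulated community to disk
#'
#' Emits the same tab-separated formats the readers consume (MAG table,
#' long-format annotations, diet design) plus the ground-truth tables, which
#' the analysis pipeline never reads.
#'
#' @param sim a `simulated_community`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named output paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mags = file.path(dir, "mags.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "truth_degraders.tsv"))
  write_mag_table(sim$mags, paths[["mags"]])
  write_annotations(sim$annotations, paths[["annotations"]])
  write.table(sim$design, paths[["design"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth$degraders, paths[["truth"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
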