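# Shared fixture builders: everything is generated in code at test time.

# write a YAML pathway file and read it back through the package parser
make_defs <- function(yaml_text) {
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  writeLines(yaml_text, path)
  read_pathway_defs(path)
}

# named copy-count vector in canonical key space
counts_vec <- function(...) {
  x <- c(...)
  names(x) <- toupper(names(x))
  x
}

# small long-format annotation data.frame
ann_df <- function(mag_id, namespace, family_id, count = NULL) {
  df <- data.frame(mag_id = mag_id, namespace = namespace,
                   family_id = family_id, stringsAsFactors = FALSE)
  if (!is.null(count)) df$count <- count
  df
}

# minimal MAG metadata table
make_mags <- function(mag_id, completeness, contamination = 1,
                      class = "Gammaproteobacteria", ani = NA_real_) {
  n <- length(mag_id)
  df <- data.frame(mag_id = mag_id, stringsAsFactors = FALSE)
  for (rank in c("domain", "phylum", "class", "order", "family",
                 "genus", "species")) df[[rank]] <- ""
  df$class <- rep_len(class, n)
  df$completeness <- rep_len(completeness, n)
  df$contamination <- rep_len(contamination, n)
  df$coverage <- 10
  df$ani_nearest <- rep_len(ani, n)
  df$red <- NA_real_
  df$neighbor_accession <- NA_character_
  class(df) <- c("mag_table", "data.frame")
  df
}

# diet labels for the shipped reef-fish table, from the MAG id prefix
reef_fish_diets <- function(mags) {
  diet <- ifelse(grepl("^H1N1", mags$mag_id), "piscivorous",
          ifelse(grepl("^T4LTN", mags$mag_id), "herbivorous",
                 "invertivorous"))
  stats::setNames(diet, mags$mag_id)
}

# independent brute-force pathway evaluation used as an oracle: direct loops
# over steps, no shared code with the package internals
oracle_eval <- function(present_keys, def, defs) {
  if (def$category == "any_of_pathways") {
    subs <- lapply(def$members, function(m)
      oracle_eval(present_keys, defs[[m]], defs))
    frac <- max(vapply(subs, `[[`, 0, "fraction"))
    complete <- any(vapply(subs, `[[`, "", "status") == "complete")
    status <- if (frac == 0) "absent" else if (complete) "complete" else "partial"
    return(list(status = status, fraction = frac))
  }
  sat <- 0
  for (st in def$steps) {
    if (any(st$alternatives %in% present_keys)) sat <- sat + 1
  }
  frac <- sat / length(def$steps)
  complete <- switch(def$category,
                     enzyme_fraction = frac >= def$threshold - 1e-12,
                     sat == length(def$steps))
  status <- if (sat == 0) "absent" else if (complete) "complete" else "partial"
  list(status = status, fraction = frac)
}
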