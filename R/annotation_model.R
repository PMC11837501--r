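#' @importFrom stats sd var pchisq pf dist rnorm runif rpois rlnorm
#' @importFrom utils read.delim write.table combn head
NULL

# ---- error helper -----------------------------------------------------------

md_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "magdiet_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# ---- gene family identity ---------------------------------------------------

NAMESPACES <- c("CAZY", "KO", "MEROPS", "HYDDB", "CUSTOM")

#' Canonical gene-family key
#'
#' Gene families are identified by a namespace (CAZy family, KEGG Orthology,
#' MEROPS peptidase family, HydDB hydrogenase group, or custom) plus a family
#' identifier. Identity is case-insensitive and whitespace-insensitive on the
#' identifier, so dbCAN/KO outputs with inconsistent casing collapse to one
#' family.
#'
#' @param namespace character vector of namespace tokens (one of CAZY, KO,
#'   MEROPS, HYDDB, CUSTOM; case-insensitive).
#' @param family_id character vector of family identifiers (e.g. "GH5",
#'   "K00016", "M01").
#' @return character vector of canonical `"NAMESPACE:FAMILY"` keys.
#' @export
family_key <- function(namespace, family_id) {
  ns <- toupper(trimws(namespace))
  bad <- !(ns %in% NAMESPACES)
  if (any(bad)) {
    md_error("magdiet_schema_error", "unknown namespace token(s): %s",
             paste(unique(namespace[bad]), collapse = ", "))
  }
  paste0(ns, ":", toupper(trimws(family_id)))
}

# split canonical keys back into namespace / family id
split_family_key <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(
    namespace = vapply(parts, `[[`, "", 1L),
    family_id = vapply(parts, function(p) paste(p[-1L], collapse = ":"), ""),
    stringsAsFactors = FALSE
  )
}

# ---- MAG metadata -----------------------------------------------------------

LINEAGE_RANKS <- c("domain", "phylum", "class", "order", "family",
                   "genus", "species")

#' Read a MAG metadata table
#'
#' Reads a tab-separated table of MAG (metagenome-assembled genome) metadata:
#' identifier, lineage (domain through species), completeness and
#' contamination percentages, mean read coverage, and ANI to the nearest
#' reference genome. The ANI column accepts the `"RED, <x>"` dialect: such
#' cells are parsed into a relative evolutionary distance (`red`) with
#' `ani_nearest` left missing, mirroring taxonomy pipelines that fall back to
#' RED when ANI placement fails.
#'
#' A quality gate in the spirit of standard MAG retention rules
#' (completeness >= 50%, contamination <= 20%) is applied at read time by
#' default; set `quality_filter = FALSE` to keep every row.
#'
#' @param path path to the tab-separated file. Required columns: `mag_id`,
#'   `completeness`, `contamination`, `coverage`; lineage columns
#'   (`domain`..`species`), `ani_or_red` and `neighbor_accession` are
#'   optional.
#' @param quality_filter apply the completeness/contamination gate?
#' @param min_completeness,max_contamination gate thresholds (percent).
#' @return a `data.frame` of class `mag_table` with columns `mag_id`, the
#'   seven lineage ranks, `completeness`, `contamination`, `coverage`,
#'   `ani_nearest`, `red`, `neighbor_accession`. Missing ANI/RED are `NA`.
#' @export
read_mag_table <- function(path, quality_filter = TRUE,
                           min_completeness = 50, max_contamination = 20) {
  if (!file.exists(path)) md_error("magdiet_io_error", "file not found: %s", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE, na.strings = NULL, quote = "")
  required <- c("mag_id", "completeness", "contamination", "coverage")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    md_error("magdiet_schema_error", "missing required column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  parse_num <- function(col, what, allow_empty = FALSE) {
    x <- trimws(raw[[col]])
    if (allow_empty) x[x == "" | x == "n/a" | x == "NA" | x == "-"] <- NA
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      md_error("magdiet_parse_error", "non-numeric %s at data row %d: '%s'",
               what, bad[1L], x[bad[1L]])
    }
    out
  }
  out <- data.frame(mag_id = trimws(raw$mag_id), stringsAsFactors = FALSE)
  for (rank in LINEAGE_RANKS) {
    v <- if (rank %in% names(raw)) trimws(raw[[rank]]) else rep("", n)
    v[v == "-"] <- ""
    out[[rank]] <- v
  }
  out$completeness  <- parse_num("completeness", "completeness")
  out$contamination <- parse_num("contamination", "contamination")
  out$coverage      <- parse_num("coverage", "coverage")
  ani <- rep(NA_real_, n)
  red <- rep(NA_real_, n)
  if ("ani_or_red" %in% names(raw)) {
    cell <- trimws(raw$ani_or_red)
    is_red <- grepl("^RED[ ,]", cell, ignore.case = TRUE)
    red[is_red] <- suppressWarnings(
      as.numeric(sub("^RED[ ,]+", "", cell[is_red], ignore.case = TRUE)))
    plain <- !is_red & cell != "" & cell != "n/a" & cell != "NA"
    ani[plain] <- suppressWarnings(as.numeric(cell[plain]))
    bad <- which(plain & is.na(ani))
    if (length(bad)) {
      md_error("magdiet_parse_error", "unparseable ANI/RED cell at data row %d: '%s'",
               bad[1L], cell[bad[1L]])
    }
  }
  out$ani_nearest <- ani
  out$red <- red
  out$neighbor_accession <- if ("neighbor_accession" %in% names(raw)) {
    acc <- trimws(raw$neighbor_accession); acc[acc %in% c("n/a", "")] <- NA; acc
  } else rep(NA_character_, n)

  dup <- out$mag_id[duplicated(out$mag_id)]
  if (length(dup)) {
    md_error("magdiet_uniqueness_error", "duplicate mag_id: %s",
             paste(unique(dup), collapse = ", "))
  }
  if (any(out$completeness < 0 | out$completeness > 100, na.rm = TRUE) ||
      any(is.na(out$completeness))) {
    md_error("magdiet_validation_error", "completeness must be in [0, 100]")
  }
  if (any(is.na(out$contamination) | out$contamination < 0)) {
    md_error("magdiet_validation_error", "contamination must be >= 0")
  }
  if (quality_filter) {
    keep <- out$completeness >= min_completeness &
      out$contamination <= max_contamination
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("mag_table", "data.frame")
  out
}

#' Write a MAG metadata table
#'
#' Inverse of [read_mag_table()]; `ani_nearest`/`red` are folded back into a
#' single `ani_or_red` column using the `"RED, <x>"` dialect.
#'
#' @param mags a `mag_table` data.frame.
#' @param path output path.
#' @export
write_mag_table <- function(mags, path) {
  ani_or_red <- ifelse(!is.na(mags$ani_nearest),
                       format(mags$ani_nearest, trim = TRUE, scientific = FALSE),
                       ifelse(!is.na(mags$red),
                              paste0("RED, ", format(mags$red, trim = TRUE)),
                              ""))
  out <- data.frame(mag_id = mags$mag_id, stringsAsFactors = FALSE)
  for (rank in LINEAGE_RANKS) out[[rank]] <- mags[[rank]]
  out$completeness  <- mags$completeness
  out$contamination <- mags$contamination
  out$coverage      <- mags$coverage
  out$ani_or_red    <- ani_or_red
  out$neighbor_accession <- ifelse(is.na(mags$neighbor_accession), "n/a",
                                   mags$neighbor_accession)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- annotation matrix ------------------------------------------------------

#' Build an annotation matrix from long-format records
#'
#' @param df data.frame with columns `mag_id`, `namespace`, `family_id` and
#'   optionally `count` (absent count = one gene hit per row). Rows are
#'   aggregated by summation; family identity is case-insensitive.
#' @param all_mags optional character vector of MAG ids that must appear as
#'   rows even when they have no annotations (all-zero rows).
#' @return integer matrix of class `annotation_matrix` (MAGs x families);
#'   column names are canonical `"NAMESPACE:FAMILY"` keys.
#' @export
as_annotation_matrix <- function(df, all_mags = NULL) {
  need <- c("mag_id", "namespace", "family_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    md_error("magdiet_schema_error", "missing required column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  count <- if ("count" %in% names(df)) suppressWarnings(as.numeric(df$count)) else rep(1, nrow(df))
  count[is.na(count) & !("count" %in% names(df))] <- 1
  if (any(is.na(count))) md_error("magdiet_parse_error", "non-numeric count value")
  if (any(count < 0)) md_error("magdiet_validation_error", "negative gene copy count")
  if (any(count != floor(count))) {
    md_error("magdiet_validation_error", "gene copy counts must be integers")
  }
  keys <- family_key(df$namespace, df$family_id)
  mags <- unique(c(as.character(df$mag_id), all_mags))
  fams <- unique(keys)
  mat <- matrix(0L, nrow = length(mags), ncol = length(fams),
                dimnames = list(mags, fams))
  if (nrow(df)) {
    agg <- tapply(count, list(factor(df$mag_id, levels = mags),
                              factor(keys, levels = fams)), sum)
    agg[is.na(agg)] <- 0
    mat[rownames(agg), colnames(agg)] <- as.integer(agg)
  }
  structure(mat, class = c("annotation_matrix", class(mat)))
}

#' Read a long-format gene-family annotation table
#'
#' Adapter for dbCAN-style and KO-annotation-style outputs flattened to
#' `(mag_id, namespace, family_id[, count])` tab-separated rows.
#'
#' @inheritParams as_annotation_matrix
#' @param path path to the tab-separated file.
#' @return an `annotation_matrix`.
#' @export
read_annotations <- function(path, all_mags = NULL) {
  if (!file.exists(path)) md_error("magdiet_io_error", "file not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE, quote = "")
  if ("count" %in% names(df)) df$count <- as.numeric(df$count)
  as_annotation_matrix(df, all_mags = all_mags)
}

#' Write an annotation matrix as long-format rows
#'
#' Only non-zero cells are written; reading the result back reproduces the
#' matrix exactly (up to all-zero rows, which can be reinstated via
#' `all_mags`).
#'
#' @param mat an `annotation_matrix`.
#' @param path output path.
#' @export
write_annotations <- function(mat, path) {
  idx <- which(mat > 0, arr.ind = TRUE)
  keys <- colnames(mat)[idx[, 2L]]
  fam <- split_family_key(keys)
  out <- data.frame(mag_id = rownames(mat)[idx[, 1L]],
                    namespace = fam$namespace,
                    family_id = fam$family_id,
                    count = mat[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(out$mag_id, out$namespace, out$family_id), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that annotated MAGs match a metadata table
#'
#' Every MAG id present in the annotation matrix must have a metadata record;
#' mismatches are reported, never silently dropped.
#'
#' @param mat an `annotation_matrix`.
#' @param mags a `mag_table`.
#' @return invisibly `TRUE`; errors with the offending ids otherwise.
#' @export
check_annotation_join <- function(mat, mags) {
  orphan <- setdiff(rownames(mat), mags$mag_id)
  if (length(orphan)) {
    md_error("magdiet_join_error",
             "annotated MAG(s) without metadata record: %s",
             paste(orphan, collapse = ", "))
  }
  invisible(TRUE)
}

# ---- marker gene tables -----------------------------------------------------

#' Read a marker-gene (rps3-style) coverage table
#'
#' @param path tab-separated file with columns `gene_id`, `taxonomy`,
#'   `coverage` and optionally `mag_id` (empty = unbinned).
#' @return data.frame with those columns; `mag_id` is `NA` when unbinned.
#' @export
read_marker_table <- function(path) {
  if (!file.exists(path)) md_error("magdiet_io_error", "file not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE, quote = "")
  need <- c("gene_id", "taxonomy", "coverage")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    md_error("magdiet_schema_error", "missing required column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  df$coverage <- suppressWarnings(as.numeric(df$coverage))
  if (any(is.na(df$coverage) | df$coverage < 0)) {
    md_error("magdiet_validation_error", "marker coverage must be numeric and >= 0")
  }
  if (!("mag_id" %in% names(df))) df$mag_id <- NA_character_
  df$mag_id[trimws(df$mag_id) == ""] <- NA_character_
  df
}

# ---- shipped defaults -------------------------------------------------------

#' Paths to shipped default configuration files
#'
#' @return file path within the installed package.
#' @export
default_pathway_file <- function() {
  system.file("extdata", "pathways.yaml", package = "magdiet", mustWork = TRUE)
}

#' @rdname default_pathway_file
#' @export
default_substrate_file <- function() {
  system.file("extdata", "substrate_families.yaml", package = "magdiet",
              mustWork = TRUE)
}

#' @rdname default_pathway_file
#' @export
reef_fish_mag_file <- function() {
  system.file("extdata", "reef_fish_mags.tsv", package = "magdiet",
              mustWork = TRUE)
}

#' @rdname default_pathway_file
#' @export
reef_fish_vitamin_file <- function() {
  system.file("extdata", "reef_fish_vitamins.tsv", package = "magdiet",
              mustWork = TRUE)
}
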