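# Multivariate and rank statistics for diet comparisons, implemented from
# first principles: scaled PCA, one-way PERMANOVA with a permutation null,
# homogeneity of multivariate dispersion, Kruskal-Wallis with tie
# correction, and post-hoc pairwise Wilcoxon rank-sum tests.

# ---- distances --------------------------------------------------------------

#' Pairwise dissimilarity matrix
#'
#' @param x numeric matrix (rows = samples).
#' @param method "euclidean" or "bray" (Bray-Curtis on non-negative data).
#' @return full symmetric matrix of dissimilarities.
#' @export
dissimilarity_matrix <- function(x, method = c("euclidean", "bray")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (method == "euclidean") {
    return(as.matrix(stats::dist(x, method = "euclidean")))
  }
  if (any(x < 0)) {
    md_error("magdiet_domain_error", "Bray-Curtis requires non-negative data")
  }
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- sum(x[i, ]) + sum(x[j, ])
      d[i, j] <- d[j, i] <- if (tot == 0) 0 else
        sum(abs(x[i, ] - x[j, ])) / tot
    }
  }
  d
}

# ---- scaled PCA -------------------------------------------------------------

#' Principal component analysis of a scaled feature matrix
#'
#' Columns are centered and divided by their sample standard deviation, then
#' decomposed by SVD (an eigendecomposition of the correlation structure).
#' Zero-variance columns cannot be scaled and are dropped with a warning.
#'
#' @param x numeric matrix or data.frame of features (rows = samples).
#' @return list of class `pca_result`: `loadings` (feature x component),
#'   `scores` (sample x component), `sdev`, `variance_explained` (fractions
#'   summing to 1), `dropped` (names of zero-variance columns), `center`,
#'   `scale`.
#' @export
scaled_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) md_error("magdiet_domain_error", "PCA needs >= 2 rows")
  sds <- apply(x, 2L, sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning(sprintf("dropping zero-variance column(s): %s",
                    paste(dropped, collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  ctr <- colMeans(x)
  xs <- sweep(sweep(x, 2L, ctr), 2L, sds, "/")
  sv <- svd(xs)
  k <- sum(sv$d > max(sv$d) * 1e-12)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  dimnames(loadings) <- list(colnames(xs), paste0("PC", seq_len(k)))
  dimnames(scores) <- list(rownames(xs), paste0("PC", seq_len(k)))
  ev <- sv$d^2
  structure(list(loadings = loadings, scores = scores,
                 sdev = sv$d[seq_len(k)] / sqrt(nrow(xs) - 1),
                 variance_explained = ev[seq_len(k)] / sum(ev),
                 dropped = dropped, center = ctr, scale = sds),
            class = "pca_result")
}

# ---- permutation machinery --------------------------------------------------

# all distinct assignments of a label multiset to positions (for exact tests)
multiset_permutations <- function(labels) {
  labels <- as.character(labels)
  uniq <- unique(labels)
  counts <- table(factor(labels, levels = uniq))
  recurse <- function(counts) {
    if (sum(counts) == 0L) return(list(character(0)))
    out <- list()
    for (u in names(counts)[counts > 0L]) {
      rest <- counts; rest[u] <- rest[u] - 1L
      for (tail in recurse(rest)) out[[length(out) + 1L]] <- c(u, tail)
    }
    out
  }
  recurse(counts)
}

n_distinct_assignments <- function(labels) {
  tab <- table(labels)
  exp(lgamma(sum(tab) + 1) - sum(lgamma(tab + 1)))
}

check_design <- function(groups) {
  tab <- table(groups)
  if (length(tab) < 2L) md_error("magdiet_design_error", "need >= 2 groups")
  if (any(tab < 2L)) {
    md_error("magdiet_design_error", "group(s) of size < 2: %s",
             paste(names(tab)[tab < 2L], collapse = ", "))
  }
  tab
}

# ---- PERMANOVA --------------------------------------------------------------

#' Permutational multivariate analysis of variance
#'
#' One-way PERMANOVA from a dissimilarity matrix. Total and within-group sums
#' of squares come from the sums-of-squared-dissimilarities identity
#' (`SS = sum over pairs of d^2 / group size`); the pseudo-F is
#' `(SS_between/(k-1)) / (SS_within/(n-k))` and significance is assessed by
#' permuting group labels: `p = (#{F_perm >= F_obs} + 1) / (P + 1)`.
#' When `exact = TRUE` (or `exact = NULL` and the design admits at most
#' `exact_limit` distinct label assignments) every distinct assignment is
#' enumerated instead, and `p` is the exact proportion of assignments with
#' `F >= F_obs` (the observed assignment counts itself).
#'
#' @param x numeric feature matrix, or a precomputed dissimilarity matrix
#'   (`dist` object or full symmetric matrix) if `is_distance = TRUE`.
#' @param groups group label per row.
#' @param distance dissimilarity for feature input ("euclidean" or "bray").
#' @param n_permutations number of random label permutations (>= 99).
#' @param seed integer seed driving the permutation draws.
#' @param exact `TRUE`/`FALSE`/`NULL` (auto).
#' @param exact_limit maximum number of distinct assignments enumerated in
#'   auto mode.
#' @param is_distance is `x` already a dissimilarity matrix?
#' @return list of class `permanova_result`: `pseudo_F`, `R2`, `p_value`,
#'   `n_permutations` (or the enumeration size), `exact`, `seed`,
#'   `ss_between`, `ss_within`, `ss_total`, `df_between`, `df_within`.
#' @export
permanova <- function(x, groups, distance = "euclidean",
                      n_permutations = 999, seed = NULL, exact = NULL,
                      exact_limit = 2000, is_distance = FALSE) {
  d <- if (is_distance) as.matrix(x) else dissimilarity_matrix(x, distance)
  groups <- as.character(groups)
  n <- nrow(d)
  if (length(groups) != n) {
    md_error("magdiet_design_error", "labels do not match rows")
  }
  check_design(groups)
  d2 <- d^2
  ss_total <- sum(d2) / (2 * n)
  if (ss_total <= 0) {
    md_error("magdiet_degenerate_error", "constant data: total SS is zero")
  }
  f_stat <- function(g) {
    z <- stats::model.matrix(~ g - 1)
    ng <- colSums(z)
    ssw <- sum(colSums(z * (d2 %*% z)) / (2 * ng))
    k <- length(ng)
    ((ss_total - ssw) / (k - 1)) / (ssw / (n - k))
  }
  f_obs <- f_stat(factor(groups))
  k <- length(unique(groups))
  if (is.null(exact)) {
    exact <- n_distinct_assignments(groups) <= exact_limit
  }
  if (exact) {
    perms <- multiset_permutations(groups)
    f_perm <- vapply(perms, function(g) f_stat(factor(g)), 0)
    p <- mean(f_perm >= f_obs - 1e-12)
    n_used <- length(perms)
  } else {
    if (n_permutations < 99) {
      md_error("magdiet_config_error", "n_permutations must be >= 99")
    }
    if (!is.null(seed)) set.seed(seed)
    f_perm <- vapply(seq_len(n_permutations), function(i)
      f_stat(factor(sample(groups))), 0)
    p <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_permutations + 1)
    n_used <- n_permutations
  }
  z <- stats::model.matrix(~ factor(groups) - 1)
  ng <- colSums(z)
  ss_within <- sum(colSums(z * (d2 %*% z)) / (2 * ng))
  structure(list(pseudo_F = f_obs, R2 = (ss_total - ss_within) / ss_total,
                 p_value = p, n_permutations = n_used, exact = exact,
                 seed = seed,
                 ss_between = ss_total - ss_within, ss_within = ss_within,
                 ss_total = ss_total, df_between = k - 1, df_within = n - k),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, R2 = %.4f, P = %.4g (%s, %d %s)\n",
              x$pseudo_F, x$R2, x$p_value,
              if (x$exact) "exact" else "sampled", x$n_permutations,
              if (x$exact) "assignments" else "permutations"))
  invisible(x)
}

# ---- dispersion (betadisper-style) -----------------------------------------

#' Homogeneity of multivariate dispersion
#'
#' Embeds the dissimilarity matrix by principal-coordinates analysis (keeping
#' axes with negative eigenvalues and subtracting their squared
#' contributions, the standard correction), computes each sample's distance
#' to its own group centroid in that embedding, and compares group mean
#' distances with a one-way ANOVA F. Significance comes from permuting the
#' group labels of the distances-to-centroid procedure.
#'
#' @inheritParams permanova
#' @return list of class `dispersion_result`: `F`, `p_value`, `distances`
#'   (per-sample distance to own group centroid), `group_means`,
#'   `n_permutations`, `seed`.
#' @export
dispersion_test <- function(x, groups, distance = "euclidean",
                            n_permutations = 999, seed = NULL,
                            is_distance = FALSE) {
  d <- if (is_distance) as.matrix(x) else dissimilarity_matrix(x, distance)
  groups <- factor(as.character(groups))
  n <- nrow(d)
  check_design(groups)
  # principal coordinates with negative-eigenvalue bookkeeping
  a <- -0.5 * d^2
  j <- diag(n) - matrix(1 / n, n, n)
  g <- j %*% a %*% j
  eg <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-8
  keep <- abs(eg$values) > tol
  lambda <- eg$values[keep]
  coords <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(abs(lambda)),
                                                      sum(keep))
  pos <- lambda > 0
  dist_to_centroid <- function(g) {
    z <- numeric(n)
    for (lev in levels(g)) {
      idx <- which(g == lev)
      ctr <- colMeans(coords[idx, , drop = FALSE])
      dev2 <- sweep(coords[idx, , drop = FALSE], 2L, ctr)^2
      d2 <- rowSums(dev2[, pos, drop = FALSE]) -
        (if (any(!pos)) rowSums(dev2[, !pos, drop = FALSE]) else 0)
      z[idx] <- sqrt(pmax(d2, 0))
    }
    z
  }
  z <- dist_to_centroid(groups)
  anova_f <- function(vals, g) {
    gm <- tapply(vals, g, mean)
    ng <- tabulate(g)
    ssb <- sum(ng * (gm - mean(vals))^2)
    ssw <- sum((vals - gm[as.integer(g)])^2)
    k <- nlevels(g)
    if (ssw == 0) return(if (ssb == 0) 0 else Inf)
    (ssb / (k - 1)) / (ssw / (length(vals) - k))
  }
  f_obs <- anova_f(z, groups)
  if (!is.null(seed)) set.seed(seed)
  f_perm <- vapply(seq_len(n_permutations), function(i) {
    anova_f(z, groups[sample.int(n)])
  }, 0)
  p <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_permutations + 1)
  structure(list(F = f_obs, p_value = p,
                 distances = stats::setNames(z, rownames(d)),
                 group_means = tapply(z, groups, mean),
                 n_permutations = n_permutations, seed = seed),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("Homogeneity of dispersion: F = %.4f, P = %.4g (%d permutations)\n",
              x$F, x$p_value, x$n_permutations))
  invisible(x)
}

# ---- rank tests -------------------------------------------------------------

#' Kruskal-Wallis test with tie correction and post-hoc rank-sum tests
#'
#' H is computed on midranks with the standard tie correction
#' `1 - sum(t^3 - t) / (N^3 - N)`; the p-value is chi-squared with k-1
#' degrees of freedom. When every observation is identical H is defined as 0
#' with p = 1. If the omnibus test is significant at `alpha`, two-sided
#' pairwise Wilcoxon rank-sum tests are run between all group pairs (exact
#' enumeration when both groups have at most `exact_max_n` observations and
#' there are no ties; otherwise a normal approximation with tie-corrected
#' variance and continuity correction), with multiplicity adjustment.
#'
#' @param values numeric observations.
#' @param groups group label per observation (>= 2 groups).
#' @param alpha level gating the post-hoc tests.
#' @param adjust p-adjustment method for the pairwise tests (see
#'   [stats::p.adjust()]).
#' @param exact_max_n largest group size for exact rank-sum enumeration.
#' @param posthoc force (`TRUE`) or suppress (`FALSE`) the pairwise tests;
#'   `NULL` gates on `alpha`.
#' @return list of class `rank_test_result`: `statistic` (tie-corrected H),
#'   `df`, `p_value`, and `pairwise` (data.frame group1, group2, statistic,
#'   p_raw, p_adjusted, exact) or `NULL`.
#' @export
kruskal_wallis <- function(values, groups, alpha = 0.05, adjust = "holm",
                           exact_max_n = 12, posthoc = NULL) {
  groups <- factor(as.character(groups))
  if (nlevels(groups) < 2L) md_error("magdiet_design_error", "need >= 2 groups")
  if (any(tabulate(groups) < 1L)) {
    md_error("magdiet_design_error", "empty group")
  }
  n <- length(values)
  r <- rank(values)  # midranks
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction == 0) {  # all observations identical
    h <- 0; p <- 1
  } else {
    rg <- tapply(r, groups, sum)
    ng <- tabulate(groups)
    h <- (12 / (n * (n + 1))) * sum(rg^2 / ng) - 3 * (n + 1)
    h <- h / correction
    p <- pchisq(h, df = nlevels(groups) - 1L, lower.tail = FALSE)
  }
  pairwise <- NULL
  run_posthoc <- if (is.null(posthoc)) p <= alpha else posthoc
  if (run_posthoc) {
    pairs <- combn(levels(groups), 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(i) {
      g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
      w <- wilcoxon_rank_sum(values[groups == g1], values[groups == g2],
                             exact_max_n = exact_max_n)
      data.frame(group1 = g1, group2 = g2, statistic = w$statistic,
                 p_raw = w$p_value, exact = w$exact, stringsAsFactors = FALSE)
    })
    pairwise <- do.call(rbind, rows)
    pairwise$p_adjusted <- stats::p.adjust(pairwise$p_raw, method = adjust)
  }
  structure(list(statistic = h, df = nlevels(groups) - 1L, p_value = p,
                 pairwise = pairwise),
            class = "rank_test_result")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Mann-Whitney U statistic on midranks. Exact null enumeration (via the
#' Wilcoxon distribution) when both samples have at most `exact_max_n`
#' observations and there are no ties; otherwise a normal approximation with
#' tie-corrected variance and a 0.5 continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_max_n exact-computation size limit.
#' @return list with `statistic` (U for `x`), `p_value`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 12) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !has_ties && n1 <= exact_max_n && n2 <= exact_max_n
  if (use_exact) {
    p <- 2 * min(stats::pwilcox(u, n1, n2),
                 stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE))
    p <- min(p, 1)
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    ties <- table(c(x, y))
    sigma2 <- (n1 * n2 / 12) * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    if (sigma2 == 0) return(list(statistic = u, p_value = 1, exact = FALSE))
    cc <- sign(u - mu) * 0.5
    z <- (u - mu - cc) / sqrt(sigma2)
    p <- min(2 * stats::pnorm(-abs(z)), 1)
  }
  list(statistic = u, p_value = p, exact = use_exact)
}

# ---- full report ------------------------------------------------------------

#' Run the full diet-comparison analysis
#'
#' One call over a substrate profile table: scaled PCA, PERMANOVA and
#' dispersion test on the scaled feature matrix, a Kruskal-Wallis test with
#' post-hoc pairwise rank-sum tests per substrate, and all pairwise fold
#' changes of group means. All seeds and settings are echoed into the report
#' for reproducibility.
#'
#' @param profiles a `substrate_profiles` data.frame (or any data.frame with
#'   `mag_id` plus numeric feature columns).
#' @param design diet labels (named vector or `mag_id`/`diet` data.frame).
#' @param distance dissimilarity for the permutation tests.
#' @param n_permutations permutations for PERMANOVA and dispersion.
#' @param seed master seed; sub-seeds are derived from it.
#' @param adjust,alpha post-hoc adjustment method and omnibus level.
#' @param binary_columns feature columns excluded from the per-substrate rank
#'   tests and fold changes (capability flags, not copy counts).
#' @return list of class `diet_stats_report`.
#' @export
run_diet_analysis <- function(profiles, design, distance = "euclidean",
                              n_permutations = 999, seed = 1,
                              adjust = "holm", alpha = 0.05,
                              binary_columns = "fatty_acid") {
  labels <- as_diet_labels(design)
  missing <- setdiff(profiles$mag_id, names(labels))
  if (length(missing)) {
    md_error("magdiet_labeling_error", "unlabeled MAG(s): %s",
             paste(missing, collapse = ", "))
  }
  groups <- labels[profiles$mag_id]
  feat_cols <- setdiff(names(profiles)[vapply(profiles, is.numeric, TRUE)],
                       "mag_id")
  x <- as.matrix(profiles[, feat_cols, drop = FALSE])
  rownames(x) <- profiles$mag_id
  pca <- scaled_pca(x)
  xs <- scale(x[, setdiff(colnames(x), pca$dropped), drop = FALSE])
  perm <- permanova(xs, groups, distance = distance,
                    n_permutations = n_permutations, seed = seed,
                    exact = FALSE)
  disp <- dispersion_test(xs, groups, distance = distance,
                          n_permutations = n_permutations, seed = seed + 1L)
  test_cols <- setdiff(feat_cols, binary_columns)
  rank_tests <- lapply(test_cols, function(col) {
    kruskal_wallis(profiles[[col]], groups, alpha = alpha, adjust = adjust)
  })
  names(rank_tests) <- test_cols
  diets <- unique(unname(groups))
  fc <- do.call(rbind, lapply(test_cols, function(col) {
    do.call(rbind, lapply(utils::combn(diets, 2L, simplify = FALSE), function(pr) {
      den_mean <- mean(profiles[[col]][groups == pr[2L]])
      value <- if (den_mean == 0) NA_real_ else
        fold_change(profiles, labels, col, pr[1L], pr[2L])
      data.frame(substrate = col, numerator = pr[1L], denominator = pr[2L],
                 fold_change = value, stringsAsFactors = FALSE)
    }))
  }))
  structure(list(
    config = list(distance = distance, n_permutations = n_permutations,
                  seed = seed, adjust = adjust, alpha = alpha,
                  features = feat_cols, binary_columns = binary_columns),
    n = nrow(profiles),
    group_sizes = as.list(table(groups)),
    pca = list(variance_explained = pca$variance_explained,
               loadings = pca$loadings, dropped = pca$dropped),
    permanova = unclass(perm)[c("pseudo_F", "R2", "p_value",
                                "n_permutations", "seed")],
    dispersion = list(F = disp$F, p_value = disp$p_value,
                      group_means = as.list(disp$group_means),
                      n_permutations = disp$n_permutations, seed = disp$seed),
    rank_tests = lapply(rank_tests, function(rt) {
      list(statistic = rt$statistic, df = rt$df, p_value = rt$p_value,
           pairwise = rt$pairwise)
    }),
    fold_changes = fc
  ), class = "diet_stats_report")
}

#' Serialize / restore a diet statistics report
#'
#' @param report a `diet_stats_report`.
#' @param path JSON file path.
#' @export
write_diet_report <- function(report, path) {
  obj <- rapply(unclass(report), function(x) {
    if (is.matrix(x)) {
      list(values = as.vector(x), dim = dim(x), dimnames = dimnames(x))
    } else x
  }, classes = "matrix", how = "replace")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_diet_report
#' @export
read_diet_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$pca$loadings$values)) {
    l <- obj$pca$loadings
    dn <- lapply(seq_len(2L), function(i)
      if (is.matrix(l$dimnames)) l$dimnames[i, ] else l$dimnames[[i]])
    obj$pca$loadings <- matrix(l$values, nrow = l$dim[1L], dimnames = dn)
  }
  structure(obj, class = "diet_stats_report")
}

#' @export
print.diet_stats_report <- function(x, ...) {
  cat(sprintf("Diet statistics report: n = %d MAGs, groups: %s\n", x$n,
              paste(sprintf("%s (%d)", names(x$group_sizes),
                            unlist(x$group_sizes)), collapse = ", ")))
  cat(sprintf("  PCA: first two components explain %.1f%% of variance\n",
              100 * sum(x$pca$variance_explained[1:min(2, length(x$pca$variance_explained))])))
  cat(sprintf("  PERMANOVA: F = %.4f, R2 = %.3f, P = %.4g\n",
              x$permanova$pseudo_F, x$permanova$R2, x$permanova$p_value))
  cat(sprintf("  Dispersion: F = %.4f, P = %.4g\n",
              x$dispersion$F, x$dispersion$p_value))
  for (nm in names(x$rank_tests)) {
    rt <- x$rank_tests[[nm]]
    cat(sprintf("  Kruskal-Wallis [%s]: H = %.4f, P = %.4g\n",
                nm, rt$statistic, rt$p_value))
  }
  invisible(x)
}
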