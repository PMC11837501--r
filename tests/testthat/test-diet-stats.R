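test_that("scaled PCA satisfies trace conservation and reconstruction", {
  set.seed(21)
  x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  p <- scaled_pca(x)
  expect_equal(sum(p$variance_explained), 1, tolerance = 1e-9)
  expect_equal(unname(colMeans(p$scores)), rep(0, ncol(p$scores)),
               tolerance = 1e-12)
  # projecting back with all components reproduces the scaled matrix
  xs <- scale(x)
  expect_equal(p$scores %*% t(p$loadings), xs, ignore_attr = TRUE,
               tolerance = 1e-9)
  # components are orthogonal
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("scaled PCA agrees with prcomp up to component sign", {
  set.seed(22)
  x <- matrix(rnorm(60), 12, 5)
  p <- scaled_pca(x)
  ref <- prcomp(x, center = TRUE, scale. = TRUE)
  expect_equal(p$sdev, ref$sdev, tolerance = 1e-9)
  expect_equal(abs(p$loadings), abs(ref$rotation), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(p$variance_explained, ref$sdev^2 / sum(ref$sdev^2),
               tolerance = 1e-9)
})

test_that("single varying column loads everything on PC1", {
  x <- cbind(a = c(1, 2, 3, 4), b = rep(5, 4), c = rep(2, 4))
  expect_warning(p <- scaled_pca(x), "zero-variance")
  expect_equal(p$variance_explained[1L], 1)
  expect_setequal(p$dropped, c("b", "c"))
  expect_error(scaled_pca(x[1, , drop = FALSE]),
               class = "magdiet_domain_error")
})

test_that("PERMANOVA pseudo-F and R2 match vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(31)
  for (rep in 1:3) {
    x <- matrix(rnorm(60), 15, 4)
    g <- rep(c("a", "b", "c"), each = 5)
    mine <- permanova(x, g, n_permutations = 99, seed = 1, exact = FALSE)
    ref <- vegan::adonis2(dist(x) ~ g, permutations = 99)
    expect_equal(mine$pseudo_F, ref$F[1L], tolerance = 1e-10)
    expect_equal(mine$R2, ref$R2[1L], tolerance = 1e-10)
    expect_equal(mine$ss_total, ref$SumOfSqs[nrow(ref)], tolerance = 1e-10)
  }
  # Bray-Curtis route
  xb <- matrix(rexp(40), 10, 4)
  gb <- rep(c("a", "b"), each = 5)
  mineb <- permanova(xb, gb, distance = "bray", n_permutations = 99,
                     seed = 1, exact = FALSE)
  refb <- vegan::adonis2(vegan::vegdist(xb, "bray") ~ gb, permutations = 99)
  expect_equal(mineb$pseudo_F, refb$F[1L], tolerance = 1e-10)
})

test_that("PERMANOVA permutation p equals exact enumeration on 3+3 designs", {
  set.seed(32)
  for (rep in 1:3) {
    x <- matrix(rnorm(24), 6, 4)
    g <- rep(c("a", "b"), each = 3)
    mine <- permanova(x, g, exact = TRUE)
    expect_equal(mine$n_permutations, 20L)  # 6!/(3!3!) distinct assignments
    # independent combn oracle over which rows form group "a"
    d2 <- as.matrix(dist(x))^2
    fstat <- function(gg) {
      sst <- sum(d2) / (2 * 6)
      ssw <- 0
      for (lev in unique(gg)) {
        idx <- which(gg == lev)
        ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
      }
      ((sst - ssw) / 1) / (ssw / 4)
    }
    fs <- apply(combn(6, 3), 2L, function(idx) {
      gg <- rep("b", 6); gg[idx] <- "a"; fstat(gg)
    })
    p_exact <- mean(fs >= fstat(g) - 1e-12)
    expect_equal(mine$p_value, p_exact)
    expect_gte(mine$p_value, 1 / 20)
  }
})

test_that("pseudo-F is invariant to uniform distance scaling", {
  set.seed(33)
  x <- matrix(rnorm(48), 12, 4)
  g <- rep(c("a", "b", "c"), each = 4)
  f1 <- permanova(x, g, n_permutations = 99, seed = 5, exact = FALSE)
  f2 <- permanova(3 * x, g, n_permutations = 99, seed = 5, exact = FALSE)
  expect_equal(f1$pseudo_F, f2$pseudo_F, tolerance = 1e-10)
  expect_equal(f1$p_value, f2$p_value)  # same seed, same permutations
  # design and degeneracy guards
  expect_error(permanova(x, c("a", rep("b", 11)), exact = FALSE),
               class = "magdiet_design_error")
  expect_error(permanova(matrix(1, 6, 2), rep(c("a", "b"), each = 3)),
               class = "magdiet_degenerate_error")
})

test_that("seeded permutation p-values are reproducible and lower-bounded", {
  set.seed(34)
  x <- matrix(rnorm(40), 10, 4)
  g <- rep(c("a", "b"), each = 5)
  p1 <- permanova(x, g, n_permutations = 199, seed = 7, exact = FALSE)
  p2 <- permanova(x, g, n_permutations = 199, seed = 7, exact = FALSE)
  expect_identical(p1$p_value, p2$p_value)
  expect_gte(p1$p_value, 1 / 200)
})

test_that("dispersion distances on Euclidean input equal direct computation", {
  set.seed(41)
  x <- matrix(rnorm(60), 15, 4)
  g <- rep(c("a", "b", "c"), each = 5)
  disp <- dispersion_test(x, g, n_permutations = 99, seed = 1)
  direct <- numeric(15)
  for (lev in unique(g)) {
    idx <- which(g == lev)
    ctr <- colMeans(x[idx, , drop = FALSE])
    direct[idx] <- sqrt(rowSums(sweep(x[idx, , drop = FALSE], 2, ctr)^2))
  }
  expect_equal(unname(disp$distances), direct, tolerance = 1e-9)
})

test_that("dispersion distances match vegan::betadisper centroids", {
  skip_if_not_installed("vegan")
  set.seed(42)
  x <- matrix(rexp(48), 12, 4)
  g <- rep(c("a", "b"), each = 6)
  d <- dissimilarity_matrix(x, "bray")
  disp <- dispersion_test(d, g, n_permutations = 99, seed = 1,
                          is_distance = TRUE)
  ref <- vegan::betadisper(as.dist(d), g, type = "centroid")
  expect_equal(unname(disp$distances), unname(ref$distances),
               tolerance = 1e-8)
})

test_that("dispersion test separates unequal spreads and nulls equal ones", {
  set.seed(43)
  base <- matrix(rnorm(40), 10, 4)
  # second group is a translated copy: spreads identical, F exactly 0
  x_null <- rbind(base, sweep(base, 2, c(5, 5, 5, 5), "+"))
  g <- rep(c("a", "b"), each = 10)
  d0 <- dispersion_test(x_null, g, n_permutations = 99, seed = 2)
  expect_equal(d0$F, 0, tolerance = 1e-18)
  expect_gte(d0$p_value, 0.5)
  # scaling one group inflates its centroid distances and F
  x_alt <- rbind(base, sweep(base, 2, colMeans(base)) * 10)
  d1 <- dispersion_test(x_alt, g, n_permutations = 99, seed = 2)
  expect_gt(d1$group_means[["b"]], d1$group_means[["a"]])
  expect_gt(d1$F, d0$F)
})

test_that("Kruskal-Wallis H matches the tie-corrected reference to 1e-12", {
  set.seed(51)
  for (rep in 1:5) {
    vals <- sample(round(rnorm(30), 1))  # rounded: guaranteed ties
    g <- sample(rep(c("a", "b", "c"), each = 10))
    mine <- kruskal_wallis(vals, g, posthoc = FALSE)
    ref <- kruskal.test(vals, factor(g))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  allsame <- kruskal_wallis(rep(3.3, 9), rep(c("a", "b", "c"), 3))
  expect_equal(allsame$statistic, 0)
  expect_equal(allsame$p_value, 1)
})

test_that("rank-sum tests match wilcox.test in exact and approximate modes", {
  # fully separated 3 vs 3: 2 of 20 equally likely rankings are this extreme
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_true(w$exact)
  expect_equal(w$p_value, 0.1)
  set.seed(52)
  x <- rnorm(8); y <- rnorm(9) + 0.5
  mine <- wilcoxon_rank_sum(x, y)
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  # ties force the normal approximation with continuity correction
  xt <- c(1, 2, 2, 3, 5, 7, 8, 9, 11, 12, 13, 14, 15)
  yt <- c(2, 3, 3, 4, 6, 8, 9, 10, 12, 13, 14, 15, 16)
  minet <- wilcoxon_rank_sum(xt, yt)
  expect_false(minet$exact)
  reft <- suppressWarnings(wilcox.test(xt, yt, exact = FALSE, correct = TRUE))
  expect_equal(minet$p_value, reft$p.value, tolerance = 1e-12)
})

test_that("post-hoc tests run when the omnibus rejects, with adjusted >= raw p", {
  set.seed(53)
  vals <- c(rnorm(10), rnorm(10) + 3, rnorm(10) + 6)
  g <- rep(c("a", "b", "c"), each = 10)
  res <- kruskal_wallis(vals, g)
  expect_false(is.null(res$pairwise))
  expect_equal(nrow(res$pairwise), 3L)
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_raw - 1e-15))
  null_res <- kruskal_wallis(rnorm(30), g)
  if (null_res$p_value > 0.05) expect_null(null_res$pairwise)
})

test_that("the full diet report is seeded, reproducible and serializable", {
  set.seed(61)
  sim <- simulate_community(simulation_config(
    mags_per_group = c(6L, 6L, 6L), seed = 99L))
  prof <- build_profile_matrix(sim$annotations, sim$mags,
                               read_substrate_config())
  rep1 <- run_diet_analysis(prof, sim$design, n_permutations = 99, seed = 4)
  rep2 <- run_diet_analysis(prof, sim$design, n_permutations = 99, seed = 4)
  expect_equal(rep1$permanova$p_value, rep2$permanova$p_value)
  expect_equal(rep1$dispersion$p_value, rep2$dispersion$p_value)
  expect_equal(rep1$config$seed, 4)
  expect_gte(rep1$permanova$p_value, 1 / 100)

  path <- withr::local_tempfile(fileext = ".json")
  write_diet_report(rep1, path)
  back <- read_diet_report(path)
  expect_equal(back$permanova$pseudo_F, rep1$permanova$pseudo_F)
  expect_equal(back$permanova$p_value, rep1$permanova$p_value)
  expect_equal(back$dispersion$F, rep1$dispersion$F)
  expect_equal(back$pca$variance_explained, rep1$pca$variance_explained)
  expect_equal(back$pca$loadings, rep1$pca$loadings, tolerance = 1e-12)
  for (nm in names(rep1$rank_tests)) {
    expect_equal(back$rank_tests[[nm]]$statistic,
                 rep1$rank_tests[[nm]]$statistic)
  }
  expect_error(run_diet_analysis(prof, sim$design[-1, ]),
               class = "magdiet_labeling_error")
})
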