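chain4 <- "
pathways:
  - pathway_id: chain4
    category: degradation_chain
    substrate_class: cellulose
    steps:
      - {step_id: s1, alternatives: [CAZY:F1, CAZY:F2]}
      - {step_id: s2, alternatives: [CAZY:F3]}
      - {step_id: s3, alternatives: [CAZY:F4, CAZY:F5, CAZY:F6]}
      - {step_id: s4, alternatives: [CAZY:F7]}
"

test_that("vacuous annotations give absent calls with fraction zero", {
  defs <- read_pathway_defs()
  zero <- stats::setNames(numeric(0), character(0))
  for (p in c("cellulose_degradation", "glycolysis", "pyruvate_oxidation",
              "lactate_fermentation", "hemicellulose_degradation")) {
    call <- evaluate_pathway(zero, defs[[p]], defs)
    expect_equal(call$status, "absent")
    expect_equal(call$fraction, 0)
  }
})

test_that("the enzyme-fraction threshold is a closed inequality", {
  steps <- paste(sprintf(
    "      - {step_id: s%d, alternatives: [KO:K%05d]}", 1:10, 1:10),
    collapse = "\n")
  defs <- make_defs(sprintf(
    "pathways:\n  - pathway_id: frac10\n    category: enzyme_fraction\n    threshold: 0.8\n    steps:\n%s", steps))
  fams <- sprintf("KO:K%05d", 1:10)
  counts8 <- stats::setNames(rep(1, 8), fams[1:8])
  call <- evaluate_pathway(counts8, defs[["frac10"]])
  expect_equal(call$status, "complete")   # exactly at 80% qualifies
  expect_equal(call$fraction, 0.8)
  counts7 <- stats::setNames(rep(1, 7), fams[1:7])
  expect_equal(evaluate_pathway(counts7, defs[["frac10"]])$status, "partial")
})

test_that("any-of pathways are complete when any member is complete", {
  defs <- read_pathway_defs()
  xylan_fams <- unlist(lapply(defs[["xylan_degradation"]]$steps,
                              function(s) s$alternatives[1L]))
  counts <- stats::setNames(rep(1, length(xylan_fams)), xylan_fams)
  call <- evaluate_pathway(counts, defs[["hemicellulose_degradation"]], defs)
  expect_equal(call$status, "complete")
  expect_equal(call$fraction, 1)
  # fraction is the max over members
  one_mannan <- stats::setNames(1, defs[["mannan_degradation"]]$steps[[1L]]$alternatives[1L])
  call2 <- evaluate_pathway(one_mannan, defs[["hemicellulose_degradation"]], defs)
  expect_equal(call2$status, "partial")
  expect_equal(call2$fraction, 0.5)
})

test_that("evaluation agrees with exhaustive presence-pattern enumeration", {
  defs <- make_defs(chain4)
  fams <- sprintf("CAZY:F%d", 1:7)
  for (bits in 0:(2^7 - 1)) {
    present <- fams[bitwAnd(bits, 2^(0:6)) > 0]
    counts <- stats::setNames(rep(1, length(present)), present)
    got <- evaluate_pathway(counts, defs[["chain4"]])
    want <- oracle_eval(present, defs[["chain4"]], defs)
    expect_identical(got$status, want$status)
    expect_equal(got$fraction, want$fraction)
  }
})

test_that("adding gene copies never demotes a call (status lattice)", {
  defs <- read_pathway_defs()
  rank <- c(absent = 0, partial = 1, complete = 2)
  all_fams <- unique(unlist(lapply(defs, function(d)
    unlist(lapply(d$steps, `[[`, "alternatives")))))
  set.seed(11)
  for (rep in 1:40) {
    base_fams <- sample(all_fams, 12)
    base <- stats::setNames(rpois(12, 1), base_fams)
    extra <- base + stats::setNames(rpois(12, 2), base_fams)
    more_fams <- sample(all_fams, 4)
    extra2 <- c(extra, stats::setNames(rep(1, 4), more_fams))
    for (p in c("cellulose_degradation", "hemicellulose_degradation",
                "tca_cycle", "beta_oxidation")) {
      a <- evaluate_pathway(base, defs[[p]], defs)
      b <- evaluate_pathway(extra2, defs[[p]], defs)
      expect_gte(b$fraction, a$fraction)
      expect_gte(rank[[b$status]], rank[[a$status]])
    }
  }
})

test_that("degrader classification separates complete and partial degraders", {
  defs <- make_defs(chain4)
  mat <- as_annotation_matrix(ann_df(
    c("FULL", "FULL", "FULL", "FULL", "PART", "NONE"),
    "CAZY", c("F1", "F3", "F5", "F7", "F3", "X99")))
  calls <- classify_degraders(mat, defs)
  get <- function(m) calls$status[calls$mag_id == m]
  expect_equal(get("FULL"), "complete")
  expect_equal(get("PART"), "partial")   # one step only: partial degrader
  expect_equal(get("NONE"), "absent")
  expect_equal(unique(calls$substrate_class), "cellulose")
})

test_that("a community lacking chitin initial-step families has no chitin degraders", {
  defs <- read_pathway_defs()
  # families only from cellulose steps: chitin chains cannot start
  mat <- as_annotation_matrix(ann_df(
    rep(c("M1", "M2"), each = 3), "CAZY",
    c("GH5", "GH6", "GH1", "GH9", "GH7", "GH3")))
  calls <- classify_degraders(mat, defs)
  chitin <- calls[calls$substrate_class == "chitin", ]
  expect_equal(sum(chitin$status == "complete"), 0L)
})

test_that("beta-oxidation is a strict all-four-steps binary", {
  defs <- read_pathway_defs()
  beta <- defs[["beta_oxidation"]]
  four <- vapply(beta$steps, function(s) s$alternatives[1L], "")
  expect_equal(beta_oxidation_flag(stats::setNames(rep(1, 4), four), beta), 1L)
  expect_equal(beta_oxidation_flag(stats::setNames(rep(1, 3), four[1:3]), beta), 0L)
  expect_equal(beta_oxidation_flag(stats::setNames(numeric(0), character(0)), beta), 0L)
  expect_error(beta_oxidation_flag(numeric(0), defs[["glycolysis"]]),
               class = "magdiet_definition_error")
})

test_that("substrate listing rules use strict count thresholds", {
  defs <- read_pathway_defs()
  cfg <- read_substrate_config()
  amylase6 <- stats::setNames(c(4, 2), c("CAZY:GH13", "CAZY:GH57"))
  s <- summarize_functions("M1", amylase6, defs, cfg)
  expect_equal(s$substrates, "starch")   # 6 amylase genes: listed
  amylase5 <- stats::setNames(5, "CAZY:GH13")
  s5 <- summarize_functions("M2", amylase5, defs, cfg)
  expect_false("starch" %in% s5$substrates)  # exactly 5: not listed

  # 11 exopeptidases + complete-enough TCA (>= 80% of steps)
  tca_fams <- vapply(defs[["tca_cycle"]]$steps, function(s) s$alternatives[1L], "")
  counts <- c(stats::setNames(c(6, 5), c("MEROPS:M01", "MEROPS:S09")),
              stats::setNames(rep(1, 7), tca_fams[1:7]))
  s2 <- summarize_functions("M3", counts, defs, cfg)
  expect_true("protein" %in% s2$substrates)
  expect_true("protein degradation" %in% s2$benefits)
  tca_row <- s2$energy_pathways[s2$energy_pathways$pathway == "tca_cycle", ]
  expect_false(tca_row$partial)  # 7/8 = 0.875 >= 0.8: listed without (p)

  # beta-glucosidase only: simple saccharides
  bg <- stats::setNames(1, "CAZY:GH1")
  expect_equal(summarize_functions("M4", bg, defs, cfg)$substrates,
               "simple_saccharides")
  expect_equal(summarize_functions("M5", stats::setNames(1, "KO:K00016"),
                                   defs, cfg)$substrates, character(0))
})

test_that("vitamins are listed iff the biosynthesis call is complete", {
  defs <- read_pathway_defs()
  cfg <- read_substrate_config()
  b1 <- vapply(defs[["vitamin_b1"]]$steps, function(s) s$alternatives[1L], "")
  s <- summarize_functions("M1", stats::setNames(rep(1, 5), b1), defs, cfg)
  expect_equal(s$vitamins, "B1")
  expect_true("vitamin production" %in% s$benefits)
  s2 <- summarize_functions("M2", stats::setNames(rep(1, 3), b1[1:3]), defs, cfg)
  expect_equal(s2$vitamins, character(0))
})

test_that("per-diet counts partition the group sizes and match a loop tally", {
  set.seed(5)
  mags <- sprintf("M%02d", 1:43)
  diets <- stats::setNames(rep(c("pisc", "herb", "invert"), c(18, 18, 7)), mags)
  calls <- expand.grid(mag_id = mags, pathway_id = c("p1", "p2", "p3"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  calls$status <- sample(c("complete", "partial", "absent"), nrow(calls),
                         replace = TRUE)
  counts <- count_by_pathway(calls, diets)
  expect_true(all(counts$n_complete + counts$n_partial + counts$n_absent ==
                    counts$n_total))
  expect_setequal(unique(counts$n_total), c(18L, 7L))
  # brute-force tally
  for (i in sample(nrow(counts), min(10, nrow(counts)))) {
    row <- counts[i, ]
    manual <- sum(vapply(seq_len(nrow(calls)), function(j) {
      calls$pathway_id[j] == row$pathway_id &&
        diets[[calls$mag_id[j]]] == row$diet &&
        calls$status[j] == "complete"
    }, TRUE))
    expect_equal(row$n_complete, manual)
  }
  expect_error(count_by_pathway(calls, diets[-1]),
               class = "magdiet_labeling_error")
})
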