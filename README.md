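# magdiet

Genome-resolved functional profiling of gut metagenome-assembled genomes
(MAGs) and diet-enrichment analysis.

## The problem

Fish gut microbiomes break dietary polymers down and synthesize vitamins
for their hosts. Given draft genomes recovered from guts under controlled
diets — say a piscivorous, an herbivorous and an invertivorous treatment —
the genome-resolved questions are: which substrates can each organism
degrade (completely, or only partially), which energy-harvesting and
vitamin pathways does it carry, and do those gene complements differ
between diets? `magdiet` implements this analysis as a tested pipeline
over plain annotation tables; all sequence-level processing (assembly,
binning, gene calling, HMM searches) happens upstream and is out of scope.

The pieces, each a module of the package:

* **Annotation model** — readers/writers for MAG metadata (completeness,
  contamination, coverage, ANI-or-RED), long-format gene-family annotations
  (CAZy / KEGG Orthology / MEROPS / HydDB namespaces, case-insensitive
  identity, counts aggregated by summation), and declarative YAML pathway
  definitions.
* **Pathway engine** — completeness scoring per rule category.
  A degradation chain with steps $s_1 \dots s_m$ (each an OR over
  alternative families) is *complete* iff every step has a family with
  copy number $\ge 1$, *partial* iff at least one but not all steps are
  satisfied. Enzyme-fraction pathways are complete iff the satisfied
  fraction $f \ge t$ (default $t = 0.8$, closed inequality). "Any-of"
  pathways take the best member (hemicellulose = xylan ∨ mannan ∨
  xyloglucan). Substrate listings use strict count rules (amylase total
  > 5 for starch, exopeptidase total > 10 for protein, all four
  beta-oxidation enzymes for fatty acids).
* **Substrate matrix** — per-MAG copy totals per substrate class,
  normalized to genome completeness, `normalized = raw × 100 /
  completeness`, plus the beta-oxidation binary; per-diet fold changes as
  ratios of group means.
* **Community profile** — marker-gene (rps3) coverage shares as relative
  abundances, and MAG QC summaries (means, class counts, known-species
  tally at ANI > 95).
* **Diet statistics** — implemented from first principles: scaled PCA;
  one-way PERMANOVA with pseudo-$F = \frac{SS_B/(k-1)}{SS_W/(n-k)}$ from
  the pairwise distance matrix and a seeded permutation null (exact
  enumeration on small designs); betadisper-style homogeneity of
  multivariate dispersion via principal coordinates; tie-corrected
  Kruskal–Wallis with post-hoc exact/approximate Wilcoxon rank-sum tests
  and Holm adjustment.
* **Synthetic data** — a seeded community generator (diet-structured
  enrichment, shifted-Poisson copy counts, ground-truth degrader labels
  computed by an independent tally) so every stage is testable with no
  external data.

A worked example of a bundled three-treatment reef-fish study (18 + 18 + 7
quality-passing MAGs) ships in `inst/extdata/` together with default
pathway definitions and substrate family lists.

## Worked example

```r
library(magdiet)

# QC summary of the bundled study table, per diet treatment
mags <- read_mag_table(reef_fish_mag_file())
diet <- ifelse(grepl("^H1N1", mags$mag_id), "piscivorous",
        ifelse(grepl("^T4LTN", mags$mag_id), "herbivorous", "invertivorous"))
qc_summary_by(mags, setNames(diet, mags$mag_id))[["piscivorous"]]
#> QC summary [piscivorous]: 18 MAGs
#>   mean completeness  91.44%
#>   mean contamination 4.47%
#>   classes (4): Alphaproteobacteria=8, Bacteroidia=3, Gammaproteobacteria=6, Gracilibacteria=1
#>   known species (ANI rule): 9/18 (50.0%)

# simulate a diet-structured community, profile it, and test diet effects
sim    <- simulate_community(simulation_config(seed = 1))
prof   <- build_profile_matrix(sim$annotations, sim$mags,
                               read_substrate_config())
report <- run_diet_analysis(prof, sim$design, seed = 1)
report
#> Diet statistics report: n = 43 MAGs, groups: herbivorous (18), invertivorous (7), piscivorous (18)
#>   PCA: first two components explain 72.0% of variance
#>   PERMANOVA: F = 15.0722, R2 = 0.430, P = 0.001
#>   Dispersion: F = 3.8724, P = 0.037
#>   Kruskal-Wallis [cellulose]: H = 19.1869, P = 6.818e-05
#>   Kruskal-Wallis [hemicellulose]: H = 28.4434, P = 6.662e-07
#>   Kruskal-Wallis [starch]: H = 11.9652, P = 0.002522
#>   Kruskal-Wallis [chitin]: H = 19.9892, P = 4.565e-05
#>   Kruskal-Wallis [protein]: H = 28.5064, P = 6.455e-07

fold_change(prof, sim$design, "chitin", "herbivorous", "piscivorous")
#> [1] 1.853127
```

The QC block says the 18 piscivorous-treatment MAGs average 91.44%
completeness and 4.47% contamination across four bacterial classes, with
9 of 18 within a known species at ANI > 95. In the simulated community the
diet treatments separate strongly (PERMANOVA P = 0.001, the floor for 999
permutations), group spreads differ (dispersion P = 0.037), and every
substrate's normalized copy numbers differ between diets (Kruskal–Wallis),
with herbivore chitin-gene copies about 1.9-fold the piscivorous mean —
the enrichment the generator planted.

The numbered scripts under `analysis/` run the same pipeline end to end
(simulate → classify → profile → statistics → QC), writing tables under
`results/`.

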