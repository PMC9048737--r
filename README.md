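# dysbiome

Gut-microbiota dysbiosis profiling and case-control discrimination for
16S amplicon cohorts, built around the fracture-related-infection (FRI)
study design: infected patients (FRI), fracture-healed controls (FH) and
healthy controls (HC).

Preoperative diagnosis of FRI is difficult when there is no sinus tract or
visible pus. The question this package operationalises is whether the gut
microbiome carries enough signal to act as an auxiliary diagnostic: does
the infected group show a characteristic community shift, and how well
does a scalar summary of that shift separate cases from controls?

## What it computes

The central estimator is a two-sided genus signature and the per-sample
**dysbiosis index**

```
DI = (Σ RelativeAbundance over case-enriched genera + ε) /
     (Σ RelativeAbundance over control-enriched genera + ε),   ε = 1e-6
```

Around it, the package provides:

* **Data model and I/O** — taxa × samples count tables (TSV), sample
  metadata, GreenGenes-style taxonomy lineages, rooted Newick trees
  (via `ape`); strict id cross-validation; collapsing to any taxonomic
  rank; relative abundances; the abundance/prevalence filter (keep a
  genus iff it reaches ≥ 0.01% relative abundance in ≥ 20% of samples).
* **Diversity** — Shannon (bits), Faith's PD (whole-tree), unweighted and
  (normalised) weighted UniFrac, PCoA with full eigenvalue reporting, and
  a seeded one-way PERMANOVA.
* **Biomarker discovery** — a Kruskal–Wallis screen with LEfSe-style LDA
  effect sizes (30 seeded bootstraps, ×10⁶ rescaling, log10 scores,
  threshold 2.0), and covariate-adjusted negative-binomial GLMs
  (counts ~ group + age + sex with a log-depth offset); signatures built
  from either route or supplied manually (a 14-genus FRI signature ships
  in `inst/extdata/signature_fri14.tsv`).
* **Evaluation** — Wilcoxon/ANOVA/Kruskal–Wallis/chi-square group tests,
  ROC/AUC (tie-aware, equal to Mann–Whitney concordance), leave-one-out
  cross-validated logistic AUC on the signature composition, serum-marker
  odds ratios, and Spearman marker–taxon correlation grids with BH
  adjustment.
* **Synthetic cohorts** — a seeded Dirichlet-multinomial generator with
  planted enrichments/depletions, a richness deficit in the case group,
  and copula-linked serum markers, so every stage is testable with known
  ground truth and no sequencing download.

## Worked example

Fit the estimator on a simulated study-scale cohort (20/18/12 samples,
120 genera, 4 planted case-enriched and 10 planted control-enriched
genera):

```r
library(dysbiome)

cfg <- simulation_config(seed = 42)
sim <- simulate_counts(cfg)
fit <- fit_dysbiosis(sim$counts, sim$metadata, tree = sim$tree, seed = 42)
fit
#> Dysbiosis signature fit (lefse)
#>   case group: FRI; samples: 50
#>   signature: 5 case-enriched / 21 control-enriched genera
#>   AUC(DI) FRI_vs_FH: 1.000
#>   AUC(DI) FRI_vs_HC: 1.000

summary(fit)
#> Dysbiosis fit summary (lefse, case = FRI)
#> case-enriched: Actinomyces, Escherichia, genus_058, Streptococcus, Veillonella
#> control-enriched: Anaerostipes, Blautia, Coprococcus, Desulfovibrio, ...
#> median DI by group:
#>     FH    FRI     HC
#>  0.220 18.216  0.169
#> rank-test p-values:
#>  FRI_vs_FH  FRI_vs_HC   FH_vs_HC all_groups
#>   1.54e-07   3.29e-06   1.12e-01   1.35e-08
#> AUC of the index:
#> FRI_vs_FH FRI_vs_HC
#>         1         1

head(predict(fit, sim$counts), 4)
#>       FRI_01       FRI_02       FRI_03       FRI_04
#> 2.144066e+05 7.158720e+00 2.343681e+02 8.528419e+00
```

Reading the output: the discovered signature recovers all four planted
case-enriched genera (plus one compositional pick-up); the median
dysbiosis index is two orders of magnitude higher in the FRI-like group;
the Wilcoxon contrast FRI-vs-FH is strongly significant while FH-vs-HC —
where nothing was planted — is not; and the index separates cases from
both control groups perfectly (AUC 1) at these planted effect sizes.
`predict()` scores new samples with the fitted signature; DI values far
above 1 are case-like.

A full run with every artifact written to disk (alpha diversity, UniFrac
distance matrix, PCoA, PERMANOVA, LDA scores, signature, index, ROC
tables, odds ratios, correlations, plus a checksum manifest):

```r
res <- run_pipeline(simulation_config(seed = 1), "out_run", seed = 1)
```

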