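---
title: "Methods: dysbiosis profiling and case-control discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dysbiosis profiling and case-control discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysbiome)
```

## The problem

Fracture-related infection (FRI) is hard to diagnose preoperatively when no
sinus tract or purulent discharge is visible. A case-control design with
three groups — infected patients (FRI), fracture-healed controls (FH) and
healthy controls (HC) — asks whether the gut microbiome carries a signal
strong enough to act as an auxiliary diagnostic. `dysbiome` implements that
analysis end to end on a genus-level 16S count table: diversity profiling,
signature discovery, a scalar dysbiosis index, and ROC-based evaluation,
plus a synthetic-cohort generator so the whole pipeline is testable without
any sequencing data.

## The dysbiosis index

The core estimator is a two-sided genus signature and the per-sample ratio

$$\mathrm{DI} = \frac{\sum_{g \in \text{case-enriched}} \mathrm{rel}(g) + \varepsilon}
                     {\sum_{g \in \text{control-enriched}} \mathrm{rel}(g) + \varepsilon}$$

with a symmetric pseudocount $\varepsilon = 10^{-6}$ on both sides. The
ratio is undefined when the denominator genera carry no reads; the
symmetric pseudocount keeps DI finite, strictly positive, and preserves two
useful invariants: DI is scale-free in the sample's sequencing depth, and
swapping the two signature sides maps DI to 1/DI (exactly, once both
masses dominate the pseudocount). Rank tests on DI are computed on the raw
scale (ranks are scale-invariant); plots use log10(DI).

`fit_dysbiosis()` packages the estimator in the usual modelling idiom: it
returns a classed object with `print`, `summary`, `coef` (signature
membership as ±1), `predict` (DI for new samples), `fitted` and `plot`
methods. This shape was chosen deliberately — the signature plus index is
an estimator fit on a labelled cohort, and downstream use (scoring new
samples) is exactly `predict()`.

## Signature discovery

Two discovery routes are implemented, plus a manual route.

**LEfSe-style LDA effect size** (`lda_effect_size()`). Features are first
screened with a tie-corrected Kruskal–Wallis test at $\alpha = 0.05$ (no
multiple-testing correction inside the screen — the LEfSe convention).
Passing features are rescaled to relative abundance × 10^6 and scored over
30 seeded subsamples of 2/3 of each class. For three classes the
discriminant is one-vs-rest, and each feature is scored under the class in
which its mean is largest. Per bootstrap the feature effect is

$$\tfrac{1}{2}\bigl(\,|m_1^f - m_0^f| + |w_f \cdot (w^\top(m_1 - m_0))|\,\bigr)$$

where $w$ is the pooled-covariance discriminant direction, normalised to
unit L2 norm, computed with a small always-on ridge
($\lambda = \max(10^{-6}\,\overline{\mathrm{diag}(S_w)}, 10^{-8})$,
escalated tenfold when the solve still fails) so that singular
within-class scatter degrades gracefully rather than crashing. The score
is $\log_{10}(1 + \text{mean effect})$, signed toward the case group, with
the conventional passing threshold 2.0. The per-bootstrap effect formula
is pinned here and in the code; tests assert ranking, sign, monotonicity
and seeded determinism rather than score equality with any external tool,
since the published recipe leaves those internals open.

**Covariate-adjusted GLM** (`glm_differential()`). Per genus, a
negative-binomial GLM of counts on group + age + sex with a log
total-count offset; the reported Wald $z$ and two-sided $p$ are for the
FRI contrast (HC reference in the three-group model). Dispersion is
estimated by maximum likelihood; when that fails the dispersion falls back
to method-of-moments, floored at 0.01 and capped at 10^6 to keep the IRLS
numerically sane, and as a last resort the Poisson fit itself is used.
The negative-binomial family is the default because the data are
overdispersed counts and the analysis reports $\Pr(>|z|)$-style Wald
p-values; `poisson` and presence/absence `binomial` families are exposed
for sensitivity checks. The union of genera with $p < 0.05$ in any of the
three comparisons (FRI-vs-FH-vs-HC, FRI-vs-HC, FRI-vs-FH) forms the
glm-union signature, with each member assigned to the case side iff its
mean relative abundance is higher in FRI than in the pooled controls;
exact ties go, conservatively, to the control side with a warning.

**Manual.** The package ships a 14-genus FRI signature
(`inst/extdata/signature_fri14.tsv`; 4 case-enriched, 10
control-enriched). The published description of that signature does not
state the numerator/denominator partition explicitly, so the partition is
shipped as an editable config file inferred from the reported enrichment
directions, not hard-coded.

Before any discovery the table is filtered by abundance and prevalence:
keep a genus iff its relative abundance reaches at least 0.01% in at least
20% of samples, both boundaries inclusive. The removal phrasing this rule
derives from ("low relative abundance and prevalence, <0.01% in ≥20% of
samples") is ambiguous; the implementation fixes the keep-rule complement
as the testable convention.

## Diversity conventions

* **Shannon** uses log base 2 (bits); the base is an argument.
* **Faith's PD** is the "whole tree" reading: the union of root-to-leaf
  paths of observed taxa, so the root path is included and a single-taxon
  sample already has positive PD. An empty sample scores 0.
* **UniFrac** is computed from an edge-by-tip incidence matrix built once
  per tree. Unweighted: unique branch length over union branch length.
  Weighted: $\sum_b \ell_b\,|p_A(b)-p_B(b)|$, divided by
  $\sum_b \ell_b\,(p_A(b)+p_B(b))$ when normalised — the default, so the
  distance is bounded in [0, 1]; the raw variant is available.
* **PCoA** is Gower double-centering + eigendecomposition (via
  `cmdscale`). Negative eigenvalues are reported, excluded from the
  proportion explained, and left uncorrected by default; Cailliez's
  additive correction is a flag.
* **PERMANOVA** uses the distance-based one-way partition
  (SS_total = Σd²/N; within-group sums analogously), pseudo-F =
  (SS_B/(a−1))/(SS_W/(N−a)), and a label-permutation p-value with the +1
  convention in numerator and denominator, so p ≥ 1/(n_perm+1) and the
  test is exact-valid. The permutation count (default 999) and seed are
  explicit arguments. The implementation reproduces `vegan::adonis2`'s
  pseudo-F to machine precision in the test suite, where vegan serves as
  an independent cross-check, not as the implementation.

Whether samples should be rarefied to even depth before diversity is left
to the analyst: all computations run on full columns, and
`rarefy_even_depth()` is provided as an explicit opt-in switch.

## Evaluation

ROC curves sweep the unique score thresholds; AUC counts ties as one half
and therefore equals the Mann–Whitney concordance U/(n₁n₀) exactly. The
composition-based classifier is a logistic model on log-transformed
signature abundances scored by leave-one-out cross-validation (the
validation scheme is not dictated by the study design, so LOO was chosen
as the least-biased scheme at n ≈ 30–40; resubstitution is available for
comparison). Separation — common at these effect sizes — triggers a
ridge-penalised fallback (glmnet, λ = 10⁻³), logged via `message()`.
Serum-marker odds ratios come from univariate logistic fits on
standardized markers with Wald intervals; marker–taxon association uses
tie-corrected Spearman correlation with Benjamini–Hochberg adjustment
across the tested grid (raw p-values are also reported, since starred
significance conventions vary).

## The synthetic-cohort generator

`simulate_counts()` emulates the statistical structure the analysis
assumes, with known ground truth:

* **Compositional model**: Dirichlet-multinomial. Base concentrations are
  log-normal (meanlog 0, sdlog 1.5) scaled so the total concentration is
  `base_concentration × n_taxa` (default 0.5 × 120 = 60, a moderate
  between-sample overdispersion typical of stool cohorts). Planted genera
  draw their base weight from a higher range (meanlog 1.2, sdlog 0.6) so
  planted effects act on biologically visible mass.
* **Study conditions**: groups of 20 (FRI), 18 (FH), 12 (HC); library
  sizes negative-binomial (mean 2×10⁴, size 10, floored at 1000 reads);
  four case-enriched genera at +3 log2 fold change and ten
  control-enriched genera at −3 in the FRI group. The source analysis
  reports no effect-size magnitudes, so ±3 log2FC is a calibration choice
  made once: large enough to mirror the reported near-complete group
  separation, small enough that recovery is not trivial at n = 50.
* **Richness deficit**: 15% of non-planted taxa are zeroed in the FRI
  group, reproducing the reported drop in Shannon and Faith's PD. These
  taxa are genuinely depleted by construction and are therefore included
  in the ground truth's depleted set.
* **Serum markers** are rank-preserving noisy transforms of linked
  planted-genus abundances: a Gaussian copula on ranks with the latent
  Pearson loading 2 sin(πρ/6) chosen to hit the target Spearman ρ
  approximately, then mapped through an exponential to a plausible
  positive scale. Default links put CRP/ESR/NEU/SAA on enriched genera
  (ρ 0.45–0.60) and WBC/IL-6 on depleted genera (ρ −0.35 to −0.45).
* **Covariates**: age uniform 18–70, sex Bernoulli at the cohort's 37:13
  male:female ratio, a sinus/pus flag for 16/20 of FRI samples.

Everything is a deterministic function of the config seed; reruns are
bit-identical, which the manifest-checksum test exercises end to end.

What the generator does **not** emulate: antibiotic exposure, sequencing
error and chimeras, phylogenetic correlation between effect and tree
position (planted genera are placed without reference to the simulated
topology), longitudinal structure, and the heavy zero-inflation beyond
what the Dirichlet-multinomial induces. Passing recovery tests therefore
show the pipeline is correct and well calibrated under a plausible
compositional model — not that real cohorts of this size will yield
AUC ≈ 1. One consequence of compositionality is worth noting: zeroing or
depleting taxa in one group mechanically inflates the relative abundance
of the remainder, so discovery on simulated data can place a few abundant
background genera on the case side. That is a property of
relative-abundance analysis itself, not a bug in discovery.

## Problem sizes and numerical choices

The test suite runs everything at the study scale (50 samples, 120
genera), with 10-seed replication for recovery claims, 200–400 replicate
null datasets for type-I calibration (binomial 95% acceptance band around
α = 0.05), exhaustive enumeration oracles at n ≤ 9, and ≤ 8-leaf random
trees for edge-enumeration UniFrac checks. PERMANOVA calibration uses 99
permutations per replicate; confirmatory runs use 999. Degenerate inputs
are pinned: constant taxa get H = 0, p = 1 in the Kruskal–Wallis screen;
all-zero samples are an error everywhere; an all-zero genus is skipped
(with a notice) by the GLM; an empty signature side is an error
instructing threshold relaxation rather than silently producing an
infinite index.

## Known limitations

* The LDA effect size is a faithful re-derivation of the published
  recipe's structure, not a byte-level port of any particular tool;
  absolute scores are comparable only within a run.
* The glm-union signature uses raw p < 0.05 per comparison (as the
  analysis it mirrors does); on strongly shifted compositions it admits
  compositional false positives by design. The LEfSe route with its
  effect-size threshold is the default for that reason.
* `pcoa` inherits `cmdscale`'s O(n³) eigendecomposition; fine for cohort
  sizes here, not for thousands of samples.
* The dysbiosis index treats missing signature genera as zero abundance
  with a warning — appropriate for absent genera, but silent relabelling
  mismatches are caught only by the id cross-validation in the readers.
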