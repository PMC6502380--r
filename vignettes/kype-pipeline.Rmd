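---
title: "Morphometrics, allometry and variance-component QTL mapping of the Atlantic salmon kype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometrics, allometry and variance-component QTL mapping of the Atlantic salmon kype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Sexually mature male Atlantic salmon (*Salmo salar*) develop a hook-like
elongation of the lower jaw — the kype — a secondary sexual trait used in
spawning hierarchies. Because aquaculture breeding replaces mate choice
with artificial fertilization, comparing domesticated, wild and hybrid
strains reared in a common garden can reveal whether relaxed sexual
selection has reshaped the kype. kypemorph implements the complete
analysis chain for such a cohort:

1. **Input formats** — TPS landmark files (tpsDig dialect), per-fish
   phenotype tables, pedigrees, and diploid genotypes at a 109-SNP panel
   mapped to the 29 salmon linkage groups.
2. **Geometric morphometrics** — generalized Procrustes alignment of six
   head landmarks, shape PCA, and per-group confidence ellipses.
3. **Allometric adjustment** — pooled OLS regressions of log10 kype
   length (KL) and height (KH) on log10 fork length; the residuals are the
   fork-length-adjusted traits AKL and AKH. Milt weight regressed on wet
   weight the same way yields gonadosomatic residuals (GSR).
4. **Mixed models** — REML fits with strain, sea-winter age (SW) and GSR
   as fixed effects and family/sire/dam random intercepts, backward
   elimination, type-III ANOVA with Satterthwaite df, and Tukey-adjusted
   estimated marginal means.
5. **QTL scan** — a variance-component linkage scan with a polygenic
   effect structured by the pedigree relationship matrix G and a
   locus-specific effect structured by the expected IBD matrix Z at each
   marker, compared by a boundary-corrected likelihood-ratio test.

Because the original photographs and genotypes are not deposited, the
package ships a first-class synthetic-cohort generator that reproduces
the study design (strains, family structure, unbalanced sea-winter
classes, allometric scaling, polygenic covariance, a plantable QTL), so
every stage is exercised end to end and validated against its generating
truth.

## The models

### Allometry

For each kype trait the pooled fit is

$$\log_{10} y_i = a + b \, \log_{10}(\mathrm{FL}_i) + \varepsilon_i,$$

estimated by OLS over all strains and sea-winter classes together; the
fitted residuals define AKL/AKH. Pooling matches the study design (one
regression per trait); a per-group option exists behind a flag. Fish with
an obscured mouth have missing KH and are excluded pairwise, never
imputed as zero.

### Mixed models

The full model for an adjusted trait is

```
AKL ~ SW*strain + SW*GSR + strain*GSR + (1|family) + (1|sire) + (1|dam)
```

fitted by REML (lme4). Backward elimination first removes random terms
by REML likelihood-ratio tests against the 50:50 mixture of chi-square 0
and 1 (the component sits on the boundary of its parameter space) at
alpha = 0.1, then fixed terms by type-III Satterthwaite tests at
alpha = 0.05, respecting marginality. Satterthwaite df are used
throughout, including for the Tukey-adjusted pairwise contrasts of the
estimated marginal means; the Kenward–Roger approximation would require a
specific adjusted covariance estimator and agrees with Satterthwaite in
the balanced designs used for validation, so a single df method keeps the
machinery uniform. In a strict full-sib design family, sire and dam
intercepts are mutually confounded; the elimination stage resolves this
empirically (the redundant components land on the boundary and are
dropped), and the trace records the removed terms so e.g. a sire term can
be re-added for a final ANOVA.

### Variance-component QTL scan

At each marker the two models are

$$y = X\beta + a + e \qquad (\text{no QTL}),$$
$$y = X\beta + a + q + e \qquad (\text{QTL}),$$

with $\mathrm{cov}(a) = \sigma^2_a G$ (pedigree additive relationship,
tabular method), $\mathrm{cov}(q) = \sigma^2_q Z$ (expected proportion of
alleles IBD at the marker) and iid residuals; fixed effects are tank,
strain and SW. The residual variance is profiled out of the REML
criterion and the two variance ratios are optimized on the log scale with
an explicit lower bound standing in for the zero boundary. Because
families with no common parents are independent, G and Z are block
diagonal and the likelihood factorizes over families; the evaluation loop
is compiled (RcppArmadillo), which keeps a 109-marker scan at n = 528
around three seconds. The LRT $2(\ell_1 - \ell_0)$ is clipped at zero and
referred to the boundary mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$.
The QTL variance proportion is
$\hat\sigma^2_q / (\hat\sigma^2_q + \hat\sigma^2_a + \hat\sigma^2_e)$.

Expected IBD is single-marker: for each offspring and parent the
transmitted parental haplotype posterior is obtained by enumerating the
four equally likely transmissions consistent with the trio's genotypes;
uninformative meioses contribute the full-sib prior 1/2 and missing
parental genotypes stay at the prior. Multipoint smoothing across
flanking markers is a deliberate non-feature (an extension point): it
would sharpen IBD near the extremes but the single-marker expectation is
the defensible minimum given a sparse panel. Two consequences are
documented below under *Limitations*.

## The synthetic cohort generator

`sim_config()` bundles every generating parameter; all randomness flows
from one integer seed through named sub-streams (pedigree, genotype,
phenotype, landmarks), so regenerating one layer never perturbs another.

* **Design** — per-cell (strain x SW) family and individual counts
  default to the study design table: 397/81/50 males in the
  kype-length subset across 1/2/3 SW (total 528), 378/58/44 in the
  kype-height subset, 37 families. Hybrid families are reciprocal
  Figgjo x Mowi crosses.
* **Fork length** — log10 means 1.778/1.903/1.991 (about 60/80/98 cm)
  for 1/2/3 SW with within-class SD 0.035; SW-graded sizes make the
  allometric adjustment non-trivial.
* **Allometry** — KL: a = -1.2, b = 1.3; KH: a = -3.3, b = 2.0. Over the
  simulated size range these give roughly 9-29 cm kype lengths and
  0.7-6 cm kype heights, matching the reported orders of magnitude; no
  per-strain moments are available for the cohort, so these are calibrated to ranges
  only.
* **Strain and SW effects** (log10 shifts) default to the magnitudes of
  the cohort-level marginal means: e.g. AKH higher in wild strains
  (Arna +0.100, Figgjo +0.115, Vosso +0.070) than the domesticated
  strain (-0.001), and both traits peaking at 2SW.
* **Genetics** — founders at Hardy-Weinberg with MAF 0.5 (maximally
  informative panel), gene-drop inheritance with Haldane recombination,
  markers evenly spaced over 29 groups of 100 cM. The optional QTL is
  biallelic, additive, placed exactly on a panel marker, and scaled so it
  explains a fraction q2 of the non-allometric variance
  sigma2_a + sigma2_q + sigma2_e.
* **Landmarks** — a six-point mean head shape plus a per-SW displacement
  field (dorsal shift of the eye, posterior gill plate and maxilla with
  age) plus isotropic Gaussian noise, scaled to a head size of 0.25 x
  fork length, randomly rotated and translated, with a digitizer pixel
  scale attached. Kype measurement points are placed so re-measuring the
  TPS file reproduces the phenotype table.

What the generator does **not** emulate: measurement error in landmark
placement beyond isotropic noise, shared-parent (half-sib) family
structure, dominance or epistasis at the QTL, selection, and any
environment-by-strain interaction. Passing tests therefore demonstrate
the correctness of the estimation machinery under the stated model, not
robustness to those features of real data.

## Numerical choices

* GPA: rotation-only superimposition (all photographs show the same
  lateral side, so reflections would be artefactual); convergence at
  1e-10 mean-shape change, 200 iteration cap; all configurations are
  first aligned onto the first specimen so the iteration path is
  independent of the orientations the inputs arrived in; the final
  solution is
  rotated onto the principal axes of the mean shape with a deterministic
  sign so the output is invariant to input orientations.
* Confidence ellipses: multivariate-t scale matrix (`MASS::cov.trob`)
  with df = n - 1, radius^2 = 2 F(level; 2, df).
* REML: variance ratios on the log scale in [-15, 8]; estimates within
  one log unit of the lower bound are reported as exact zeros. The no-QTL
  profile is minimized by golden section, the QTL profile by multi-start
  Nelder-Mead (a warm start from the no-QTL optimum inside scans, with a
  restart if the warm start ever undercuts the nested null optimum by
  more than 0.05 log-likelihood units).
* Degenerate inputs error early and by name: coincident landmarks,
  cyclic pedigrees, Mendelian-inconsistent trios, rank-deficient fixed
  designs, non-PSD covariance matrices.
* Ties in backward elimination resolve to the largest p-value candidate;
  kept-term records are appended to the trace for auditability.

## Problem sizes used in validation

The test suite validates at sizes chosen to keep Monte-Carlo error well
inside the asserted tolerances: 2,000 null replicates for the LRT
calibration at n = 400 (40 families — the boundary chi-square mixture is
asymptotic in the number of families and measurably conservative below
about 30 of them); 100 seeded replicates at n = 500 in
30 families for QTL localization and q2 recovery; 100 replicates at
n = 600 for the selection-consistency study; 10,000 offspring for the
recombination-fraction check; 10,000 points for ellipse coverage.

## Known limitations

* **QTL power at q2 = 0.05 is marginal by design.** With ~30 full-sib
  families and a sparse biallelic panel, the non-centrality of the
  variance-component LRT at a 5% QTL is of order 2-3, so the scan
  localizes such a QTL to the correct linkage group only in a minority of
  replicates. This mirrors the study's own caveat that its power to
  detect QTLs was marginal; the machinery is validated instead at larger
  planted effects, where localization is essentially certain.
* **Single-marker expected IBD attenuates and inflates.** Uninformative
  meioses shrink off-diagonal IBD entries toward the 1/2 prior, which
  reduces the spread of Z and biases the fitted sigma2_q upward (the
  classic errors-in-predictors effect on variance components). Estimated
  QTL variance proportions should be read as locus-specific signal
  summaries, not unbiased effect sizes.
* The female supplement enters the cohort bookkeeping and shape analyses
  only; females carry no kype measurements.
* Real-data headline estimates (e.g. PC1 = 46.5%, strain marginal means)
  depend on the undeposited photographs and genotypes; the synthetic
  cohort reproduces their structure and magnitudes, not their values.

## Running the pipeline

```{r}
library(kypemorph)
cfg <- sim_config(seed = 1234, qtl = list(marker = "M23_2", q2 = 0.05))
report <- run_analysis(run_config("results/run", sim = cfg))
```

The numbered drivers under `analysis/` run the same stages piecewise
(bookkeeping, simulation, morphometrics, allometry + mixed models, QTL
scan, recovery study) and write their tables under `results/`.
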