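---
title: "Methods: mapping the genetic architecture of phenotypic plasticity"
author: "plastGWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping the genetic architecture of phenotypic plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastGWAS)
```

# The problem

Phenotypic plasticity -- the capacity of one genotype to produce
different phenotypes under different environments -- is itself a
heritable, genotype-specific trait. In crops grown under contrasting
water regimes (well-watered, WW, versus water-limited, WL), alleles
that improve performance under stress can carry a cost under optimal
conditions (antagonistic pleiotropy), so loci controlling the
*response* cannot be found by mapping performance in a single
environment. `plastGWAS` implements an integrative pipeline for inbred
diversity panels phenotyped in two environments:

1. quantify plasticity per genotype with five complementary estimators;
2. decompose trait variance into genotype (G), environment (ENV) and
   residual components, and retain only informative traits;
3. run four genome-wide association scan families on each
   (trait x estimator) response;
4. retain markers by a two-stage consensus rule (at least two
   estimators within a method, high confidence for at least two
   methods);
5. interpret retained SNPs (region classification, GO
   overrepresentation, karyogram, allele-direction analysis).

Because suitable public data are replicated field trials that cannot be
bundled, the package ships a first-class synthetic-data module that
emulates the target design -- a multi-family nested association mapping
(NAM-like) barley panel -- with planted truth, so every downstream
stage is testable offline.

# The synthetic trial

`simulateGenotypes()` builds each family from two fully homozygous
founder haplotypes that differ at every marker; lines are
single-mosaic recombinant inbred derivatives with a
Poisson(`recombination_rate`) number of uniformly placed crossovers per
chromosome. Consequences, all covered by tests: within-family allele
frequencies are 1/2 in expectation; linkage disequilibrium decays with
bp distance at a rate set by `recombination_rate`; with zero
recombination every polymorphic within-family pair has $r^2 = 1$.
Founder orientation is randomised per family and marker, which yields
the weak between-family stratification typical of multi-parent panels.
Genotypes use inbred dosage coding $\{0, 2\}$ (no heterozygotes),
matching advanced-generation inbred material and keeping kinship and
effect algebra simple. Missing calls are injected completely at
random; imputation (to the marker mean) is downstream's job and
exports always keep the original missing codes.

`simulatePhenotypes()` draws, per line $i$, environment $j$ and
replicate $k$:

$$y_{ijk} = \mu_t + \textstyle\sum_q \beta_q(j)\, g_{iq} + u_i + E_j
  + \varepsilon_{ijk},$$

with $u_i \sim N(0, \sigma^2_{poly})$ an iid polygenic line effect,
$E_j = \pm\,\texttt{env\_effect}/2$ a fixed environment shift, and iid
residual noise. Trait baselines default to the well-watered means of
the six retained barley traits (grain-yield scale, grams per plant),
purely so simulated values look familiar. Defaults: 7 chromosomes of
$5\times10^8$ bp, 1.5 crossovers per chromosome per meiosis,
2 replicates per environment -- values a barley NAM trial would
consider realistic; family count and lines per family are fully
configurable because the emulated design does not fix them.

**Environment-variance convention.** With only two environments, the
"environmental variance" is parameterised as the between-environment
sample variance of the two level means, $d^2/2$ for a shift of $d$ --
exactly the quantity a two-level random-intercept REML fit estimates.
`configForProportions()` converts planted (G, ENV, residual)
percentages into `sigma2_poly`, `env_effect` and `sigma2_resid` under
this convention, so parameter-recovery tests compare like with like.

`plantQTLs()` scales each additive effect so the locus explains its
target fraction of replicate-level phenotypic variance on the
*realized* genotype frequencies: with base variance
$\sigma^2_{poly} + \sigma^2_{resid}$ and total requested fraction $F$,
the implied total is $T = (\sigma^2_{poly} + \sigma^2_{resid})/(1-F)$
and $\beta_q = \sqrt{f_q T / \mathrm{Var}(g_q)}$. Kinds: `main` (equal
effects in both environments), `plastic` (WW-only effect), and
`antagonistic` (opposite signs, equal magnitude). Note that analyses
on genotype *means* over $r$ replicates see a larger share,
$f / (f + \sigma^2_{poly} + \sigma^2_{resid}/r)$, because averaging
shrinks the residual; tests and the acceptance script use that
replicate-adjusted target where appropriate.

What the generator does *not* emulate -- and hence what passing tests
cannot show about real data: genetic map heterogeneity (cM vs bp),
selection, mutation, epistasis, spatial field trends, genotype-specific
residual variances, and multi-environment (> 2) reaction norms.

# Plasticity estimators

For genotype environment means $X_{WW}, X_{WL}$:

* **WW, WL** -- the absolute environment means, the extremes of the
  response range (they count as estimators in the consensus tally);
* **Ratio** $= X_{WW}/X_{WL}$ (direction as printed: values > 1 mean
  reduction under stress; undefined at $X_{WL}=0$);
* **RDPI** $= |X_{WW}-X_{WL}|/(X_{WW}+X_{WL}) \in [0,1]$ for
  nonnegative traits. With two environments and genotype means the
  pairwise-distance definition of the relative distance plasticity
  index collapses to this single ratio; it is symmetric and
  scale-invariant, undefined only at $(0,0)$;
* **CV** -- the sample ($n-1$ denominator, a documented and
  configurable choice; the source material does not specify)
  standard deviation of the two means over their mean;
* **Linear** -- the Finlay-Wilkinson joint-regression slope.

**Finlay-Wilkinson form.** The classic reaction-norm model is
multiplicative in the environmental index,
$y_{ij} = \mu_i + b_i E_j + \varepsilon_{ij}$, with
$E_j$ the centred environment mean computed from the same data. An
additive rendering ($\mu_i + b_i + E_j$) sometimes appears in print,
but only the multiplicative form makes $b_i$ a sensitivity slope, so
that is what `fwSlopes()` implements. With two environments
$b_i = (y_{i,WW} - y_{i,WL})/(E_{WW} - E_{WL})$ and the complete-data
genotype-average slope is exactly 1 -- an identity the tests assert to
1e-10 rather than a statistical property.

`wilcoxonEnv()` runs the paired two-sided signed-rank test on
per-genotype WW - WL differences: zeros dropped, exact distribution up
to $n = 25$ untied pairs, tie-corrected normal approximation beyond.

**Redundancy screen.** `estimatorScreen()` computes pairwise Spearman
correlations (complete cases, pooled over traits) and iteratively
breaks any pair with $|\rho|$ above 0.95 -- strongest pair first -- by
dropping its lower-priority member. The priority order
WW > WL > Linear > RDPI > Ratio > CV is a package decision: the source
analysis only records that CV was the redundant estimator dropped, so
the order encodes "absolute values first, then the derived metric most
distinct from them", and puts CV last.

# Variance decomposition and trait retention

`fitVarianceComponents()` fits
$y_{ijk} = \mu + G_i + E_j + (GE)_{ij} + \varepsilon_{ijk}$ with all
terms random, by REML via `lme4`. Numerical choices:

* REML cannot produce negative components (truncation at zero is
  structural, not post hoc); a near-zero component flags itself via
  its likelihood-ratio test.
* Significance of G and ENV uses the boundary-corrected LRT: the null
  distribution is the mixture
  $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, the standard remedy for
  testing a variance on its boundary. Calibration is verified by
  simulation.
* The GxE term is pooled into the residual by default (the reference
  decomposition reports no GxE column; whether it was estimable is
  unstated). With `include_gxe = TRUE` it is fitted when replication
  within (genotype, environment) cells allows, otherwise reported
  merged with a flag.
* A two-level environment factor yields an unstable random-effect
  variance, so the fixed-effect environment share of the total sum of
  squares is also reported (`prop_ENV_fixed`) as a flagged fallback.
* The lme4 optimizer runs at tightened tolerance (1e-14 relative) so
  balanced-design estimates agree with closed-form method-of-moments
  ANOVA estimators to 1e-6, which the tests check.

`retentionFilter()` encodes the published screening logic as explicit
rules: drop traits whose genotype component is not significant
(`alpha_G`, default 0.05), drop traits without a relevant environmental
response (`min_prop_env`, default 5%), and optionally drop the single
remaining trait most dominated by residual noise. The numeric cutoffs
are package defaults -- the source names the excluded traits but not
thresholds -- and the shipped reference table
(`barleyVarianceTable()`) reproduces the expected six retained traits
under them.

# Association scans

All scans take a per-genotype response (an environment mean or a
plasticity estimator) against a QC'd panel. `markerQC()` applies the
stated panel rules: markers with at least 10% missing calls removed,
monomorphic markers removed, and "complete linkage disequilibrium"
operationalized as $r^2 = 1$ on complete cases with the first marker
in map order kept (a deterministic tie-break).

**Kinship mixed model (`mlmScan`).** Per marker,
$y = \mu + x_m\beta_m + g + \varepsilon$ with
$g \sim N(0, \sigma^2_g K)$ and $K$ the VanRaden genomic relationship.
The variance ratio is estimated once on the null model via the
eigendecomposition of $K$ (the population-parameters-previously-
determined shortcut -- orders of magnitude faster than per-marker REML
with negligible p-value distortion at these scales), then every marker
gets a generalized-least-squares Wald t-test. Two design points:

* With $K = I$ the test reduces *exactly* to the OLS t-test -- the
  oracle-equivalence tests rely on this.
* By default the scan uses **leave-one-chromosome-out (LOCO)**
  kinship: markers on the tested chromosome are excluded from $K$.
  With a whole-genome $K$ the tested marker contributes to its own
  covariance correction (proximal contamination) and the null scan is
  mildly conservative; LOCO restores uniform null p-values, which the
  calibration tests verify. Supplying `K` explicitly disables LOCO.

**Multi-locus scan (`multilocusScan`).** A faithful-in-spirit
re-derivation of the published principles of iterative multi-locus
GWAS (the FarmCPU/BLINK family), not a port: (i) single-marker tests
given current pseudo-QTN covariates; (ii) candidates by ascending p,
skipping any in LD ($r^2 > 0.7$) with an already-selected candidate;
(iii) pseudo-QTN set size chosen by BIC over nested candidate sets;
(iv) all markers re-tested with the selected pseudo-QTNs (excluding
self and linked) as covariates; iterate to a stable set (max 10
iterations). With no candidate passing the entry threshold the result
equals the plain single-marker scan, a degenerate case the tests pin.

**Tree-ensemble importance scans (`mlImportanceScan`).** Random-forest
(impurity importance, 500 trees by default) and gradient-boosting
(gain importance; learning rate 0.05, depth 4) regressors of the
response on all markers. Fixed, recorded hyperparameters stand in for
"defaults unless otherwise specified". Importances have no null
distribution of their own, so an empirical max-statistic null is
built: the model is refit on permuted responses and the maximum
importance per refit is pooled;
$p_m = (1 + \#\{\text{null maxima} \ge I_m\})/(B+1)$. The max-null
makes the p-values family-wise valid and hence conservative per
marker -- the calibration tests check validity, not exactness. All
fits are single-threaded and seeded, so results are bit-reproducible.

**Significance calling.** Benjamini-Hochberg FDR at 0.05 for
model-based p-values, direct $\alpha = 0.05$ for the (already
family-wise) permutation p-values, Bonferroni available. The source
analysis does not state its per-method criteria, so these are
explicit, configurable package defaults.

# Consensus retention

The two-stage rule: within each method, keep markers significant for
at least two of the five estimators (WW and WL count toward the tally,
matching how the absolute values are intersected with the plasticity
metrics); then annotate the union across methods and flag markers
retained by at least two methods as high-confidence. Whether the
original analysis applied the estimator rule within each method first
or pooled estimators across methods is not stated; within-method-first
is the default and the pooled alternative is available via
`within_method = FALSE`. Upset-style summaries use exact-subset
(disjoint) counts, so counts over all subsets sum to the union size.

`qtlVarianceExplained()` regresses the response on retained-marker
genotypes (plus an environment term for joint two-environment
responses) and reports sequential in-sample percentages alongside an
adjusted proportion and a 5-fold cross-validated $R^2$, to temper
small-sample inflation when marker sets grow.

# Functional interpretation

* `classifyRegion()`: a marker inside any CDS interval (union over
  transcripts) is *coding*; inside a gene body but outside every CDS,
  *intronic* -- UTR positions therefore classify as intronic in this
  deliberate three-way scheme; otherwise *intergenic* with the bp
  distance to the nearest gene boundary.
* `goEnrichment()`: one-sided Fisher exact test per GO term with BH
  FDR. Genes, not SNPs, are the counting unit (a gene counts once
  however many SNPs hit it) -- a flagged assumption. No GO-graph
  ancestor propagation is performed.
* `alleleDirection()`: allele-stratified estimator means per marker,
  with an antagonism flag when the WW and WL effect estimates differ
  in sign and each exceeds $k = 2$ standard errors. The noise floor is
  a package choice (direction reversal is described only qualitatively
  in the source); $k = 2$ keeps the false-positive rate on same-sign
  controls at or below 10% in the recovery tests.
* `karyogramExport()`: BED (0-based, half-open) with the exact inverse
  conversion back to 1-based map positions.
* `makeAnnotationFixture()` writes a synthetic GFF3 and gene-to-GO map
  (labelled synthetic) so the whole annotation path runs offline; real
  annotation files in the same formats are accepted but never
  required.

# Problem sizes and reproducibility

The test suite and the acceptance script exercise the pipeline at desk
scale, chosen as the smallest sizes at which each statistical property
is comfortably measurable: panels of 100-400 lines and 120-500
markers, 10-50 simulation seeds per property, 100 permutations for the
ensemble scans. Every stochastic routine takes a mandatory seed and
restores the caller's RNG state, so any output is a pure function of
(configuration, seed).

# Known limitations

* Two environments only; multi-environment RDPI averaging and
  nonlinear reaction norms are out of scope.
* The iid polygenic line effect is not marker-linked, so the simulator
  understates the confounding a real polygenic background creates for
  the scans.
* The multi-locus and ensemble scans are method-family equivalents
  built from stated principles; they are not numerical replicas of any
  external software.
* GO enrichment ignores term dependence beyond BH FDR and does not
  propagate the GO graph.
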