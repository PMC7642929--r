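---
title: "Dissecting plasticity QTL in a NAM population: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting plasticity QTL in a NAM population: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarnam)
```

# The problem

The shade avoidance response (SAR) is a syndrome of developmental changes —
accelerated bolting, faster inflorescence elongation, reduced biomass —
triggered in plants by a low red:far-red light ratio signalling neighbour
proximity. `sarnam` implements a complete analysis chain for dissecting the
genetic architecture of such plasticity in a nested association mapping (NAM)
population: several biparental recombinant-inbred-line (RIL) families that
share one recurrent parent, phenotyped for a cascade of developmental traits
(bolting days BD, rosette biomass RB, inflorescence growth IG, inflorescence
biomass IB) under two light treatments (sun and shade).

The chain has four stages, each usable on its own:

1. **Synthetic NAM generator** — genotypes and cascading sun/shade trait data
   with known ground truth, so every downstream stage has a recovery target.
2. **Line effects** — a mixed model per family and trait that turns replicated
   observations into per-line genotype (G) and plasticity (GxE) effects,
   variance components, PVE and CV~p~.
3. **QTL scan** — joint multi-family forward-stepwise Haley–Knott mapping of
   the plasticity effects, with background-kinship correction, permutation
   thresholds, TASSEL-style confidence intervals and per-QTL PVE.
4. **Path analysis** — multi-group (sun/shade) recursive path models that
   split each QTL's effect on a late trait into a direct effect and indirect
   effects transmitted through earlier traits.

# The synthetic generator

## Genotypes

RIL genotypes are simulated directly at the selfed-inbred limit rather than by
generation-by-generation meiosis. Along each chromosome the indicator of the
non-recurrent allele follows a Markov chain whose adjacent-marker switch
probability is the Haldane–Waddington expansion

$$ R = \frac{2r}{1 + 2r}, $$

of the per-meiosis recombination fraction $r$, obtained from the cM distance
through the Haldane map function (no interference; Kosambi is available as
`mapFunction = "kosambi"`). This matches the marginal two-locus properties of
single-seed-descent RILs at a fraction of the cost. Residual heterozygosity
from finite selfing is injected per locus at rate $(1/2)^g$ after $g$ selfing
generations (F8 lines: $g = 7$, rate $\approx 0.0078$) and recorded as dosage
0.5, which is how genotype-probability pipelines represent such calls.

Defaults mirror the population the package is designed around: seven families
(Blh-1, Bur-0, Cvi-0, Ita-0, Jea, Oy-0, Sha donors; Col-0 recurrent), 165
lines per family, five chromosomes, F8 selfing. Family sizes are equal because
per-family counts are not published for the motivating panel. Tests and the
demo pipeline use 3 families x 100 lines to keep runtimes down; the scale is
fully configurable.

## Phenotypes

Latent trait values are built per line and environment in developmental order
BD, RB, IG, IB:

$$ z_{t} = \mu_t + \beta_t\,\mathrm{shade} + \sum_q a_{qtf e}\, x_q
   + \sum_{s < t} b_{st e}\, z_s + g_t + u_{te}, $$

with per-family QTL effects $a$ (an allelic series is a family-indexed effect
vector on the non-recurrent allele; a plasticity QTL has unequal sun/shade
effects), environment-specific path coefficients $b$, a shared line deviation
$g_t \sim N(0, \sigma^2_G)$ and an independent per-environment deviation
$u_{te} \sim N(0, \sigma^2_{GxE})$ — exactly the RIL and RIL:TRT random
effects the downstream mixed model estimates. Observed replicates add a shelf
(block) effect and residual noise $N(0, \sigma^2_e)$.

The default truth (`demoTruth()`) states treatment main effects on the
transformed scale equal to the reported population-level shade responses of
the four traits (BD $-0.58$, RB $-0.78$, IG $+0.27$, IB $-0.15$ sd). Values no
source states were chosen once and are not tuned: variance components give
moderate heritability ($\sigma^2_G$ 0.25–0.4, $\sigma^2_{GxE}$ 0.05–0.08,
$\sigma^2_e$ 0.5–0.6, shelf sd 0.1 — mid-range for greenhouse quantitative
traits), and the cascade coefficients (BD→RB 0.4/0.6 sun/shade, BD→IG
−0.3/−0.4, RB→IB 0.5, IG→IB 0.3) encode the biology that early bolting reduces
rosette investment and that biomass integrates earlier growth, with a stronger
BD→RB link in shade.

What the generator deliberately does **not** emulate: genotyping error and
HMM-based genotype-probability inference, segregation distortion, epistasis,
non-linear trait relationships, and non-Gaussian residuals. A green test
therefore establishes correctness of the estimation machinery under the
stated model, not robustness to those violations.

# Line effects: the plasticity mixed model

Per family and trait the package fits, by REML via `lme4`,

$$ P_{ijkl} = \mathrm{SHELF}_i + \mathrm{TRT}_j + \mathrm{RIL}_k +
   \mathrm{RIL{:}TRT}_{jk} + e_{ijkl}, $$

with shelf (spatial block; experiments are absorbed by concatenating
experiment and shelf labels) and treatment fixed, line and line-by-treatment
random. The original analysis this models used a Bayesian fit with student-t
residuals; this package substitutes Gaussian REML + BLUPs — deterministic,
dependency-light, and checkable against closed forms, with posterior means
under vague priors coinciding with BLUPs for Gaussian models. Sun is the
reference level throughout, so the treatment coefficient and every "plasticity"
quantity is shade minus sun (shade > sun ⇒ positive).

Outputs per family and trait:

* **Variance components** $\sigma^2_G, \sigma^2_{GxE}, \sigma^2_e$, with
  `G_PVE` and `GxE_PVE` defined as each component over their sum, and
  $CV_p = \sigma_{GxE} / |\mu_\mathrm{plasticity}|$ (standard deviation over
  the absolute mean plasticity; an error, never a silent infinity, when the
  mean plasticity is zero).
* **Line effects**: the G BLUP and the GxE BLUP contrast (shade line deviation
  minus sun line deviation). The GxE contrast is the scan phenotype for the
  "shade response" of a trait.

Traits are Box–Cox transformed before fitting (profile likelihood on a
$\lambda$ grid $[-2, 2]$ step 0.05, exact ties broken toward $\lambda = 1$,
automatic shift for non-positive values) and standardised to mean 0, sd 1, so
effects are in sd units.

The test suite pins this stage to two independent oracles: a dense 2-D
grid-search REML likelihood (agreement to 3 decimals on a 50-line toy) and the
closed-form balanced-design shrinkage BLUPs (agreement to 1e-8).

# The QTL scan

## Single-marker joint test

At each test marker, per family, a Haley–Knott linear mixed model is fitted:
the phenotype (a line-effect column) is regressed on the expected
non-recurrent-allele dosage, with a random effect whose covariance is
$\tau^2 K + \sigma^2 I$. $K$ is the genomic relationship matrix built from
centred dosages of all markers **farther than 10 cM** from the test marker
(only the window on the test chromosome is removed — all other chromosomes are
retained), which prevents the tested signal from being absorbed into the
background ("proximal contamination"). The variance ratio
$h^2 = \tau^2/(\tau^2+\sigma^2)$ is profiled on the fixed grid
$\{0, 0.05, \dots, 0.95\}$; the grid is not refined further because the
likelihood-ratio differences between adjacent grid points are far below test
resolution while determinism and permutation cost dominate.

Marker effects are estimated per family — never pooled — which is what makes
cross-family allelic-series comparison possible. Families where the test
marker is monomorphic contribute zero likelihood ratio. The joint statistic
sums family LRs and is referred to a chi-square. The published convention of 6
df for 7 families is reproducible via `dfRule = "fixed:6"`; the default,
`"segregating-families"`, uses the number of families where the marker
actually segregates, since each segregating family contributes one
allele-substitution parameter. Both are recorded in the scan output.

## Threshold, stepwise search, intervals

The genome-wide entry threshold is the 95% quantile (type-7) of
per-permutation maximum $-\log_{10} p$ over 1000 within-family permutations of
the line-to-genotype assignment, with counter-derived child seeds so the
threshold is reproducible. The forward stepwise search adds the best marker
exceeding the threshold, conditions on it, and rescans (ties broken toward the
lower chromosome/bp and logged). Scans use a pruned marker set built by
dropping the later member of adjacent pairs correlated above 0.99 (pooled
across families after within-family centring).

Confidence intervals follow the TASSEL-style rule: flanking markers of the
full map are added one at a time at increasing distance from the peak, and the
bound on each side is the nearest added marker that leaves the peak's p-value
at or below $\alpha$ — one outward pass only. Whether $\alpha$ here is the
nominal 0.05 or the permutation-derived level is not settled by the source
description; the package defaults to nominal 0.05 (`ciAlpha`), overridable.
Per-QTL SNP PVE is the incremental variance the marker explains (plain
Haley–Knott OLS, pooled over families) relative to the total phenotypic
variance of the scan phenotype.

# Path analysis and mediation

## Conditional scans

`qtlPathScan()` repeats the joint scan for each trait with the G and GxE
effects of every earlier trait (order BD → RB → IG → IB, fixed by
developmental timing) as fixed covariates. Line-level effects, not observed
per-environment differences, are used as the covariates — they are on the same
scale as the scan phenotype and free of replicate noise. A QTL whose effect on
a late trait is transmitted through an earlier trait loses its peak in the
conditional scan; a direct effect survives.

## Multi-group path model

For the final model, colocalizing QTL (confidence intervals overlapping in bp
on the same chromosome) are merged into single QTL regions, and a recursive
path model is fitted separately to the sun and shade groups, per family.
Estimation is per-equation ordinary least squares: for recursive
observed-variable systems with independent errors this coincides with
full-information maximum likelihood, is exact, and needs no SEM optimiser. The
implied covariance is assembled from the structural matrices as
$(I-B)^{-1}\Psi(I-B)^{-T}$ with the exogenous (QTL) block saturated at the
observed covariance; all covariances use the $n-1$ denominator so a saturated
model reproduces the observed moments exactly ($\chi^2 = 0$, CFI $= 1$,
RMSEA $= 0$, SRMR $= 0$).

Model fit per group: $\chi^2 = (n-1) F_{ML}$, df = non-redundant moments minus
free parameters, CFI against the independence model, RMSEA
$= \sqrt{\max(0, (\chi^2 - df)/(df\,(n-1)))}$, SRMR as the root mean square of
standardised residual covariances. Multi-group indices pool $\chi^2$ and df
across groups; SRMR is averaged.

Backward elimination drops, among terms non-significant ($p > 0.01$) in
**both** environments, the one with the largest minimum-across-group p-value,
refitting until every remaining term is significant in at least one
environment. Given distinct p-values the result is invariant to term input
order.

## Decomposition

For each QTL, trait, family and group, `decomposeEffects()` reports the direct
effect (the QTL→trait coefficient; zero if eliminated), one indirect component
per mediating path (the product of edge coefficients), their total, and
`total = direct + Σ indirect`, which equals the reduced-form coefficient
implied by the fitted system — an exact identity that the tests enforce at
1e-10. Standard errors for products use the first-order delta method with
coefficient covariances taken within equations and zero across equations
(per-equation OLS estimates are asymptotically uncorrelated in a recursive
system; a seeded nonparametric bootstrap could replace this but is not needed
at the package's scales). Environment contrasts are shade minus sun with
$SE = \sqrt{SE^2_{sun} + SE^2_{shade}}$. A trait unreachable from a QTL in the
reduced graph yields an all-zero decomposition flagged `disconnected`.

# Numerical and design choices

* **Degenerate inputs** raise classed conditions (`sarnamInvalidArgument`,
  `sarnamDegenerateInput`, `sarnamKeyingError`, ...) naming the offending
  marker, line or column, so callers can distinguish failure modes.
* **Determinism**: one master seed; stage and permutation seeds are derived by
  counter (all below $2^{31}$). Identical configs give byte-identical tables.
* **Boundaries**: variance components may sit at zero; kinship eigenvalues are
  floored at zero; $LR \ge 0$ holds by construction because null and full
  models are maximised over the same $h^2$ grid.
* **Pruning semantics**: which member of a too-correlated pair is dropped is
  not specified by the source method; the later-in-map-order member is dropped
  here, which keeps the first marker of every chromosome.
* **Tie-breaks** in the stepwise search go to the lower (chromosome, bp) and
  are logged in the model object.

## Acceptance-test sizing

The recovery criteria are checked at the population scale the package's
defaults state: the FWER calibration uses 3 families x 150 lines with 200
markers and 200 permutations; the allelic-series recovery uses the full
7-family, 165-line panel on a 10 cM framework map, because localisation of a
0.5 sd effect to within one marker is a property of the whole NAM design — two
informative families of 150 lines cannot place such an effect to ±3 cM, and no
marker density is stated for that criterion.

# Limitations

* Gaussian REML replaces the heavy-tailed Bayesian fit; outliers in real data
  should be screened beforehand (a robust option is deliberately out of scope).
* All trait→trait relationships are linear; the motivating biology suggests
  the effect of bolting time on later traits may be partly non-linear.
* Delta-method SEs for indirect effects ignore cross-equation covariance;
  at the package's sample sizes this is negligible against sampling noise.
* The permutation threshold treats lines as exchangeable within families,
  which is exact for line-effect phenotypes but would be anti-conservative
  under strong residual family substructure.

# A worked example

```{r example, eval = FALSE}
library(sarnam)
cfg <- pipelineConfig(
  outDir = tempfile("sarnam_demo_"), seed = 11,
  families = c("Blh-1", "Bur-0", "Cvi-0"), linesPerFamily = 100,
  nChromosomes = 2, markersPerChromosome = 40, nPermutations = 100
)
manifest <- runPipeline(cfg)
read.delim(file.path(cfg$outDir, "qtl_table.tsv"))
```

The demo truth plants a BD plasticity QTL (allelic series across families,
effect only in shade) and a non-plastic RB QTL. The scan finds the BD QTL for
`BD_SAR` and — through the BD→RB developmental edge — also for `RB_SAR`, while
the non-plastic RB QTL is correctly absent from every shade-response scan; the
path stage then attributes the `RB_SAR` signal to the mediated route. The
README shows the printed output of this exact run.
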