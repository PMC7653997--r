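---
title: "Dissecting feed-efficiency GWAS with association weight matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting feed-efficiency GWAS with association weight matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awmfe)
```

## The problem

Feed efficiency in growing cattle is measured by several partially
redundant criteria. **Residual feed intake (RFI)** is the part of daily
feed intake (FI) that is not explained by maintenance requirements and
growth: an efficient animal eats less than predicted, so negative RFI is
favourable. **Residual gain (RG)** flips the regression: it is the part
of average daily gain (ADG) not explained by intake and body weight, so
positive RG is favourable. The **feed-efficiency ratio (FE)** is simply
ADG/FI. The three criteria have moderate heritabilities (around 0.35)
and are genetically correlated but not identical, so part of their
genetic determinism is shared and part is criterion-specific. This
package implements an analysis chain for dissecting that structure from
genotyped populations:

1. derive the efficiency criteria from raw feeding records,
2. precorrect all traits for management fixed effects,
3. run a mixed-linear-model association scan (MLMA) per trait,
4. build an **association weight matrix (AWM)** around each efficiency
   criterion to select co-associated genes,
5. quantify trait relationships by z-score genomic correlations and the
   variance captured by selected versus random marker panels.

Because individual feed-intake records are proprietary in practice, the
package ships a quantitative-genetic simulator that generates
populations with the same statistical structure, and every stage is
tested against it.

## Trait construction

Animals are weighed at the start and end of a feeding test of length
$\Delta t$ days. The package derives:

* $\mathrm{ADG} = (w_{final} - w_{initial}) / \Delta t$ (kg/day),
* mid-test weight $= (w_{initial} + w_{final})/2$, and the metabolic
  mid-test weight $\mathrm{MMW} = \text{mid-test weight}^{0.75}$
  (kg^0.75^), the classical allometric proxy for maintenance,
* $\mathrm{FE} = \mathrm{ADG} / \mathrm{FI}$ (kg gain per kg dry matter).

The residual criteria are ordinary-least-squares residuals of

$$\mathrm{FI} = year + \beta_1\,\mathrm{MMW} + \beta_2\,\mathrm{ADG} +
\beta_3\,\text{final age} + \mathrm{RFI}$$

$$\mathrm{ADG} = year + \beta_1\,\mathrm{MMW} + \beta_2\,\mathrm{FI} +
\beta_3\,\text{final age} + \mathrm{RG}$$

with contemporary-group year as a categorical fixed effect. Two
properties follow from the OLS construction and are asserted by the test
suite on every fixture: the residual traits have mean zero, and RFI is
phenotypically uncorrelated with MMW and ADG (likewise RG with MMW and
FI) — being uncorrelated with its component traits is the defining
feature of a residual efficiency criterion.

The mid-test weight is taken as the arithmetic mean of the endpoint
weights. Records of intermediate weighings are not modelled; only
endpoint weights enter the criteria, so a growth-curve-based mid-test
weight is out of scope.

Before association analysis, all six traits (RFI, RG, FE, FI, FW, ADG)
are precorrected by OLS for contemporary-group year, dam-age class
(3/4/5/6+), twinning and the final-age covariate. Precorrection and the
residual-trait regressions are two distinct models, applied in that
order: the criteria are built from raw records first, then everything is
corrected with the full covariate set. Single-level factors and constant
covariates are dropped from a model rather than producing a
rank-deficient fit; genuine collinearity among informative regressors is
an error that names the offending terms.

## Mixed-model association

The scan follows the classical two-step MLMA scheme. For each trait the
null model

$$\mathbf{y} = \mathbf{1}\mu + \mathbf{u} + \mathbf{e}, \qquad
\mathbf{u} \sim N(\mathbf{0}, \mathbf{G}\sigma_u^2), \quad
\mathbf{e} \sim N(\mathbf{0}, \mathbf{I}\sigma_e^2)$$

is fitted by REML, where $\mathbf{G}$ is the genomic relationship matrix
built from centered dosages ($\mathbf{G} = \mathbf{Z}\mathbf{Z}' / 2\sum_k
p_k(1-p_k)$, the frequency-centered construction with aggregate scaling
that mixed-model GWAS software uses by default). The variance components
are then **held fixed** while each variant is tested under

$$\mathbf{y} = \mathbf{1}\mu + \mathbf{x}b + \mathbf{u} + \mathbf{e}$$

by generalized least squares; $z = b/\mathrm{se}(b)$ and the P-value
comes from the two-sided normal tail. Fractional imputed dosages in
[0, 2] are accepted as-is; monomorphic variants are emitted with
$z = 0$, $p = 1$ and a flag rather than dropped, so every summary table
covers the full variant universe.

Numerically, the GRM is eigendecomposed once; in the rotated basis the
covariance is diagonal, the restricted likelihood profiles to a
one-dimensional function of $h^2 = \sigma_u^2/(\sigma_u^2+\sigma_e^2)$,
and each variant test is O(n). The REML optimum is found by Brent search
on $h^2 \in (10^{-6}, 1-10^{-6})$ with the common scale profiled out —
for a single-kernel model this is exact, which is why the package uses
it instead of an iterative AI-REML update; the test suite checks the
maximized restricted likelihood against a brute-force dense grid search.
The standard error of $h^2$ is obtained from the numeric observed
information of $(\sigma_u^2, \sigma_e^2)$ by the delta method; at the
$h^2 = 0$ boundary the information can be singular and the SE is
reported as `NA`. Two exact reductions serve as oracles: with
$\sigma_u^2 = 0$ the scan equals per-variant OLS with known residual
variance, and REML estimates are location-invariant and scale as $c^2$
under $y \to cy$.

Variant QC retains variants with call rate $\ge$ 0.90, MAF $> 0.01$,
Hardy–Weinberg P $\ge 10^{-4}$ and, when an imputation-quality column is
present, $R^2 > 0.30$ — strict inequalities for MAF and $R^2$ follow the
"higher than" convention used for imputed sequence data. The HWE test is
a 1-df chi-square on genotype counts. The Bonferroni threshold on the
$-\log_{10}$ scale is `bonferroni_threshold(alpha, m)` $= -\log_{10}
(\alpha/m)$; at the sequence scale (millions of tests) it lands above 8,
which is why scans of polygenic efficiency traits rarely produce
genome-wide-significant single variants and why a co-association
analysis is used instead.

## The association weight matrix

An AWM run is anchored on one **key phenotype** and proceeds in three
stages with two thresholds (defaults in parentheses):

1. **Rows.** Variants with $P \le 0.001$ for the key phenotype enter the
   matrix (the threshold is inclusive).
2. **Columns.** For every other trait, the Pearson correlation between
   its z-scores and the key trait's z-scores is computed *over the
   stage-1 rows*; traits with $|r| \ge 0.25$ are retained. The key trait
   is always retained. A trait whose z-scores are constant over the
   stage-1 rows has no defined correlation and is not retained.
3. **Secondary rows.** Variants outside stage 1 that are associated
   ($P \le 0.001$) with at least 2 retained non-key traits are recruited.

One marker per gene is then selected. A variant belongs to a gene when
its position lies inside the gene body (1-based closed interval, strand
ignored); variants inside no gene are reported separately and excluded
from the gene table. When genes overlap, the gene whose midpoint is
nearest wins. Within a gene, the variant associated with the largest
number of retained traits is chosen; ties are broken by the smallest
*cumulated P-value* — the arithmetic sum of raw P-values over the
variant's associated traits — and remaining ties by genomic position,
so the selection is deterministic. The package also exposes the
correlation type and the cumulated-P definition exactly as stated here;
they are the most literal reading of common AWM practice, and the test
suite pins the whole procedure against an exhaustive rule-by-rule
enumeration on small instances.

The network summary classifies genes by the association pattern of
their chosen marker: key-trait only, key plus at least one other trait,
and other traits without the key. These three categories partition the
gene total exactly — an identity asserted on every run. Gene-level
flags are those of the chosen variant, not the union over the gene's
variants, so the per-trait counts refer to selected markers.

## Genomic correlations and heritability contrasts

Over the rows of an AWM, the Pearson correlation between two traits'
z-score columns is a summary-statistic proxy for their genetic
correlation on the co-associated variant set. It is computed over all
rows of the given AWM (one matrix per run, reported side by side when
several key traits are configured), is invariant to row permutation and
to common positive rescaling of the z columns, and requires at least 3
rows and 2 retained traits.

`greml_h2()` builds a GRM from a chosen variant subset only and
re-estimates $h^2$ — the SNP-based heritability captured by that panel.
`heritability_contrast()` compares a selected panel against an
equal-size panel drawn uniformly without replacement from the remaining
variants (seeded, reproducible). No MAF matching is applied by default;
the contrast is meant as the qualitative check that a co-association
selection concentrates genetic variance far beyond a random panel of the
same size.

## The synthetic population

`sim_config()` defaults encode the study design the package emulates: a
genotyped population of 789 growing bulls, tens of thousands of SNPs, 22
contemporary-group year classes, four dam-age classes (3/4/5/6+), a 3%
twinning rate, a 175-day test, and base traits FI, ADG and FW with means
and SDs of 10.63 (1.23) kg DM/day, 1.44 (0.19) kg/day and 695 (87) kg —
the scale of Charolais bulls on a fattening test. Heritabilities default
to 0.35 for each base trait and the genetic correlations to r(FI,ADG) =
0.44, r(FI,FW) = 0.76, r(ADG,FW) = 0.80, pedigree-scale values for these
traits in beef cattle.

Genotypes are drawn through a Gaussian copula: each variant's latent
value follows an AR(1) process within an LD block and the allele is the
latent value thresholded at the normal quantile of the variant's allele
frequency, so marginal frequencies are exact while adjacent variants are
positively correlated (`ld_block_size = 1` gives independent variants).
Causal effects are sampled from a multivariate normal across the base
traits and then linearly rotated so that the *realized* breeding values
match the target correlation matrix and heritabilities exactly. The
rotation is deliberate: with a few hundred causal variants, raw sampling
noise in the effect draws would be of order $1/\sqrt{n_{causal}}$ and
parameter-recovery tests would conflate estimation error with simulation
error. Pleiotropy is complete — every causal variant affects all base
traits with correlated effects. Fixed effects are independent draws per
class level with magnitudes around half a phenotypic SD (a quarter for
dam age and twinning; the final-age slope contributes about a quarter SD
over the age range), large enough to matter if precorrection were
skipped, small enough not to dominate.

Initial weight is derived as $FW - ADG\,\Delta t$ so that ADG and MMW
are exactly recoverable from the emitted endpoint records; in the
extreme tails initial weight is floored at 5% of final weight and ADG
recomputed, keeping records internally consistent. RFI, RG and FE are
*not* simulated directly — they emerge from the derivation applied to
simulated records, exactly as they would from real records, so their
heritabilities and mutual correlations are emergent properties rather
than dials. The simulator does not model pedigree structure (no
sire-family clustering), selection, genotyping error, or an
imputation-error process; passing tests therefore demonstrate the
correctness and calibration of the machinery on an idealized polygenic
population, not robustness to those real-data features.

## Problem sizes and numerical choices

The test suite and the acceptance script use desk-scale populations:
n = 250–1000 individuals and 600–2000 variants, sizes at which the
statistical properties under test (REML calibration, scan size,
selected-versus-random contrasts) are already stable. Tolerances follow
the property being checked: exact identities (partition counts, FE =
ADG/FI, OLS orthogonality) at 1e-8 or exactly; oracle equivalences at
1e-4 to 1e-8; stochastic parameter-recovery bands at ±0.10 with 8/10
seeds. GRM eigenvalues are floored at zero; variances at 1e-8; the
profile REML search runs on $h^2 \in (10^{-6}, 1-10^{-6})$.

## Known limitations

* The one-kernel profile REML is exact but specific to a single GRM; a
  multi-kernel partition would need an iterative REML.
* The MLMA carries no covariates beyond the grand mean — covariates are
  handled entirely by precorrection, matching the two-step design it
  implements.
* Gene assignment is strictly within gene bodies; a nearest-gene policy
  for intergenic variants is a documented alternative some AWM analyses
  use, and intergenic variants are reported so the user can see the cost
  of the policy.
* Gene–gene edge inference downstream of the AWM selection (e.g. PCIT)
  and ontology enrichment are out of scope; the gene tables and edge
  lists are written so external tools can consume them.

## A minimal run

```{r eval = FALSE}
cfg <- run_config(
  out_dir = "awmfe_demo",
  simulate = sim_config(n_individuals = 600, n_variants = 2000,
                        n_causal = 60, n_genes = 300, seed = 1),
  p_threshold = 0.01, seed = 1
)
manifest <- run_pipeline(cfg)
```

The run directory then holds `phenotypes_derived.tsv`,
`phenotypes_corrected.tsv`, `qc_report.tsv`, one `gwas_<trait>.tsv` per
trait, `variance_components.tsv`, per-key `awm_<key>.tsv` and
`genes_<key>.tsv`, `genomic_correlations.tsv`, `h2_contrast.tsv`,
`summary.json` (gene categories, per-trait counts, cross-key overlap)
and `manifest.json` with MD5 checksums that reproduce bit-for-bit under
the same seed.
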