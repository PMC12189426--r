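---
title: "Models and methods behind ssblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ssblup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssblup)
```

## The problem this package addresses

Litter-size traits in pigs — total number born (TNB), number born alive
(NBA), number of healthy births (NHB) and their companions — are
economically central but statistically awkward: heritabilities sit between
0.01 and 0.06, every sow contributes repeated records across parities, and
in a modern nucleus herd only a small core of the pedigree (a few thousand
of tens of thousands of animals with records) is genotyped. `ssblup`
implements the full quantitative-genetics pipeline for this setting:
repeatability animal models with pedigree or combined pedigree–genomic
(single-step) relationships, REML variance components, expected accuracy
from prediction error variance with k-fold cross-validation, and the
iteratively weighted single-step GWAS that decomposes genetic variance into
0.3 Mb marker windows.

## The repeatability animal model

All analyses start from

$$y = Xb + Za + Wt + e$$

where $y$ are the phenotypic records, $b$ the fixed effects of
farm-year-month and parity (treatment contrasts: the first level of each
factor is the reference), $a \sim N(0, K\sigma_a^2)$ the additive genetic
effect of every pedigree animal, $t \sim N(0, I\sigma_{pe}^2)$ a permanent
environment effect per sow with records, and $e \sim N(0, I\sigma_e^2)$.
$K$ is either the numerator relationship matrix $A$ (pedigree BLUP) or the
single-step matrix $H$ (ssGBLUP). Heritability is
$h^2 = \sigma_a^2/\sigma_p^2$ and repeatability
$(\sigma_a^2+\sigma_{pe}^2)/\sigma_p^2$ with
$\sigma_p^2 = \sigma_a^2+\sigma_{pe}^2+\sigma_e^2$. Whether parity also
defines the permanent-environment grouping was left open by the model
statement we follow; we use sow identity alone, with parity as a fixed
class, which is the common choice for litter records.

Solutions come from Henderson's mixed model equations in variance-ratio
form; the coefficient matrix is factorised with a sparse supernodal
Cholesky (the `Matrix` interface to CHOLMOD), and prediction error
variances (PEV) are diagonal entries of its inverse, obtained by solving
for unit vectors in column blocks.

### Relationship matrices

* `a_inverse()` assembles $A^{-1}$ directly from the pedigree by
  Henderson's rules. Meuwissen–Luo inbreeding coefficients enter the
  Mendelian-sampling variances by default; the source of our pedigrees
  (simulated or field) rarely makes this matter, but deep pedigrees need
  it and a flag turns it off for comparability with software that ignores
  inbreeding.
* `a_submatrix()` returns the relationship block $A_{22}$ among a subset,
  by the tabular method on the ancestor closure for small problems and by
  solving the sparse $A^{-1}$ for the subset's unit vectors (Colleau's
  indirect method) for large ones; the two routes agree to machine
  precision and are cross-checked in the test suite.
* `vanraden_g()` builds $G = ZDZ'/\lambda$ from centered gene content
  $Z$ (counts minus $2p_j$, missing genotypes mean-imputed), diagonal SNP
  weights $D$ and $\lambda = \sum_j 2p_j(1-p_j)$. Allele frequencies are
  the observed ones unless supplied. Note that with observed frequencies
  $G$ is singular by construction ($G\mathbf{1}=0$), which is why the
  single-step system uses a blended matrix:
* `blend_and_invert()` first (optionally) rescales $G$ so its mean
  diagonal and mean off-diagonal match $A_{22}$, then blends
  $G_b = 0.95\,G_t + 0.05\,A_{22}$ and inverts. The default 0.95/0.05 is
  the standard stabilisation; lowering the genomic share is the remedy the
  error message suggests when $G_b$ is not positive definite.
* `h_inverse()` forms
  $H^{-1} = A^{-1} + \begin{bmatrix}0&0\\0&G^{-1}-A_{22}^{-1}\end{bmatrix}$
  on the genotyped block, the single-step combination of all pedigree,
  phenotype and marker information.

### Genotype editing

`qc_filter()` applies the usual editing rules in a fixed order: animals
with call rate below 0.95 first, then SNPs with minor allele frequency
below 0.01, Hardy–Weinberg deviation at $p<10^{-6}$ (a deterministic 1-df
chi-square on genotype counts; at this threshold the choice between the
chi-square and the exact test is immaterial), call rate below 0.99, or
fewer than 30 animals in either homozygote class. The editing thresholds
are those routinely used for GBS-derived pig genotypes. The "individual
call rate" rule is phrased ambiguously in common protocols (SNP-wise vs
animal-wise); we implement it as the animal-level filter, which is the
conventional reading.

## Variance components: EM-REML with AI acceleration

`em_reml()` iterates the expectation–maximisation REML updates built from
MME solutions and exact traces of the inverted coefficient matrix
(computed chunk-wise through the sparse factor, never by dense inversion of
the full system). Plain EM is robust and monotone in the restricted
likelihood but slow — hundreds of iterations for low-heritability traits —
so each iteration first proposes an average-information (AI) step using
the score vector derived from the same traces; the step is accepted only
if it stays in the parameter space (small positive floor, so the boundary
$\sigma_a^2 \to 0$ remains reachable) and does not decrease the restricted
likelihood, otherwise the EM update is taken. The accepted sequence is
therefore non-decreasing in likelihood by construction, which the test
suite asserts per iteration, and convergence typically takes fewer than
15 iterations. Standard errors come from the inverse AI matrix at
convergence; ratios ($h^2$, repeatability, $r_g$) get delta-method errors.
All the MME-based identities (restricted likelihood, trace formulas,
scores, AI quadratic forms) are verified against dense matrix oracles on
small instances in the tests.

The bivariate model stacks two traits with unstructured $2\times2$
genetic, permanent-environment and residual covariance matrices on the
covariance scale, restricted to records where both traits are observed.
EM updates keep the covariance matrices PSD by construction; AI steps over
the nine parameters use step-halving under the same likelihood guard, and
a defensive nearest-PSD projection is applied (and flagged) if numerics
ever produce an indefinite proposal. Genetic correlations are classified
with the conventional magnitude bands (very high $|r|\ge0.80$; high
$0.40\le|r|<0.80$; low $0.2<|r|<0.40$; very low below); the boundary
values 0.2 and 0.40 are assigned to "very low" and "high" respectively —
the published band definitions leave the two boundaries ambiguous, so the
package fixes them as documented constants.

## Expected accuracy and cross-validation

The expected accuracy of a (G)EBV is
$R_g = \sqrt{1 - \mathrm{PEV}/\sigma_a^2}$, clipped at zero when shrinkage
leaves PEV above $\sigma_a^2$. The accuracy literature this quantity comes
from defines it with the square root; a printed formula without the
radical circulates, so `accuracy_from_pev(..., sqrt = FALSE)` exposes the
reliability-style reading behind a flag. `kfold_cv()` partitions the
phenotyped animals (not records) into k folds so a sow's repeated records
move together and permanent-environment information cannot leak, masks
each fold's records, re-solves the MME with the variance components held
at their full-data estimates (components are not re-estimated per fold;
folds stay comparable and the convention matches routine evaluation), and
averages validation animals' $R_g$ per fold. Accuracies are averaged over
validation animals only, optionally restricted to a subset such as the
genotyped core — the natural group when comparing pedigree BLUP with
ssGBLUP.

## Weighted single-step GWAS

`run_weighted_ssgwas()` implements the iterative loop: start at $D = I$;
build $G^* = ZDZ'/\lambda$ (blended and tuned as above for the MME); solve
the single-step system for GEBV; back-solve SNP effects
$\hat u = DZ'G^{-1}\hat a_g/\lambda$; derive weights
$d_j = \hat u_j^2\, 2p_j(1-p_j)$; renormalise so
$\sum_j d_j 2p_j(1-p_j)$ is constant (total represented genetic variance
unchanged); rebuild $G^*$ and repeat. For an unblended, invertible $G$ the
back-solve satisfies $Z\hat u = \hat a_g$ exactly — an identity the tests
enforce at $10^{-8}$ — while production runs use the blended inverse,
whose deviation from the identity is bounded by the blend. The loop as
published has no stopping rule; two iterations is the point at which
weighted ssGWAS results are conventionally read, so `n_iterations = 2` is
the default and the argument is exposed.

Windows are SNP-anchored and span a fixed 0.3 Mb of physical map — the
distance to which linkage disequilibrium ($r^2 = 0.2$) extends in the
population this pipeline targets — rather than a fixed SNP count, so
overlapping windows with varying SNP numbers are all evaluated. A
window's share of genetic variance is the empirical variance across
genotyped animals of $\sum_{j \in \text{win}} Z_j\hat u_j$, divided by the
REML additive variance of the same run. Windows above 1% are candidate
regions; overlapping selected windows merge into one region reported with
the anchor of its maximal window as top SNP ("the" top SNP is not
operationally defined in the method description we follow; the
maximal-window anchor is our interpretation and is flagged as such).
`map_candidate_genes()` assigns genes whose interval lies strictly less
than 0.3 Mb from a region's top SNP, using `GenomicRanges` distances.

## The synthetic-data generator

Because the phenotypes that motivated this pipeline are proprietary, every
stage is exercised on simulated data whose defaults mirror the published
population structure:

* **Pedigree** — discrete generations, random sire/dam draws from the
  previous generation; females of the last two generations carry records
  (about 2.7 parities per sow, 36% with a single litter); a seeded subset
  of those sows is genotyped, mimicking a nucleus-herd scheme of roughly
  2,000 genotyped among tens of thousands with records.
* **Genotypes** — founder haplotypes are thresholded Gaussian AR
  processes along each chromosome, giving LD that decays with distance;
  the correlation length (default 0.7 Mb) is calibrated so marker $r^2$
  at 0.3 Mb is near 0.2. Descendants arise by gene dropping with Haldane
  recombination at 1 cM/Mb.
* **Traits** — six litter traits (TNB, NSB, MUMM, NWB, NDF, LBWT) are
  simulated directly on a latent Gaussian scale with means, phenotypic
  variances, heritabilities (0.01–0.06), repeatabilities (0.02–0.14) and
  genetic correlations set to the published estimates; breeding values are
  a causal-marker part (default 30% of $\sigma_a^2$) plus a
  pedigree-polygenic part, permanent-environment and residual effects
  share the genetic correlation structure by default, and records are
  rounded/truncated counts (LBWT continuous). The composition traits NBA,
  NHB and rNHB are **derived** so that TNB = NBA + NSB + MUMM and
  NBA = NHB + NWB + NDF hold in every record — consequently their
  heritabilities are emergent rather than targeted; the directly simulated
  traits hit their targets. The record identities are preserved through
  editing: capping TNB at 22 removes the excess from the largest
  components first and recomputes the derived columns.
* **Editing** — litters with TNB of 3 or fewer are removed, TNB of 22 or
  more is capped at 22, parities above 8 are coded 8 ("records of 8 pairs
  or more" is ambiguous between a parity cap and a record-count cap; it is
  implemented as a parity cap and flagged here). An editing report counts
  every rule.

What the generator does **not** emulate: genotyping-by-sequencing read
data and imputation error, selection across generations, maternal effects,
and the heavy zero-inflation of the rarest count traits (latent Gaussians
rounded to counts approximate, but do not reproduce, their extreme
skewness). Passing tests on these simulations therefore demonstrate the
estimators' internal correctness and their behaviour under the stated
genetic architecture — not robustness to every feature of field data.

Mendelian-sampling variances in the trait simulator ignore parental
inbreeding (generation depth is small and matings random, so $F$ is near
zero); the analysis-side $A^{-1}$ does account for it.

## Numerical choices and problem sizes

* MME are factorised once per solve with CHOLMOD (supernodal, permuted);
  singular systems raise an error naming the cause rather than silently
  regularising.
* REML convergence is declared at a relative parameter change below
  `tol` (default $10^{-6}$ univariate, $10^{-5}$ bivariate); hitting
  `max_iter` warns and returns the last iterate flagged as not converged.
* The univariate parameter-recovery checks run at 5,000 sows with four
  parities each (20,000 records, ~10,600 equations); the bivariate check
  at 800 sows; the BLUP-vs-ssGBLUP cross-validation contrast at 20,000
  pedigree animals with a 2,000-sow genotyped core, ten replicate
  populations; the weighted-GWAS signal checks at 800 genotyped sows with
  one QTL at 20% of $\sigma_a^2$. These sizes are the package's choice of
  scaled-down study conditions: large enough for the stochastic
  assertions' 3-standard-error bands, small enough to run routinely.
* In null (no-QTL) populations the quadratic reweighting amplifies the
  largest noise window by a factor of roughly five between iterations one
  and two; the tests therefore bound per-population amplification (below
  three times the iteration-one maximum) and check that the top window's
  location is not reproducible across populations, rather than asserting
  an absolute ceiling.

## Configuration and orchestration

`run_pipeline()` executes qc → reml → blup/ssgblup → cv → ssgwas from a
`run_config()`, validating stage dependencies before any computation and
writing per-stage TSVs plus a manifest with md5 checksums; with a fixed
seed the manifest checksums are reproducible. Run configurations can be
read from a small TOML subset (`read_toml()`), implemented in-package.
The package deliberately ships no shell executable: the exported functions,
`run_pipeline()` and this vignette are the interface, in the style of the
modelling packages this one follows.
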