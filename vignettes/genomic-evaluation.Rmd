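---
title: "Genomic evaluation for family-based oyster breeding: models and methods"
author: "oysterGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic evaluation for family-based oyster breeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Quality traits of farmed oysters — meat yield (soft tissue weight, condition
index), shell shape (cup and fan ratios) and shell/mantle color — can only be
measured after slaughter, so conventional selection must rely on sib
information and progresses slowly. Genomic selection replaces the pedigree
expectation of relatedness with relationships realized in dense SNP
genotypes, capturing within-family Mendelian sampling that is invisible to a
pedigree. `oysterGS` implements the full evaluation workflow for a
two-generation full-sib breeding population of the Portuguese oyster
(*Crassostrea angulata*): genotype quality control, genomic and pedigree
relationship matrices, restricted-maximum-likelihood variance components,
GBLUP prediction with cross-validated accuracy, and population-structure
diagnostics — together with a synthetic data generator that reproduces the
study's family design with *known* variance components, so every estimator in
the package can be checked against ground truth.

## The animal model and AI-REML

The univariate animal model is

$$ y = X\beta + g + e, \qquad
   g \sim N(0, K\sigma^2_a), \quad e \sim N(0, I\sigma^2_e), $$

where $K$ is either the VanRaden genomic relationship matrix
$G = MM'/\sum_j 2 p_j q_j$ (with $M$ the genotype matrix column-centered by
$2p_j$), the per-marker standardized (GCTA-style) matrix, or the pedigree
numerator relationship matrix $A$ computed by the tabular recursion.
Heritability is $h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_e)$.

`reml_univariate()` maximizes the restricted likelihood by
average-information (AI) updates. The implementation rotates the model by the
eigenvectors of $K$ (restricted to the phenotyped samples), after which the
covariance is diagonal and each iteration costs $O(n p^2)$ — one
eigendecomposition up front, then essentially free iterations. Every AI
proposal is checked against the likelihood; proposals that leave the
parameter space or decrease the likelihood are step-halved and, failing
that, replaced by an EM step, which provably never decreases the restricted
likelihood. Numerical choices:

* **Start values**: half the (fixed-effects-adjusted) phenotypic variance
  for each component.
* **Floors**: variances are constrained to at least $10^{-6}\,\mathrm{var}(y)$;
  hitting the floor sets a `boundary` flag.
* **Convergence**: $|\Delta \log L| < 10^{-6}$ and relative parameter change
  $< 10^{-5}$, at most 100 iterations. Non-convergence is flagged, never
  silent.
* **Identifiability**: if $K$ has (numerically) constant eigenvalues — e.g.
  $K = I$ — the genetic and residual variances are not separately
  identifiable; the fit warns and flags this rather than failing.
* **Standard errors** come from the inverse of the final AI matrix, with the
  delta method for $h^2$ (and $r_g$ in the bivariate model). A calibration
  test in the suite verifies ~95% coverage of $\hat h^2 \pm 1.96\,SE$ over
  100 simulated replicates.

### Bivariate model

`reml_bivariate()` fits two traits with genetic covariance
$\Sigma_a \otimes K$ and residual covariance $\Sigma_e \otimes I$; the
genetic correlation is $r_g = \sigma_{a12}/\sqrt{\sigma^2_{a1}\sigma^2_{a2}}$.
Two code paths compute the same likelihood:

* a **rotated path** used when both traits are recorded on exactly the same
  samples — after the eigen-rotation of $K$ the covariance is block-diagonal
  in $2\times2$ blocks and iterations are $O(n)$;
* a **dense path** for overlapping-but-unequal sample sets, which builds the
  full record covariance. Records observed for only one trait contribute
  only their own-trait residual (the standard missing-at-random treatment);
  the residual covariance is informed only by animals recorded for both
  traits, and is held at zero if fewer than three such animals exist.

The two paths agree to $10^{-6}$ on complete records (regression-tested).
A $\Sigma_a$ (or $\Sigma_e$) update outside the positive-definite cone is
projected back by capping the covariance at $0.999$ of its bound; estimated
correlations are reported clamped to $[-1, 1]$.

## GBLUP, allele substitution effects, cross-validation

`solve_mme()` solves Henderson's mixed-model equations with
$\lambda = \sigma^2_e/\sigma^2_a$ and returns genetic values for every
individual in $K$, including unphenotyped ones — that is how held-out
animals are predicted. If $K$'s smallest eigenvalue falls below $10^{-8}$
(sample-frequency centering always makes $G$ rank-deficient by one), a
$10^{-6}$ diagonal bump is added before inversion and reported.

`backsolve_ase()` converts genetic values to per-marker allele substitution
effects, $\hat\alpha = M' G^{-} \hat g / \sum 2pq$, using the eigenvalue
pseudo-inverse $G^{-}$ rather than a bent inverse: BLUP genetic values lie in
the column space of $M$ by construction, so the pseudo-inverse reconstructs
$M\hat\alpha = \hat g$ to machine precision where a bent inverse would leave
an error of the order of the bend. Phenotypes are then predicted as
$\hat y = X\hat\beta + M\hat\alpha$, with $M$ centered at the **training**
allele frequencies.

`cross_validate()` runs replicated k-fold cross-validation (default fivefold
with five replicates). Within each fold the variance components are
re-estimated on the training records only — the conservative choice that
avoids information leakage through $\lambda$. Held-out individuals keep
their genotypes in $G$ (phenotypes masked), the natural setting for
selection candidates that are genotyped but unmeasured; a
`strict_exclusion` option instead removes them from $G$ entirely and
predicts through allele substitution effects. Predictive ability is the
coefficient of determination $R^2$ of the regression of observed on
predicted phenotypes, pooled within a replicate and averaged across
replicates; the best single replicate and the Pearson correlation are also
reported, but the mean is the headline number — selecting the best fold
overstates accuracy. Folds are sample-random by default; `stratify_by` a
family label assigns whole families to folds, which removes the optimism
that full-sib structure lends to random folds.

## The synthetic data generator

`sim_config()` defaults encode the study population: 57 generation-1
full-sib families of 2–8 offspring from unrelated founder pairs, 33
generation-2 families of 12–15 offspring whose parents are generation-1
individuals from distinct families (each used at most once), and 13,048
biallelic SNPs. Founder allele frequencies are Uniform(0.05, 0.5) —
the site-frequency spectrum of the real DArTSeq panel is not published — and
genotypes descend by gene dropping: founders are Hardy–Weinberg draws,
offspring receive one allele per parent per locus, independently across loci.

Phenotypes follow the GBLUP generative model exactly: marker effects are
i.i.d. normal across markers (correlated across traits through the
configured genetic correlation matrix), and each trait's true breeding
values $g = M\alpha$ are rescaled so their realized variance equals
$h^2\sigma_p^2$ exactly, which makes parameter-recovery tests sharp.
Residuals carry a configurable residual correlation (default 0.30 between
trait pairs, a plausible mid-range value; the study does not publish
residual correlations). Fixed effects — generation, sex, their interaction,
and an age slope nested within generation — default to modest fractions of
$\sigma_p$ (25%, 10%, 5%, and 2% per day respectively) and are centered so
the configured trait mean is the marginal population mean, as phenotypic
summary tables report it. Sex is Bernoulli(0.5) and age is Normal(270, 15)
days, matching a nine-month grow-out. Default traits are whole weight
(h² 0.45, mean 51.07 g, SD 16.13 g) and soft tissue weight (h² 0.43, mean
9.55 g, SD 3.13 g, 24% missing to match its lower record count), with a
genetic correlation of 0.63.

**What the generator does not emulate.** Markers are unlinked: there is no
LD, no shared restriction-site tags, and no genotyping error or missingness
in the simulated calls (QC behavior is tested on constructed matrices
instead). Real DArTSeq data have strong local LD and far fewer independent
segments, which is why published cross-validated accuracies (0.38–0.92)
exceed what unlinked markers can deliver at this sample size — the package's
simulated CV accuracies are correspondingly lower, and tests assert the
*direction* (GBLUP above pedigree BLUP, predictive $R^2$ bounded by $h^2$
plus noise) rather than the published magnitudes. There is also no selection
or mortality between generations, and no major-gene architecture (the
equal-variance marker model is exactly the GBLUP assumption). Nucleotide
diversity of the synthetic panel is on the per-SNP-site scale (~0.29 with
the default frequency law); the study's per-tag-base value (0.009) depends
on the unpublished tag-length denominator, which `nucleotide_diversity()`
exposes via `tag_length`.

## Genotype QC and formats

The study's QC is a 50% call-rate filter (retained when the fraction of
non-missing calls is **at least** 0.5 — the boundary is kept inclusive, the
printed rule does not specify strictness) followed by mean imputation
(missing calls replaced by the per-marker mean of observed calls, a real
number in [0, 2]). No MAF or HWE filter is applied, matching the published
pipeline. Imputation preserves marker means, so allele frequencies are
identical before and after — a regression-tested invariant. The call-rate
rule is per-marker (this is what reproduces a marker-count reduction);
per-sample filtering is available behind a flag. Genotypes read and write as
CSV matrices (sample id first column) and as GT-only VCF 4.2 with synthetic
`tag<k>` contigs, since DArT tags are unplaced; VCF carries only hard calls,
so imputed matrices refuse serialization.

## Population structure

Pairwise divergence is the allele-sharing distance (mean over shared markers
of $|x_i - x_j|/2$; a count scale is available), nucleotide diversity the
average pairwise divergence, and the neighbor-joining tree is the standard
Saitou–Nei construction with negative branch lengths clamped to zero and the
deficit moved to the sister branch (path lengths preserved). The fixation
index is computed from diversity partitioning,
$F_{ST} = (\pi_T - \pi_S)/\pi_T$ with $\pi_S$ the size-weighted mean
within-cluster diversity, clamped to $[0, 1]$: under the pairwise-average
definition an *arbitrary* partition of a homogeneous sample can make the raw
difference marginally negative by sampling noise (the gene-diversity
formulation is what guarantees non-negativity), so the clamp is part of the
definition here. Cluster labels can come from any assignment; the automatic
choice cuts the three longest internal branches of the NJ tree into four
groups, mirroring the four-cluster structure reported for the study
population. For structure analyses the package selects one individual per
full-sib family (`select_unrelated()`), the sibling-exclusion used in the
study, and bins whole weight into the reported market categories
(I: 30–40 g … V: >70 g, left-closed; weights below 30 g are left unbinned
rather than guessed into category I).

## Problem sizes used in the checks

The test suite simulates the full two-generation family design at a
2,000-marker panel (roughly 730 measured animals) for parameter-recovery
checks — 20 replicates each for the univariate ($h^2 = 0.45$) and bivariate
($r_g = 0.63$) models — and smaller single-generation designs (50–100
families) for oracle comparisons, coverage calibration and cross-validation,
which keeps the whole suite within a few minutes without diluting the
checks. The same sizes are used by `scripts/acceptance.R`, which recomputes
the headline quantities from scratch at a user-supplied seed.

## Known limitations

* No multivariate REML beyond two traits, no dominance or epistatic
  variance, no Bayesian whole-genome regression, and no single-step
  (H-matrix) blending — genomic and pedigree evaluations are compared
  separately, as in the study.
* The AI-REML likelihood is evaluated through dense eigendecompositions;
  this is the right trade-off at $n \approx 650$ but would need sparse or
  low-rank methods beyond $n \sim 10^4$.
* Bivariate fits with very few doubly-recorded animals cannot estimate the
  residual covariance; it is then fixed at zero rather than guessed.
* The simulator's unlinked markers understate the accuracy a real linked
  panel achieves from family LD, as discussed above.
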