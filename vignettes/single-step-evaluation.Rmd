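---
title: "Single-step genomic evaluation for family-structured breeding programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation for family-structured breeding programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The evaluation model

StepBLUP implements genomic evaluation for aquaculture breeding programs in
which large full-sib families are reared separately in tanks until tagging
and then stocked communally in ponds. The single-trait animal model is

$$ \mathbf{y} = \mathbf{Xb} + \mathbf{Zu} + \mathbf{Wp} + \mathbf{e}, $$

where $\mathbf{b}$ holds the fixed effects, $\mathbf{u}$ the additive
genetic effects of *all* pedigree animals (phenotyped or not), and
$\mathbf{p}$ a common-environment effect with one independent level per
full-sib spawn — it absorbs the shared tank environment that would
otherwise masquerade as additive family variance. For harvest weight the
fixed structure is the year-sex-pond interaction plus age as a linear
covariate nested within sex; for carcass weight it is the year-sex-pond
interaction plus body weight nested within year-sex. Fitting carcass weight
with the body-weight covariate (rather than pre-computing a residual trait)
identifies fish with a high saleable-carcass proportion at a given size;
the trait is therefore referred to as residual carcass weight.

Pedigree BLUP uses $\mathrm{Var}(\mathbf{u}) = \mathbf{A}\sigma^2_u$ with
$\mathbf{A}$ the numerator relationship matrix. Single-step GBLUP
(ssGBLUP) replaces $\mathbf{A}^{-1}$ in the mixed-model equations with

$$ \mathbf{H}^{-1} = \mathbf{A}^{-1} +
   \begin{bmatrix} 0 & 0 \\ 0 & \mathbf{G}^{-1} - \mathbf{A}_{22}^{-1}
   \end{bmatrix}, $$

so that genotyped and ungenotyped animals are evaluated jointly. The
genomic relationship matrix is VanRaden's
$\mathbf{G} = \mathbf{MDM}' / (2\sum_j p_j(1-p_j))$ with $\mathbf{M}$ the
dosage matrix centered by twice the current (sample) allele frequencies
and $\mathbf{D}$ a diagonal SNP-weight matrix, the identity by default.
$\mathbf{G}$ is blended with 5% of $\mathbf{A}_{22}$ before inversion to
guarantee positive definiteness; with the sample allele frequencies the
unblended $\mathbf{G}$ is always singular (the centering puts the unit
vector in its null space), so blending is not optional in production.

`computeInbreeding()` uses the Meuwissen–Luo recursion, so inbreeding and
the sparse $\mathbf{A}^{-1}$ (Henderson's rules with Mendelian-sampling
variances $d_i = 0.5 - 0.25(F_s + F_d)$) scale to full pedigrees;
`tabularA()` is retained as a dense test-scale oracle, and `extractA22()`
prunes to the genotyped animals' ancestors before going dense.

## Solving and variance components

The mixed-model equations are solved by sparse Cholesky factorization up
to 5 000 equations and by Jacobi-preconditioned conjugate gradients above
that, to a relative residual of $10^{-8}$. Identifiability of the fixed
effects is enforced by QR-dropping redundant columns (reference-level
coding).

Variance components are estimated by EM-REML. Each round solves the
current equations and updates
$\sigma^2_u = (\hat{u}'\mathbf{K}^{-1}\hat{u} +
\mathrm{tr}(\mathbf{K}^{-1}\mathbf{C}^{uu})\sigma^2_e)/q_u$ (and
analogously for the spawn variance), with the inverse-coefficient-matrix
traces computed through the sparse Cholesky factor rather than a dense
inverse. Plain EM steps increase the restricted likelihood monotonically
but converge geometrically slowly; by default the implementation applies
Aitken extrapolation along the EM trajectory every fourth round, which
cuts rounds by roughly an order of magnitude and is disabled by
`accelerate = FALSE` when the textbook monotone sequence is wanted (the
test suite asserts monotonicity on the plain sequence). Components
collapsing below $10^{-8}$ of the total are pinned at that boundary and
flagged. A fixed-variance mode (components supplied directly) mirrors
routine evaluation runs.

One caution from the simulation work: with a *single* unrelated
year-class, the between-family variance ($\sigma^2_u/2 + \sigma^2_p$) and
within-family variance ($\sigma^2_u/2 + \sigma^2_e$) are the only two
observable strata, so the three components are not separately
identifiable. Heritability recovery therefore requires (and the tests
use) at least two year-classes, whose cross-family parent relationships
break the confounding — as they do in the real multi-year program.

## Validation designs and scoring

`runValidation()` implements four training/validation designs: (1)
replicated random k-fold cross-validation over genotyped phenotyped
animals; (2) halving every genotyped full-sib family into training and
validation (odd member to training); (3) as 2, but only half of the
genotyped training sibs keep phenotypes; (4) as 2, but phenotypes are
removed from *all* genotyped animals, so information reaches the
candidates only because $\mathbf{H}$ connects them to ungenotyped
phenotyped relatives. Strategies 3 and 4 reuse strategy 2's validation
set. Predictive ability is the Pearson correlation between (G)EBV and
adjusted phenotypes of the validation animals; the inflation slope $b_1$
is the OLS regression of adjusted phenotypes on (G)EBV, with $b_1 < 1$
indicating over-dispersed predictions.

The adjusted phenotypes deserve a design note. The literal form
$y^* = y - \mathbf{X}\hat{\mathbf{b}}_{\text{full}}$ (fixed effects from
the full-data fit; available as `adjustedPhenotypes()` and
`adjust = "fixed"`) retains the spawn effect. Because validation full
sibs share their spawn with training sibs, that retained effect leaks
into the score: it rewards family-mean-driven (pedigree) predictions more
per unit of prediction s.d. than genomic ones, and it pushes $b_1$ for
*any* family-based prediction well above 1. Under such scoring the
inflation slope could never sit near or below 1 the way routinely
reported evaluations do, and the genomic-versus-pedigree comparison is
distorted in the pedigree method's favor even when genomic predictions
track true breeding values much better. `runValidation()` therefore
defaults to `adjust = "nongenetic"`: $y^*$ removes all non-genetic model
effects estimated from the full data — fixed effects and the spawn
effect — so both metrics measure alignment with genetic merit. The two
choices coincide whenever the model has no common-environment term.

Re-estimating variance components per training set (`vcMode =
"reestimate"`) changes $b_1$ but leaves predictive ability essentially
unchanged; the package asserts agreement to 0.01, the precision at which
such results are reported. Exact invariance would require $\hat{u}$ to be
a fixed vector rescaled, which is not literally true as the variance
ratio moves, but the departure is far below reporting precision.

Calibration ($b_1 \approx 1$) is asserted on data generated exactly under
the fitted model — breeding values drawn from
$N(0, \sigma^2_u \mathbf{H})$ with the same $\mathbf{H}$ used in the fit,
true components, and no shared-environment leakage — because that is the
setting in which BLUP theory guarantees
$\mathrm{cov}(u, \hat{u}) = \mathrm{var}(\hat{u})$. Each calibration
replicate redraws the trait, since replicates on a single draw share its
dataset-level sampling error.

## Weighted ssGBLUP association scans

SNP effects are back-solved from genomic breeding values as
$\hat{\mathbf{a}} = \mathbf{D}\mathbf{M}'\mathbf{G}^{-1}\hat{\mathbf{u}} /
(2\sum_j p_j(1-p_j))$. Weights follow VanRaden's nonlinear-A scheme,
$d_j = 1.125^{\min(|\hat{a}_j|/sd(\hat{a}) - 2,\; 5)}$: the exponent cap
bounds every weight at $1.125^5 \approx 1.802$, which is what keeps the
iteration stable under polygenic architectures (linear $\hat a^2 2pq$
weights, which diverge there, are deliberately not the production
scheme). `wssgblup()` runs five weight iterations by default, records
held-out predictive ability and inflation per iteration, and selects the
iteration with the highest predictive ability (ties broken by least
inflation). Variance is attributed to non-overlapping windows of 20
adjacent SNPs within chromosomes (trailing shorter window kept) under the
independent-locus approximation $\sum_w 2p_j(1-p_j)\hat{a}_j^2$,
normalized so all windows sum to 100% — LD covariance between SNPs is
ignored, so window percentages are comparative, not partitions of the
REML variance. Production back-solving uses the blended $\mathbf{G}$; the
exact reconstruction identity $\mathbf{M}\hat{\mathbf{a}} =
\hat{\mathbf{u}}$ is asserted in tests with an unblended, invertible
$\mathbf{G}$ (reference frequencies distinct from the sample mean).

## Linkage disequilibrium and effective population size

Genotypes are unphased, so LD uses the composite (Burrows) disequilibrium
$\hat{D} = \mathrm{cov}(g_A, g_B)/2$. The denominator uses the
Hill-corrected composite form $(\mathrm{var}(g_A)/2)(\mathrm{var}(g_B)/2)$
— equivalently, $r^2$ is the squared dosage correlation — which equals
the haplotype-based $D^2/(P_A P_a P_B P_b)$ exactly under Hardy–Weinberg
proportions and, unlike the raw HWE denominator, keeps $r^2 \in [0, 1]$
for any input (a duplicated SNP always scores 1). Distances convert from
bp at a fixed 1 cM/Mb (configurable).

Per chromosome, `fitSvedDecay()` fits $E[r^2] = 1/(1 + 4 N_e d)$ by
nonlinear least squares (falling back to the closed form on
non-convergence), and `neFromMeanR2()` evaluates
$N_e = (4d_t)^{-1}[(r^2_t - 1/N)^{-1} - \alpha]$ with the sample-size
correction $1/N$ and $\alpha = 2$ (mutation accounted for). For $d_t$,
`neFromLd()` uses the mean distance of the SNP pairs that produced
$r^2_t$ — using a whole-chromosome length together with adjacent-pair
$r^2$ would bias $N_e$ by roughly the SNP count per chromosome — and
aggregates chromosomes by unweighted mean (length-weighted available).
Adjacent pairs feed the summary statistics; `pairwiseR2()` provides the
longer-range pairs needed for decay curves.

## The gene-drop simulator

`simulateDataset()` produces the synthetic study system: unrelated base
broodfish, one full-sib family per sire-dam pair (no full-sib matings, at
most 10% of broodstock from one family), ~30 tagged offspring per family
per year-class, two traits with heritabilities 0.27 and 0.34, a genetic
correlation of 0.5 (configurable; no value is established for this
population), a common-environment fraction of 0.15 shared per spawn, and
partial genotyping (10% by default). Meioses follow Haldane's model:
Poisson crossovers with mean equal to the chromosome length in Morgan at
uniform positions. Founder haplotypes are sampled from a small ancestral
population (effective size 30, forty generations of random mating) so
that markers carry the long-range LD characteristic of the study
population's small $N_e \approx 27$; with linkage-equilibrium founders
(`founderNe = 0`) markers would only capture family co-segregation.
True breeding values are sums of QTL dosages times Gaussian effects,
rescaled so the realized additive variance hits its target exactly; an
optional planted QTL carries 20% of the additive variance for
association-scan tests. Broodstock selection defaults to random:
index selection is available (`selection = TRUE`), but calibration
properties are only interpretable on an unselected base, and the
footprint of a selected population (reduced variance, drifted
frequencies) is not needed by any downstream test.

What the simulator does *not* emulate: genotyping error and missingness
mechanisms (missing calls must be planted explicitly), non-additive
genetic effects, genotype-by-environment interaction, overlapping
generations within a spawning season, and mortality/culling between
tagging and harvest. Passing tests on this generator therefore
demonstrate internal consistency of the estimators under an additive,
randomly mating, cleanly recorded world — not robustness to those
real-data complications.

## Problem sizes and numerical choices

The test suite runs at desk scale, chosen as the smallest sizes at which
each property is identifiable: relationship-oracle checks on pedigrees up
to n = 300; heritability recovery on 2 year-classes x 50 families x 20
offspring (2 000 records, 10 seeds); the genomic-versus-pedigree
comparison on 100 families x 30 offspring with 40% genotyped at 2 000
SNPs (10 seeds); calibration on 40 families x 20 with 50% genotyped at
800 SNPs (20 trait draws); the planted-QTL scan on 60 families x 20 with
70% genotyped at 500 SNPs; drift-based $N_e$ on 10 replicates of a
30-animal, 20-generation population with 400 SNPs on 10 chromosomes
(adjacent spacing 0.025 Morgan, so 20 generations suffice for LD at that
scale to reflect the contemporary size). Master seeds derive per stage
and replicate through `deriveSeed()`, a documented linear-congruential
mix, so every table is reproducible from one integer and seeds stay
below $2^{31}$.

Other defaults: solver tolerance $10^{-8}$ (relative residual of the
normal equations); EM-REML tolerance $10^{-6}$ on the maximum relative
component change with at most 500 rounds; QC thresholds exactly as
printed in the field's convention — SNPs removed when MAF *strictly*
below 0.05, monomorphic, or call rate strictly below 90%, animals removed
when call rate strictly below 90%, animals filtered before SNP
statistics, frequencies recomputed on the surviving sample, and remaining
missing dosages mean-imputed to $2p_j$ before centering.

## Known limitations

Single-trait models only (the two-trait selection index combines
standardized single-trait EBV); no dominance or epistasis; reliabilities
are not computed beyond the test-scale dense inverse; the GEBV
decomposition into parent-average, genomic and subtraction terms is
limited to the parent-average component, since the decomposition weights
are population-dependent quantities not derivable here. The EM-REML path
requires the coefficient-matrix trace machinery and is intended for up to
a few thousand equations; production-scale variance components should be
estimated once at that scale and then fixed.
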