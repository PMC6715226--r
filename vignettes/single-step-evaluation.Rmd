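---
title: "Single-step genomic evaluation for partially genotyped breeding populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation for partially genotyped breeding populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssgblup)
```

## The problem

Fruit-tree breeding programs accumulate phenotypes over decades — fruit
weight, sugar content, acidity, recorded once to a few times per tree —
but only a small, recent slice of the population is ever genotyped.
Classical pedigree BLUP (ABLUP) uses all phenotypes but only *expected*
relationships; genomic BLUP (GBLUP) uses *realized* marker
relationships but discards every record from an ungenotyped tree.
Single-step GBLUP (ssGBLUP) joins the two sources in one evaluation, so
that genomic information propagates through the pedigree to
non-genotyped relatives and non-genotyped records sharpen the
prediction of genotyped selection candidates.

This package implements that evaluation as a set of composable pieces:
pedigree handling and the numerator relationship matrix $A$; SNP
quality control and the genomic relationship matrix $G$; the combined
matrix $H$ and its tunable inverse; exact REML for the variance
components; BLUP prediction; and the two leave-one-family-out
cross-validation (CV) schemes used to measure prediction accuracy in
genotyped and non-genotyped material. A gene-dropping simulator
generates populations with the same structure, so every stage is
testable end to end without access to confidential breeding data.

## The model

All evaluations fit the same linear mixed model per trait,

$$\mathbf{y} = \mathbf{Xb} + \mathbf{Zu} + \mathbf{e},$$

where $\mathbf{y}$ are the phenotypic records (repeated across harvest
years), $\mathbf{b}$ holds an intercept and year effects,
$\mathbf{Z}$ maps records to individuals,
$\mathbf{u} \sim N(0, \mathbf{K}\sigma^2_u)$ are breeding values and
$\mathbf{e} \sim N(0, \mathbf{I}\sigma^2_e)$. The three evaluations
differ only in the kernel $\mathbf{K}$: $A$ (ABLUP), a blended genomic
matrix (GBLUP) or $H$ (ssGBLUP). Given the variance ratio
$\lambda = \sigma^2_e/\sigma^2_u$, the predictor is

$$\hat{\mathbf{u}} = (\mathbf{Z}'\mathbf{M}\mathbf{Z} +
  \lambda\mathbf{K}^{-1})^{-1}\mathbf{Z}'\mathbf{M}\mathbf{y},
  \qquad \mathbf{M} = \mathbf{I} -
  \mathbf{X}(\mathbf{X}'\mathbf{X})^{-1}\mathbf{X}',$$

which the package evaluates both literally (`solve_blup_direct()`) and
through Henderson's mixed-model equations (`solve_blup_mme()`); the
two routes are algebraically identical and are cross-checked against
each other in the test suite rather than trusted individually.
*Genotypic values*, the quantities compared in the CV schemes, are the
intercept plus the breeding value.

There is deliberately **no** permanent-environment effect for the
repeated records: the model carries a single residual term, exactly as
the evaluation is written above. Year is the only fixed effect besides
the intercept, coded with the first year as reference level; genotypic
values are invariant to that coding choice. Each trait is analysed
separately.

## Relationship matrices

**Pedigree.** `build_A()` uses the recursive tabular method including
inbreeding ($a_{ii} = 1 + \tfrac12 a_{s_i d_i}$), and
`build_A_inverse()` assembles $A^{-1}$ directly by Henderson's rules
with Quaas' inbreeding correction, taking the Mendelian-sampling
variance $d_i = \tfrac12 - \tfrac14(F_s + F_d)$ from the tabular
inbreeding coefficients, so the two functions are exact inverses of
each other. Inbreeding is always accounted for: the $H$-matrix
identities below only hold with the true $A$. Unknown parents are
treated as unrelated, non-inbred founders of a single base population
(no genetic groups), and individuals appearing only as parents are
auto-registered as founders, because parental cultivars are part of
the evaluated population.

**Genomic.** `build_G()` implements VanRaden's first method,
$G = ZZ'/(2\sum_j p_j(1-p_j))$ with genotypes column-centred at
$2p_j$. Allele frequencies are observed frequencies in the genotyped
set — base-population frequencies are unobservable here. Because a
raw $G$ and $A_{22}$ sit on different scales, `scale_G_to_A22()`
applies the affine rescaling $G^* = a + bG$ solving the two-moment
system (mean diagonal and mean off-diagonal of $G^*$ equal those of
$A_{22}$), the standard compatibility adjustment that avoids bias in
single-step evaluations. A small pedigree admixture
$\alpha G^* + \beta A_{22}$ ($\alpha = 0.95$, $\beta = 0.05$,
$\alpha + \beta = 1$ enforced) guarantees invertibility.

**Combined.** `build_H()` assembles the combined matrix blockwise,

$$H = \begin{bmatrix}
A_{11} + A_{12}A_{22}^{-1}(G - A_{22})A_{22}^{-1}A_{21} &
A_{12}A_{22}^{-1}G \\ GA_{22}^{-1}A_{21} & G \end{bmatrix},$$

and `build_H_inverse()` its tuned inverse

$$H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\
0 & \tau(\alpha G^* + \beta A_{22})^{-1} - \omega A_{22}^{-1}
\end{bmatrix}.$$

With $\tau = \omega$ the genomic:pedigree mixing proportion is
$\tau:(1-\tau)$; the package always sets $\omega = \tau$ by default
and evaluates the grid $\tau \in \{1.00, 0.75, 0.50\}$. Setting
$\tau = \omega = 0$ returns $A^{-1}$ unchanged, which
`ss_kernel()` exploits to make the single-step model collapse to
ABLUP *bit for bit* at that corner — a property the tests assert
exactly. Where the inverse-$H$ route at $\tau \ne 1$ needs a kernel
for REML, the kernel is the dense inverse of $H^{-1}(\tau)$, keeping
the variance components consistent with the equations actually solved.
Whether rescaling happens before or after blending is a genuinely open
choice; the package rescales first and then blends, because the
rescaling contract is stated against the unblended $G$.

All algebra is dense. At the population sizes this design targets (a
few thousand individuals) dense factorizations are fast, exact and
simpler to verify than sparse $A^{-1}$ machinery; the mutual-inverse
identities above are asserted to $10^{-8}$ on random populations.

## SNP quality control

`qc_genotypes()` runs five ordered stages: call-rate filter
(< 0.80 removed), minor-allele-frequency filter (< 0.01 removed, the
boundary itself retained — the inequality is strict), a
Mendelian-consistency check (an offspring call with zero transmission
probability given two genotyped parents is set missing), imputation,
and greedy pruning of loci with squared correlation above 0.99 to an
already-retained locus. Imputation fills a missing call with the most
probable genotype under Mendelian transmission given the parental
calls (ties broken toward the heterozygote), falling back to
single-parent transmission times the locus allele frequency, and to
the rounded locus mean when no parent is genotyped. Imputation runs in
pedigree order and the blank-and-impute pair iterates to a fixed
point, so a second QC pass changes nothing — an invariant the tests
check. The imputation rule and the pruning rule are internal
substitutes for external phasing-based imputation software and
published pruning recipes; they implement the same intent, not the
same algorithms.

## REML

`reml_estimate()` estimates $(\sigma^2_u, \sigma^2_e)$ by exact
restricted maximum likelihood. The kernel is projected onto the
orthogonal complement of $\mathbf{X}$ and eigendecomposed once, after
which the restricted likelihood is a smooth one-dimensional function
of $\lambda$, maximised by a coarse bracket on $\log_{10}\lambda$ over
$[-8, 8]$ followed by Brent refinement; $\sigma^2_u$ is then available
in closed form. For a two-component model this is preferred over
quasi-Newton schemes on the pair of variances (such as
average-information REML): it cannot step outside the parameter space,
has no convergence heuristics to tune, and finds the global optimum of
the profiled likelihood on the bracket. The restricted log-likelihood
it reports is verified in the tests against an independent dense
evaluation of $-\tfrac12(\log|V| + \log|X'V^{-1}X| + y'Py)$ plus
constants. A boundary solution ($\sigma^2_u$ at its floor of
$10^{-8}\times$ the phenotypic variance, or $\lambda$ at the bracket
edge) raises a warning and is flagged on the result. Heritability is
$h^2 = \sigma^2_u/(\sigma^2_u + \sigma^2_e)$.

## Cross-validation schemes

**Genotyped individuals** (`cv_genotyped()`): the targets are
genotypic values of the members of the genotyped families, estimated
by ABLUP from *all* records — the best available proxy for total
genetic merit when the truth is unknown. Each cycle removes one
genotyped family's records from the training response (one cycle per
genotyped family; individuals stay in the pedigree and genotype
matrix, so the scheme mimics selecting juvenile seedlings that have
genotypes but no phenotypes yet) and each model predicts the omitted
family. Accuracy is the Pearson correlation between targets and
predictions pooled over all cycles; per-cycle correlations are
reported alongside, since the pooled statistic mixes between- and
within-family signal.

**Non-genotyped families** (`cv_nongenotyped()`): targets are the
observed family means of the non-genotyped families with strictly
more than 10 members, computed from records adjusted for the year
effects of the full-data ABLUP fit. Each cycle removes one target
family's records entirely; its predicted genotypic value is then
identical across members (they are exchangeable full sibs with no
data), and is compared to the observed mean. Accuracy is the weighted
correlation across families with family sizes as weights. The
$\tau$ used here is the one with the best genotyped-CV accuracy,
mirroring how a breeder would pick it.

Standard errors use $\sqrt{(1-r^2)/(n-2)}$, with the effective sample
size $n_{\mathrm{eff}} = (\sum w)^2/\sum w^2$ replacing $n$ in the
weighted case. These are declared formulas, not reproductions of any
particular software's output. Variance components are re-estimated by
REML inside every training cycle by default — the conservative choice,
since the omitted records may shift the components — with
`refit_varcomp = FALSE` available to reuse the full-data estimates.

Two no-leakage invariants are enforced by tests: perturbing an omitted
family's phenotypes changes none of its predictions, and the targets of
the genotyped scheme come from one fixed full-data fit, never from a
training subset.

## The synthetic population

`sim_config()` describes the population the defaults emulate: 106
founder cultivars, 122 pair-cross families (~1830 F1), 9 genotyped
families of ~42 members (~377 genotyped F1) plus all founders, 50
large non-genotyped families (more than 10 members, the non-genotyped
CV targets) and the remainder small, four harvest years with 1–4
records per individual, and $h^2 = 0.6$
($\sigma^2_u = 0.6, \sigma^2_e = 0.4$) — inside the 0.57–0.82 range
typical of fruit-quality traits in such material. Family-size ranges
(genotyped 38–46, large 11–35, small 2–9) are the package's own
choice, picked once to reproduce the category totals above; the year
effects (0, 0.8, −0.5, 0.4 in trait units) are likewise fixed
arbitrary values of realistic magnitude. `sim_config_small()` keeps
the same architecture at 30 founders / 24 families / 4 genotyped
families / 500 SNPs, the size used throughout the test suite and the
acceptance script so that a full CV run takes seconds, and the REML
recovery checks use ~1500-individual pedigrees with a single record
per individual.

Founder genotypes are drawn binomial$(2, p_j)$ with $p_j$ uniform in
(0.05, 0.5) and dropped through the pedigree one independently
segregating allele at a time. What the simulator deliberately does
**not** emulate: linkage and LD between loci (relationship-matrix
algebra at these scales is insensitive to it, but real GBS panels are
not independent), relatedness *among* founders (real parental
cultivars share ancestry; founders here are unrelated, which makes the
simulated $A$ blockier than a real citrus pedigree), selection over
generations, and genotype-by-environment interaction. Passing tests
on this population therefore demonstrate the correctness of the
algebra and the qualitative behaviour of the estimators — they do not
certify accuracy levels on real breeding data. A `n_qtl` mode draws
genic breeding values from a finite number of loci instead of the
infinitesimal pedigree model, for sensitivity checks of the additive
assumption.

## Numerical choices and degenerate inputs

* Symmetry is enforced after every dense inverse ($\,(M + M')/2$);
  relationship matrices must be symmetric to $10^{-10}$ on
  construction.
* Pedigrees are sorted by a stable topological sort (input order
  preserved within a generation); cycles and self-parentage are
  errors, not warnings.
* Singular $A_{22}$ or $\alpha G + \beta A_{22}$ produce immediate
  errors (the latter suggesting a larger $\beta$); a monomorphic-only
  genotype matrix is an error because the VanRaden denominator
  vanishes.
* The rescaling system for $(a, b)$ is singular when the mean diagonal
  of $G$ equals its mean off-diagonal; this is reported rather than
  silently regularised.
* Ties in the imputation posterior break toward the heterozygote,
  the most conservative single call.
* REML convergence tolerance is $10^{-8}$ on the restricted
  log-likelihood with a cap of 200 optimiser iterations; the variance
  floor is $10^{-8}\times$ phenotypic variance.

## Known limitations

Dense algebra bounds the practical population size at a few tens of
thousands of individuals; no APY-style approximations are provided.
There are no genetic groups or metafounders, no dominance or epistatic
components, no multi-trait REML, and no standard errors of individual
breeding values (the CV schemes need only point predictions). The
Mendelian filter tests trios only — single-parent conflicts are left
to the imputation stage — and the correlated-SNP pruning is a greedy
scan, not an optimal subset selection.
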