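---
title: "Genomic evaluation, back-solved GWAS and quantitative-genetics theory with snpblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic evaluation, back-solved GWAS and quantitative-genetics theory with snpblup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpblup)
```

# The models

## Relationship matrices

The package is organised around the animal model
$$ y = X\beta + a + e, \qquad a \sim N(0,\, K\,\sigma^2_A), \quad
   e \sim N(0,\, I\,\sigma^2_e), $$
where the kinship matrix $K$ is one of

* **A** — the pedigree (numerator) relationship matrix, built recursively
  by the tabular method (`build_A()`). Its diagonal is $1+F_i$ with $F_i$
  the inbreeding coefficient.
* **G** — the genomic relationship matrix (`build_G()`),
  $G = ZZ'/k$ with $Z$ the matrix of dosages centered by twice the
  allele frequency and the single scale constant $k = 2\sum_i p_i q_i$.
  The single-constant form (rather than per-SNP standardisation, which is
  available via `scaling = "per_snp"`) was chosen because the same $1/k$
  appears in the SNP-effect back-solving step, which keeps the
  animal-level and SNP-level parameterisations exactly interconvertible.
  Missing dosages are imputed to $2p_i$, so they center to zero.
* **H** — the single-step matrix combining both. Only its inverse is ever
  needed:
  $H^{-1} = A^{-1} + \begin{pmatrix} 0 & 0 \\ 0 & G^{*-1} - A_{22}^{-1}
  \end{pmatrix}$,
  with the nonzero block on the genotyped animals (`build_H_inverse()`).

`build_A_inverse()` constructs $A^{-1}$ directly by Henderson's rules with
the inbreeding-corrected Mendelian-sampling variance
$d_i = \tfrac12 - \tfrac14(F_s + F_d)$: each animal touches at most the
nine cells spanned by itself and its known parents (one with no known
parents, four with one, nine with two). Using parental $F$ here is what
makes $A^{-1}A = I$ hold exactly for inbred pedigrees; the test-suite
checks the identity to $10^{-8}$ on random pedigrees up to 200 animals.

### Why G must usually be blended

With allele frequencies observed in the genotyped set, the columns of $Z$
sum to zero, so the all-ones vector lies in the null space of $Z'$ and $G$
is *exactly* singular. Family data make things worse: full sibs can
inherit identical gametes, duplicating rows of $Z$. `blend_tune_G()`
therefore computes
$G^* = w\,G_\text{tuned} + (1-w)\,A_{22}$ (default $w = 0.95$), after
optionally solving $\alpha + \beta G$ so that the mean diagonal and mean
off-diagonal match $A_{22}$ (compatibility of the pedigree and genomic
bases). Defaults: tuning on for single-step evaluations, off for pure
GBLUP toys where the exact SNP-BLUP equivalence matters. When no pedigree
exists, blending toward the identity serves the same numerical purpose.

## Mixed-model equations and prediction-error variances

`assemble_mme()` builds the Henderson system
$$ \begin{pmatrix} X'X & X'W \\ W'X & W'W + K^{-1}\lambda \end{pmatrix}
   \begin{pmatrix} \hat\beta \\ \hat a \end{pmatrix} =
   \begin{pmatrix} X'y \\ W'y \end{pmatrix}, \qquad
   \lambda = \sigma^2_e/\sigma^2_A, $$
solved by dense Cholesky (`solve_mme()`); the package is deliberately
desk-scale (exact inverse blocks are needed downstream, so no iterative
solvers). A second genetic component sharing $W$ is supported for the
window-variance model. Rank-deficient fixed effects are handled by
constraining the solutions of the QR-dependent columns to zero — a
deterministic, test-friendly convention. Prediction-error (co)variances
are reported in trait-variance units,
$\mathrm{Var}(a - \hat a) = C^{aa}\sigma^2_e$ with $C^{aa}$ the
corresponding block of the inverse left-hand side
(`extract_pev_block()`), so that $G\sigma^2_A - C^{a_2a_2}$ below is
dimensionally coherent.

## Variance components

`estimate_variance_components()` implements EM-REML. EM was preferred to
Newton-type REML for robustness: updates stay positive and the REML
log-likelihood never decreases (asserted by the tests on every trace).
Because EM creeps geometrically near zero-variance boundaries, each step
attempts two guarded accelerations — a log-space extrapolation of the EM
update and, in the dense multi-component path, an average-information
(AI) step with negative proposals clamped to the boundary — each
*accepted only when the REML log-likelihood improves*, preserving the
monotonicity guarantee while converging in tens rather than thousands of
iterations. A window component whose likelihood optimum sits at zero
variance is thus reached directly instead of being crawled toward.
Convergence is declared when the largest relative parameter change falls
below `tol` ($10^{-6}$ by default); components smaller than $10^{-6}$ of
the total variance are judged on an absolute scale so that a vanishing
component cannot stall the criterion. A single genetic component uses a
one-time eigendecomposition of the observed-animal kinship, making every
iteration linear in the number of records; two components use dense
inversions (intended for up to a few thousand records).

# Association testing

## Back-solved SNP effects and their variances

A GBLUP (or single-step) evaluation yields breeding values, not SNP
effects. The SNP-centric model $y = X\beta + Zg + e$, $g \sim N(0,
I\sigma^2_g)$ with $\sigma^2_g = \sigma^2_A/k$, has identical fitted
breeding values $a = Zg$, and its solution can be recovered from the
animal-level one:
$$ \hat g = \tfrac1k\,Z' G^{-1} \hat a_2, \qquad
   \mathrm{Var}(\hat g_i) = \tfrac1k\, z_i' G^{-1}
   \left(G\sigma^2_A - C^{a_2a_2}\right) G^{-1} z_i\, \tfrac1k, $$
computed for the diagonal only (one vectorised pass over SNPs). The test
statistic is $t_i = \hat g_i / \sqrt{\mathrm{Var}(\hat g_i)}$ with
two-tailed Gaussian P-value $p_i = 2(1-\Phi(|t_i|))$: under the null the
back-solved effect estimator is Gaussian with exactly this variance. SNPs
with zero variance (no information) are flagged rather than given
statistics.

The same statistic arises from the two-stage fixed-SNP (EMMAX-style)
test: fit the null model once, then test each SNP as a fixed covariate at
the null variance ratio (`fixed_snp_test()` refits the augmented
mixed-model equations; `fixed_snp_scan()` does all SNPs at once through
the projection matrix $P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}$:
$\hat b_i = z_i'Py / z_i'Pz_i$, $\mathrm{se} = (z_i'Pz_i)^{-1/2}$). The
two routes are algebraically equivalent when $G = ZZ'/k$ includes the
tested SNP; the acceptance suite verifies
$\max_i |t_i^{\text{back}} - t_i^{\text{fixed}}| < 10^{-6}$ over random
toys with nontrivial fixed effects. Note that the equivalence is exact
only for an *unblended*, invertible $G$; the equivalence fixtures
therefore center genotypes at their simulated-truth frequencies (a
supported `freqs` override) rather than observed ones.

## Multiple testing

`multiple_testing()` offers Bonferroni ($p < \alpha/m$) and the
proportion-of-false-positives step-up rule: reject the $k^*$ smallest
P-values where $k^* = \max\{k : m\,p_{(k)}/k \le \alpha\}$, i.e. the
estimated expected share of false positives among the rejections is kept
at $\alpha$. PFP is the default: with the long-range LD of livestock
panels the tests are strongly correlated and Bonferroni is overly
conservative. QQ/Manhattan data tables (`qq_manhattan_data()`) include a
singleton flag — a significant SNP with no neighbouring support within 1
Mb is more likely a data artifact than a causal cluster in LD.

## Genotype quality control

`genotype_qc()` filters on minor allele frequency (default 0.05; small
studies need the stringent cutoff), on the count of minor-allele carriers
(default minimum 10), and on a Hardy-Weinberg chi-square test (default
$\alpha = 10^{-8}$), and flags opposing-homozygote Mendelian conflicts
when a pedigree is supplied.

# Peak inference

`detect_peaks()` finds P-value minima separated by a minimum distance
(greedy, ties broken toward smaller coordinates). For a detected peak,
`jackknife_peak_ci()` repeatedly (default $K = 30$; the seed is
mandatory) splits the records into two random halves, re-runs the scan in
each half restricted to the region's SNPs, and uses
$$ \mathrm{se} = \sqrt{\tfrac{1}{4K}\sum_k (v_{1k} - v_{2k})^2}, \qquad
   \text{CI} = v \pm 1.96\,\mathrm{se}. $$
Halves are scored with the fixed-SNP scan using the genome-wide G of the
full data restricted to each half's animals: testing stays local (as the
procedure intends) while relatedness control stays genome-wide, and since
$V = K\sigma^2_A + I\sigma^2_e$ is positive definite for any PSD $K$, no
per-half matrix inversion of a possibly singular local G is needed.
Halves are drawn uniformly at random; family structure is *not* balanced
across halves, a simplification that can widen the spread of half-peaks
in strongly structured data.

The variance tagged by a peak can be estimated two ways:

* `window_variance()` fits the two-component model
  $y = X\beta + a_{-w} + a_w + e$ with $G_w$ from the window SNPs
  (unblended — it is fitted jointly with the genome-wide term) and
  $G_{-w}$ from the rest (blended as usual), reporting
  $h^2_w = \hat\sigma^2_w / (\hat\sigma^2_{-w} + \hat\sigma^2_w +
  \hat\sigma^2_e)$. The default window is the jackknife confidence
  interval; a fixed width or the span of significant SNPs are equally
  valid choices.
* `fixed_snp_variance()` is the one-SNP shortcut
  $\hat\sigma^2_i = \mathrm{var}(z_i)\,\hat b_i^2$ — a gross
  approximation that tends to overestimate; useful for ranking QTLs, not
  for reporting.

# Linkage-disequilibrium theory

For three biallelic loci with haplotype frequencies in the fixed order
(abc, abC, aBc, aBC, Abc, AbC, ABc, ABC),
$$ D_{ABC} = p_{ABC} - p_A D_{BC} - p_B D_{AC} - p_C D_{AB}
   - p_A p_B p_C, $$
which equals the third mixed central moment of the allele indicators
(the tests verify both routes agree on random tables).
`extremize_third_order_D()` maximises/minimises $D_{ABC}$ on the simplex
under linear constraints (fixed allele frequencies and pairwise D): the
feasible set is parameterised through the null space of the constraint
matrix, scanned on a deterministic grid (step 1/400 per free coordinate),
and polished by golden-section/Nelder-Mead refinement — reproducible
extrema with no stochastic optimiser. At intermediate frequencies with
zero pairwise disequilibria the range is exactly $[-1/8, +1/8]$.

`bulmer_haploid_ld()` reproduces the classic demonstration that
directional selection builds *negative* LD: four gametes at frequency
0.25 with phenotypes 0, 1, 1, 2 and fitnesses $(1-s), 1, 1, (1+s)$ end at
$D = -s^2/16$ (the $\pm s$ terms cancel, so the post-selection
frequencies sum to one without renormalisation). `selection_response()`
evaluates the cumulative response with additive-by-additive variance
under free recombination, $R_t = i\sigma_P(t h^2 + V_{AA}/V_P)$, and no
recombination, $R_t = i\sigma_P(t h^2 + t V_{AA}/2V_P)$; the two coincide
at $t = 2$.

# Phantom genetic parameters

`apparent_marker_variances()` shows, by exact enumeration (random union
of gametes; no sampling), how LD among three loci fabricates non-existent
variance components at the markers. Genotypic values are averaged over
the unobserved loci conditional on the observed marker genotypes, and the
conditional means are partitioned by genotype-frequency-weighted least
squares on per-locus orthogonal contrasts (linear = additive,
orthogonalised heterozygosity = dominance, products = epistasis),
orthogonalised sequentially under the joint genotype distribution so the
partition is exact under arbitrary LD and sums to the conditional-mean
variance (an identity asserted in the tests).

Under a table with *only* third-order LD (intermediate frequencies, all
pairwise D zero, $D_{ABC} = d$):

* an additive QTL seen through two markers shows **only**
  additive-by-additive variance — in this family exactly
  $V_{A \times A} = 16 d^2$, with zero marker additive and dominance;
* a dominant QTL adds apparent dominance-by-dominance variance;
* a QTL *pair* seen through one marker shows apparent dominance when the
  epistasis is dominance-by-dominance; additive-by-additive epistasis at
  the QTL instead projects onto the marker's additive contrast (a fact
  the enumeration makes exact, and worth knowing when interpreting
  "epistasis appears as dominance" folklore).

`phantom_variance_experiment()` repeats the comparison over random
gametic-frequency tables (flat Dirichlet on the 8-haplotype simplex) and
random Gaussian genotypic effects, counting how often the *apparent*
additive variance at the markers exceeds the QTL's true additive
variance. Two definitional choices matter and are deliberate:

* the apparent marker additive variance is the **sum of marginal
  per-marker regressions** — what a per-SNP analysis reports — which
  double-counts shared signal when the markers are in LD with each other;
  the joint least-squares projection, by contrast, provably cannot exceed
  the truth for a purely additive QTL (conditioning only shrinks
  variance), which would make the experiment degenerate at zero;
* the default effect draw therefore includes Gaussian dominance (and,
  for the two-QTL configuration, epistatic) values alongside the additive
  ones. Under these defaults the exceedance proportions are small and
  strictly positive (a few per mil to a few percent, with binomial
  standard errors reported).

# The population simulator

`simulate_population()` gene-drops founder haplotypes (per-SNP founder
frequencies uniform on [0.05, 0.5]) through a pedigree grown for a
configured number of generations, with meioses recombining along the
genetic map via the Haldane map function (one 100-cM chromosome of 1e8 bp
by default; multi-chromosome via the config). QTL are a random subset of
the SNP loci — so a true QTL sits exactly at a map position — with
Gaussian effects rescaled so the realized breeding-value variance equals
$h^2\sigma^2_P$; phenotypes add a Gaussian residual. Truncation selection
on phenotype or on pedigree-BLUP EBV (computed internally) reproduces
(genomic) preselection scenarios. Everything is driven by one mandatory
seed and reruns byte-identically.

What the simulator emulates: Mendelian inheritance with linkage, drift,
family structure, additive architectures, selection. What it does not:
mutation, dominance/epistasis at the trait level, genotyping error,
missingness patterns, real LD decay shaped by demography. Passing the
calibration suites on these data therefore demonstrates internal
correctness of the estimators under the assumed model, not robustness to
the quirks of real livestock data.

## Problem sizes used by the test and acceptance suites

Chosen as the smallest sizes at which the statistical checks are
informative: EMMAX-equivalence toys at $n = 200$, $m = 500$ (20
replicates); null calibration pooling 10,000 tests from five populations
of $n = 400$, $m = 2000$; the Monte-Carlo estimator-variance oracle on a
$n = 60$, $m = 120$ toy with 20,000 phenotype redraws; heritability
recovery from 20 simulated populations of $n = 2000$ with 5,000 SNPs;
jackknife coverage over 100 single-QTL populations of $n = 300$ with the
QTL explaining 15% of the phenotypic variance (a clearly significant
peak, as the procedure presupposes) and $K = 30$.

# Known limitations

* Dense algebra throughout: a few thousand animals is the intended scale;
  no APY-style approximations, metafounders or unknown-parent groups.
* The `.ped` dialect carries no allele metadata, so a SNP whose counted
  allele is absent from the sample round-trips with flipped orientation
  (dosage $2-x$); the `.raw` dialect is lossless.
* EM-REML near a zero variance component converges to the boundary
  slowly (mitigated, not eliminated, by the guarded extrapolation); the
  returned trace makes the behaviour auditable.
* Jackknife halves ignore family structure; the equivalence between
  back-solved and fixed-SNP tests is exact only for unblended G.
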