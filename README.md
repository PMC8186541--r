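# snpblup

Desk-scale quantitative genetics for genomic evaluation and association
in animal breeding. The package is for researchers and students who want
the full chain from pedigree and SNP data to tested association peaks in
plain, inspectable R:

* **Relationship matrices** — pedigree A by the tabular method, its
  sparse inverse by Henderson's rules (at most nine cells per animal,
  inbreeding handled through the parental-F Mendelian-sampling variance),
  the VanRaden genomic matrix G = ZZ′/k with k = 2Σpᵢqᵢ, blending/tuning
  of G against A₂₂, and the single-step H⁻¹.
* **Mixed models** — Henderson's mixed-model equations for GBLUP and
  single-step GBLUP (ssGBLUP), exact prediction-error covariance blocks,
  and EM-REML variance components (with a likelihood-guarded
  average-information acceleration) for one- and two-component models.
* **GWAS with real P-values from GBLUP** — SNP effects back-solved from
  breeding values, ĝ = Z′G⁻¹â/k, with exact sampling variances
  Var(ĝᵢ) = zᵢ′G⁻¹(Gσ²ₐ − C^{a₂a₂})G⁻¹zᵢ/k², tᵢ = ĝᵢ/se(ĝᵢ) and
  pᵢ = 2(1 − Φ(|tᵢ|)). The two-stage fixed-SNP (EMMAX-style) test is
  also provided and is numerically identical — the test-suite holds the
  two routes to within 1e-6. Multiple testing by Bonferroni or the
  proportion-of-false-positives step-up rule; QQ/Manhattan tables;
  MAF / carrier-count / HWE / Mendelian QC.
* **Peak inference** — jackknife confidence intervals for the position of
  an association peak (random half-splits, se = √[Σ(v₁ₖ−v₂ₖ)²/4K],
  CI = v ± 1.96·se) and the variance explained by a peak, either by a
  two-GRM window model (h²_w = σ̂²_w/(σ̂²₋w + σ̂²_w + σ̂²_e)) or the quick
  var(zᵢ)·b̂ᵢ² approximation.
* **LD and selection theory** — third-order linkage disequilibrium
  D_ABC = p_ABC − p_A·D_BC − p_B·D_AC − p_C·D_AB − p_A·p_B·p_C with
  constrained extremisation (range ±1/8 at intermediate frequencies and
  zero pairwise D), the haploid selection demonstration that builds
  D = −s²/16, response to selection with free vs. no recombination, and
  exact enumeration of the *phantom* dominance/epistasis that third-order
  LD fabricates at markers.
* **A gene-dropping simulator** (pedigree, Haldane recombination, QTL
  architectures, truncation selection) so every stage can be exercised
  and calibrated without external data, plus PLINK `.ped/.map` and `.raw`
  readers/writers and a small command line (`inst/cli/snpblup`).

## Worked example

Simulate a population, estimate variance components, run a GBLUP GWAS,
and put a confidence interval on the top peak:

```r
library(snpblup)

sim <- simulate_population(sim_config(n_founders = 150, n_generations = 2,
                                      n_snps = 1000, n_qtl = 5, h2 = 0.35,
                                      seed = 42))
G  <- build_G(sim$geno)
A  <- build_A(sim$ped)
Gs <- blend_tune_G(G, extract_A22(A, sim$geno$ids))   # w = 0.95, tuned

fit <- estimate_variance_components(sim$pheno$y, NULL, sim$pheno$animal, Gs)
round(fit$sigma2, 3)
#>     a     e
#> 0.261 0.667        # h2_hat = 0.281 (simulated: 0.35 at n = 450)

res <- adjust_gwas(gwas_gblup(sim$pheno$y, NULL, sim$pheno$animal,
                              sim$geno, fit$sigma2[1], fit$sigma2["e"],
                              G = Gs))
head(res[order(res$p), c("snp", "pos", "effect", "se", "t", "p", "p_adj")], 3)
#>     snp      pos  effect      se     t        p    p_adj
#>  snp757 76152988  0.0899 0.00842 10.68 1.27e-26 1.27e-23
#>  snp149 14290885  0.0292 0.00904  3.23 1.22e-03 6.08e-01
#>  snp722 72851139 -0.0235 0.00783 -3.00 2.67e-03 7.31e-01

pk <- detect_peaks(res, threshold = 0.05 / nrow(res))
ci <- jackknife_peak_ci(sim$pheno$y, NULL, sim$pheno$animal, sim$geno,
                        list(chr = 1, start = pk$pos[1] - 1e7,
                             end = pk$pos[1] + 1e7),
                        fit$sigma2[1], fit$sigma2["e"], K = 30, seed = 7,
                        G = Gs)
ci
#> peak at 7.6153e+07 bp, se 0.0 bp, 95% CI [76152988.0, 76152988.0] (K = 30)

wv <- window_variance(sim$pheno$y, NULL, sim$pheno$animal, sim$geno,
                      list(chr = 1, start = ci$v - 2e6, end = ci$v + 2e6))
round(wv$h2_w, 3)
#> [1] 0.368
```

The top SNP is the simulated QTL itself (`sim$qtl` confirms snp757 at
76,152,988 bp carries 96% of the genetic variance in this draw): every
half-split peak lands on the same SNP, so the jackknife interval
degenerates to the exact position, and the 4-Mb window around it tags a
window heritability of 0.37.

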