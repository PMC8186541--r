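test_that("the simulator is deterministic and honours heritability", {
  cfg <- sim_config(n_founders = 60, n_generations = 2, n_snps = 200,
                    n_qtl = 10, h2 = 0.3, seed = 51)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$geno$dosages, s2$geno$dosages)
  expect_identical(s1$pheno$y, s2$pheno$y)
  expect_identical(s1$qtl, s2$qtl)

  ## realized heritability matches the target
  big <- simulate_population(sim_config(n_founders = 500,
                                        n_generations = 2, n_snps = 400,
                                        n_qtl = 40, h2 = 0.3, seed = 52))
  h2_real <- stats::var(big$tbv) / stats::var(big$pheno$y)
  expect_lt(abs(h2_real - 0.3), 0.05)

  ## h2 = 0: phenotype carries no signal of the (zero) breeding values
  null <- simulate_population(sim_config(n_founders = 500,
                                         n_generations = 2, n_snps = 200,
                                         n_qtl = 20, h2 = 0, seed = 53))
  expect_true(all(null$tbv == 0))
  expect_equal(stats::var(null$pheno$y), 1, tolerance = 0.15)
})

test_that("gene dropping reproduces pedigree expectations in G", {
  sim <- simulate_population(sim_config(n_founders = 200,
                                        n_generations = 2, n_snps = 600,
                                        n_qtl = 0, h2 = 0, seed = 54))
  G <- build_G(sim$geno)
  ped <- sim$ped
  po <- which(ped$sire > 0)
  rel <- mapply(function(child, par) G[ped$id[child], ped$id[par]],
                po, ped$sire[po])
  expect_gt(length(rel), 300)
  expect_lt(abs(mean(rel) - 0.5), 0.05)
})

test_that("truncation selection shifts the mean relative to drift", {
  base <- simulate_population(sim_config(n_founders = 100,
                                         n_generations = 3, n_snps = 200,
                                         n_qtl = 20, h2 = 0.5, seed = 55,
                                         selection = "none"))
  sel <- simulate_population(sim_config(n_founders = 100,
                                        n_generations = 3, n_snps = 200,
                                        n_qtl = 20, h2 = 0.5, seed = 55,
                                        selection = "phenotype",
                                        prop_selected = 0.2))
  last <- function(s) mean(s$tbv[s$pheno$generation == 3]) /
    stats::sd(s$tbv)
  expect_gt(last(sel), last(base))
})

test_that("apparent marker variances vanish in linkage equilibrium", {
  p <- c(0.4, 0.5, 0.3)
  x <- hap_indicators()
  f <- apply(x, 1, function(h) prod(ifelse(h == 1, p, 1 - p)))
  tab <- haplotype_table(f)
  for (cfgn in c("one_qtl_two_markers", "two_qtls_one_marker")) {
    av <- apparent_marker_variances(tab, list(a = rep(1, 1 +
      (cfgn == "two_qtls_one_marker"))), config = cfgn)
    expect_lt(sum(av$marker), 1e-12)
    expect_gt(sum(av$qtl), 0)
  }
})

test_that("third-order LD alone fabricates epistasis at the markers", {
  s <- apply(hap_indicators() * 2 - 1, 1, prod)
  tab <- haplotype_table(1 / 8 + s * 0.1)  # D_ABC = 0.1, pairwise D = 0

  ## additive QTL: only apparent A x A at the markers
  av <- apparent_marker_variances(tab, list(a = 1),
                                  config = "one_qtl_two_markers")
  expect_equal(unname(av$qtl), c(0.5, 0), tolerance = 1e-12)
  expect_gt(av$marker[["axa"]], 0)
  expect_lt(av$marker[["additive"]], 1e-12)
  expect_lt(av$marker[["dominance"]], 1e-12)
  expect_lt(av$marker[["axd"]] + av$marker[["dxa"]] + av$marker[["dxd"]],
            1e-12)
  ## exact closed form for this family: V_AxA = 16 d^2
  expect_equal(av$marker[["axa"]], 16 * 0.1^2, tolerance = 1e-12)

  ## dominant QTL adds apparent D x D (and nothing else)
  avd <- apparent_marker_variances(tab, list(a = 1, d = 1),
                                   config = "one_qtl_two_markers")
  expect_gt(avd$marker[["axa"]], 0)
  expect_gt(avd$marker[["dxd"]], 0)
  expect_lt(avd$marker[["additive"]] + avd$marker[["dominance"]] +
              avd$marker[["axd"]] + avd$marker[["dxa"]], 1e-12)

  ## epistatic QTL pair seen through one marker fabricates dominance
  ## (dominance-by-dominance epistasis; additive-by-additive projects onto
  ## the marker's additive contrast instead)
  av2 <- apparent_marker_variances(tab, list(a = c(0, 0), d = c(0, 0),
                                             dd = 1),
                                   config = "two_qtls_one_marker")
  expect_gt(av2$marker[["dominance"]], 0)
  expect_lt(av2$marker[["additive"]], 1e-12)
  av3 <- apparent_marker_variances(tab, list(a = c(0, 0), d = c(0, 0),
                                             aa = 1),
                                   config = "two_qtls_one_marker")
  expect_gt(av3$marker[["additive"]], 0)

  ## the partition conserves the conditional-mean variance exactly
  expect_equal(sum(av$marker), av$total_marker, tolerance = 1e-12)
  expect_equal(sum(avd$marker), avd$total_marker, tolerance = 1e-12)
})

test_that("phantom variance experiment is reproducible and calibrated", {
  ## degenerate sampling on linkage-equilibrium tables: proportion zero
  le_sampler <- function(n) {
    t(replicate(n, {
      p <- stats::runif(3, 0.2, 0.8)
      apply(hap_indicators(), 1, function(h)
        prod(ifelse(h == 1, p, 1 - p)))
    }))
  }
  r0 <- phantom_variance_experiment(50, seed = 56,
                                    freq_sampler = le_sampler)
  expect_equal(r0$prop_one_qtl_two_markers, 0)
  expect_equal(r0$prop_two_qtls_one_marker, 0)

  ## default spec: strictly positive but small, and seed-reproducible
  r1 <- phantom_variance_experiment(400, seed = 57)
  r2 <- phantom_variance_experiment(400, seed = 57)
  expect_identical(r1$prop_one_qtl_two_markers, r2$prop_one_qtl_two_markers)
  expect_identical(r1$prop_two_qtls_one_marker, r2$prop_two_qtls_one_marker)
  expect_gt(r1$prop_one_qtl_two_markers + r1$prop_two_qtls_one_marker, 0)
  expect_lt(r1$prop_one_qtl_two_markers, 0.1)
  expect_lt(r1$prop_two_qtls_one_marker, 0.1)
})

test_that("evaluation drift summarises (G)EBV changes in SDa units", {
  ids <- paste0("a", 1:10)
  r1 <- stats::setNames(rnorm(10), ids)
  ds0 <- evaluation_drift(r1, r1, SDa = 2)
  expect_true(all(ds0$per_animal$change_pct == 0))

  r2 <- r1 + 0.1 * 2  # uniform +0.1 SDa shift
  cls <- stats::setNames(rep(c("g", "ng"), 5), ids)
  ds <- evaluation_drift(r1, r2, SDa = 2, classes = cls)
  expect_equal(ds$per_class$mean, c(10, 10))
  expect_equal(sum(ds$per_class$n), 10)

  sep <- stats::setNames(rep(0.05, 10), ids)
  dse <- evaluation_drift(r1, r2, SDa = 2, classes = cls, sep = sep)
  expect_true(all(dse$per_animal$exceeds_95ci))
  expect_error(evaluation_drift(r1, r2, SDa = 0), "positive")
})

test_that("two-slice rerun changes GEBV of connected genotyped animals only", {
  ## genotyped animals share information through G, so adding phenotypes
  ## for some of them moves the GEBV of the others; isolated pedigree-only
  ## animals keep their EBV
  sim <- simulate_population(sim_config(n_founders = 50, n_generations = 2,
                                        n_snps = 300, n_qtl = 10, h2 = 0.4,
                                        seed = 58))
  ped <- sim$ped
  ## append isolated, ungenotyped animals with their own records
  iso <- paste0("iso", 1:10)
  ped2 <- pedigree(c(ped$id, iso),
                   c(ped$id[pmax(ped$sire, 1)] |>
                       (\(x) ifelse(ped$sire == 0, "0", x))(), rep("0", 10)),
                   c(ped$id[pmax(ped$dam, 1)] |>
                       (\(x) ifelse(ped$dam == 0, "0", x))(), rep("0", 10)))
  A <- build_A(ped2)
  Ainv <- build_A_inverse(ped2, F = attr(A, "F"))
  gids <- sim$geno$ids[1:60]
  geno <- genotypes(sim$geno$dosages[gids, ], map = sim$geno$map,
                    ids = gids, freqs = sim$geno$freqs)
  A22 <- extract_A22(A, gids)
  Gs <- blend_tune_G(build_G(geno), A22)
  Hinv <- build_H_inverse(Ainv, Gs, A22)
  set.seed(59)
  y_iso <- rnorm(10)
  ## slice 1: founders-only records plus the isolated animals
  founders <- ped$id[ped$sire == 0]
  y1 <- c(sim$pheno$y[match(founders, sim$pheno$animal)], y_iso)
  an1 <- c(founders, iso)
  ## no fixed effects: a shifting intercept estimate would move every
  ## animal and mask the connectivity contrast under study
  run <- function(yv, av) {
    sys <- solve_mme(assemble_mme(yv, NULL, av, Hinv, 0.4, 0.6))
    sys$u[[1]]
  }
  u1 <- run(y1, an1)
  ## slice 2 adds phenotypes for half of the genotyped animals
  new_ph <- gids[1:30]
  y2 <- c(y1, sim$pheno$y[match(new_ph, sim$pheno$animal)])
  u2 <- run(y2, c(an1, new_ph))
  sd_a <- sqrt(0.4)
  ds <- evaluation_drift(u1, u2, SDa = sd_a,
                         classes = stats::setNames(
                           ifelse(names(u1) %in% iso, "isolated",
                                  ifelse(names(u1) %in% setdiff(gids, new_ph),
                                         "genotyped_no_new", "other")),
                           names(u1)))
  pa <- ds$per_animal
  moved <- function(cl) mean(abs(pa$change_pct[pa$class == cl]) > 1e-8)
  expect_gt(moved("genotyped_no_new"), moved("isolated"))
  expect_equal(moved("isolated"), 0)
})
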