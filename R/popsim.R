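#' Simulation configuration
#'
#' Defines a gene-dropping population simulation: founder genome, pedigree
#' growth, QTL architecture and trait heritability. Founder haplotypes are
#' drawn at per-SNP frequencies sampled uniformly from `founder_maf`;
#' meioses recombine along a genetic map via the Haldane map function; QTL
#' are a random subset of the SNP loci so association peaks sit at
#' map positions; phenotypes are true breeding value plus Gaussian
#' residual scaled to the requested heritability.
#'
#' @param n_founders number of founder animals (split evenly into sexes).
#' @param n_generations number of non-founder generations.
#' @param n_per_gen offspring born per generation; default `n_founders`.
#' @param offspring_per_mating litter size; default 2.
#' @param prop_selected proportion of each sex kept as parents; default 0.5.
#' @param selection `"none"`, `"phenotype"` or `"ebv"` (truncation; EBV via
#'   an internal pedigree BLUP so genomic-preselection scenarios are
#'   reproducible).
#' @param n_snps,n_qtl marker and QTL counts (`n_qtl` can be 0).
#' @param n_chr number of chromosomes; default 1.
#' @param chr_length_cM genetic length per chromosome; default 100.
#' @param chr_length_bp physical length per chromosome; default 1e8.
#' @param founder_maf range of founder allele frequencies; default
#'   `c(0.05, 0.5)`.
#' @param h2 trait heritability in `[0, 1]`.
#' @param sigma2_P phenotypic variance; default 1.
#' @param seed mandatory random seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 100, n_generations = 3,
                       n_per_gen = n_founders, offspring_per_mating = 2,
                       prop_selected = 0.5,
                       selection = c("none", "phenotype", "ebv"),
                       n_snps = 1000, n_qtl = 10, n_chr = 1,
                       chr_length_cM = 100, chr_length_bp = 1e8,
                       founder_maf = c(0.05, 0.5), h2 = 0.3,
                       sigma2_P = 1, seed) {
  selection <- match.arg(selection)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(n_founders >= 2, n_generations >= 0, n_snps >= 1, n_qtl >= 0,
            n_qtl <= n_snps, h2 >= 0, h2 <= 1, sigma2_P > 0,
            prop_selected > 0, prop_selected <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Gene-dropping population simulation
#'
#' @param config a [sim_config()].
#' @return list with `ped` ([pedigree()]), `geno` ([genotypes()], centering
#'   base fixed at the founder allele frequencies), `pheno` (data.frame
#'   `animal`, `sex`, `generation`, `y`), `qtl` (data.frame with positions
#'   and effects), `tbv` (named true breeding values), `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cf <- config
  m_per_chr <- table(rep(seq_len(cf$n_chr), length.out = cf$n_snps))
  map <- do.call(rbind, lapply(seq_len(cf$n_chr), function(ch) {
    m <- m_per_chr[[ch]]
    data.frame(chr = ch,
               pos = sort(sample.int(cf$chr_length_bp, m)),
               cM = NA_real_)
  }))
  map$cM <- (map$pos / cf$chr_length_bp) * cf$chr_length_cM
  map$snp <- paste0("snp", seq_len(nrow(map)))
  m <- nrow(map)
  ## per-adjacent-interval recombination probabilities (Haldane)
  rec <- numeric(m)
  for (ch in seq_len(cf$n_chr)) {
    idx <- which(map$chr == ch)
    d <- c(Inf, diff(map$cM[idx]) / 100)  # Morgans; Inf = new chromosome
    rec[idx] <- 0.5 * (1 - exp(-2 * d))
  }
  p0 <- stats::runif(m, cf$founder_maf[1], cf$founder_maf[2])
  ## animals: haplotype matrices grow generation by generation
  n_total <- cf$n_founders + cf$n_generations * cf$n_per_gen
  H1 <- matrix(0L, n_total, m)
  H2 <- matrix(0L, n_total, m)
  nf <- cf$n_founders
  H1[seq_len(nf), ] <- matrix(stats::rbinom(nf * m, 1, rep(p0, each = nf)),
                              nf, m)
  H2[seq_len(nf), ] <- matrix(stats::rbinom(nf * m, 1, rep(p0, each = nf)),
                              nf, m)
  sex <- rep_len(c("M", "F"), nf)
  sire <- dam <- integer(n_total)
  gen <- c(rep(0L, nf), rep(seq_len(cf$n_generations), each = cf$n_per_gen))
  meiosis <- function(h1, h2) {
    swit <- stats::runif(m) < rec
    cur <- cumsum(swit) %% 2L == 1L
    ## randomize phase at each chromosome start by the Inf distance rule:
    ## rec = 0.5 there, which already randomizes the starting haplotype
    ifelse(cur, h2, h1)
  }
  ## QTL architecture
  qtl_idx <- if (cf$n_qtl > 0) sort(sample.int(m, cf$n_qtl)) else integer(0)
  qtl_eff <- if (cf$n_qtl > 0 && cf$h2 > 0) stats::rnorm(cf$n_qtl) else
    rep(0, cf$n_qtl)
  tbv_of <- function(rows) {
    if (!length(qtl_idx)) return(rep(0, length(rows)))
    dos <- H1[rows, qtl_idx, drop = FALSE] + H2[rows, qtl_idx, drop = FALSE]
    as.numeric(dos %*% qtl_eff)
  }
  ## provisional phenotypes on the raw effect scale drive selection;
  ## the reported phenotypes are rescaled once all animals exist
  pheno_raw <- numeric(n_total)
  raw_pheno <- function(rows) {
    g <- tbv_of(rows)
    sdg <- stats::sd(g)
    if (cf$h2 > 0 && !is.na(sdg) && sdg > 0)
      g + stats::rnorm(length(rows), 0, sdg * sqrt(1 / cf$h2 - 1))
    else stats::rnorm(length(rows))
  }
  next_row <- nf
  avail <- seq_len(nf)
  pheno_raw[avail] <- raw_pheno(avail)
  for (g in seq_len(cf$n_generations)) {
    males <- avail[sex[avail] == "M"]
    females <- avail[sex[avail] == "F"]
    if (!length(males) || !length(females))
      stop("ran out of parents of one sex")
    crit <- switch(cf$selection,
      none = stats::runif(length(avail)),
      phenotype = pheno_raw[avail],
      ebv = internal_pblup(avail, sire, dam, pheno_raw, cf$h2))
    names(crit) <- as.character(avail)
    pick <- function(cands) {
      k <- max(1L, ceiling(length(cands) * cf$prop_selected))
      cands[order(-crit[as.character(cands)])][seq_len(k)]
    }
    sel_m <- pick(males); sel_f <- pick(females)
    born <- 0L
    while (born < cf$n_per_gen) {
      s <- sel_m[sample.int(length(sel_m), 1)]
      d <- sel_f[sample.int(length(sel_f), 1)]
      for (o in seq_len(cf$offspring_per_mating)) {
        if (born >= cf$n_per_gen) break
        next_row <- next_row + 1L; born <- born + 1L
        H1[next_row, ] <- meiosis(H1[s, ], H2[s, ])
        H2[next_row, ] <- meiosis(H1[d, ], H2[d, ])
        sire[next_row] <- s; dam[next_row] <- d
        sex <- c(sex, sample(c("M", "F"), 1))
      }
    }
    avail <- (nf + (g - 1L) * cf$n_per_gen + 1L):(nf + g * cf$n_per_gen)
    pheno_raw[avail] <- raw_pheno(avail)
  }
  ids <- paste0("a", seq_len(n_total))
  tbv <- tbv_of(seq_len(n_total))
  ## scale QTL effects so var(tbv) = h2 * sigma2_P over all animals
  if (cf$h2 > 0 && length(qtl_idx) && stats::var(tbv) > 0) {
    sc <- sqrt(cf$h2 * cf$sigma2_P / stats::var(tbv))
    qtl_eff <- qtl_eff * sc
    tbv <- tbv * sc
  }
  resid_sd <- sqrt(max(cf$sigma2_P - stats::var(tbv), 0))
  y <- tbv + stats::rnorm(n_total, 0, resid_sd)
  ped <- pedigree(ids,
                  ifelse(sire == 0, "0", paste0("a", sire)),
                  ifelse(dam == 0, "0", paste0("a", dam)))
  geno <- genotypes(H1 + H2, map = map[, c("snp", "chr", "pos")],
                    ids = ids, freqs = p0)
  names(tbv) <- ids
  list(ped = ped,
       geno = geno,
       pheno = data.frame(animal = ids, sex = sex, generation = gen, y = y),
       qtl = if (length(qtl_idx))
         data.frame(snp = map$snp[qtl_idx], chr = map$chr[qtl_idx],
                    pos = map$pos[qtl_idx], effect = qtl_eff)
       else data.frame(snp = character(0), chr = integer(0),
                       pos = integer(0), effect = numeric(0)),
       tbv = tbv, config = config)
}

## quick pedigree BLUP on the animals seen so far (selection on EBV)
internal_pblup <- function(avail, sire, dam, pheno_raw, h2) {
  upto <- max(avail)
  ids <- paste0("a", seq_len(upto))
  ped <- pedigree(ids,
                  ifelse(sire[seq_len(upto)] == 0, "0",
                         paste0("a", sire[seq_len(upto)])),
                  ifelse(dam[seq_len(upto)] == 0, "0",
                         paste0("a", dam[seq_len(upto)])))
  Ainv <- build_A_inverse(ped)
  h2 <- min(max(h2, 0.05), 0.95)
  sys <- assemble_mme(pheno_raw[seq_len(upto)], NULL, ids, Ainv,
                      sigma2_a = h2, sigma2_e = 1 - h2)
  sys <- solve_mme(sys)
  sys$u[[1]][paste0("a", avail)]
}
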