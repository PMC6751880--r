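# Synthetic populations with the statistical structure the evaluation
# methods assume: a multi-generation AI-ram pedigree (few sires, many dams),
# LD-structured founder haplotypes dropped through the pedigree with
# recombination, one pleiotropic causal locus of configurable variance
# fraction, repeatability-model phenotypes on females with herd-year fixed
# effects, genotyped males, and a validation cohort of young sires whose
# daughters' records can be withheld.
#
# Default scale and parameters emulate a dairy-sheep somatic-cell-score
# programme: phenotypic mean 3.12 and SD 1.56, causal-locus founder
# frequency 0.2 explaining 12% of the genetic variance, adjacent-marker
# r-squared near 0.25 at 0.064-Mb marker spacing.

#' Simulation configuration
#'
#' @param n_founders founder animals (generation 0).
#' @param founder_males number of male founders (the rest are females).
#' @param n_generations generations bred after the founders.
#' @param n_sires_per_gen sires sampled per generation (AI-ram structure).
#' @param n_dams_per_sire dams mated to each sire (sampled with
#'   replacement from the previous generation's females).
#' @param n_snps,n_chromosomes marker panel size and layout (evenly spaced).
#' @param snp_spacing_mb marker spacing in Mb (default 0.064, the chip's
#'   mean interval).
#' @param founder_ld_rho latent first-order Markov correlation between
#'   adjacent founder-haplotype loci; the default 0.895 is calibrated so
#'   mean adjacent-marker r-squared is about 0.25.
#' @param maf_floor minimum founder allele frequency.
#' @param causal_index SNP index of the causal locus (default: middle of
#'   chromosome 1).
#' @param causal_maf_target founder frequency of the mutant allele
#'   (default 0.2).
#' @param causal_variance_fraction fraction of the genetic variance
#'   explained by the causal locus (default 0.12).
#' @param mu,sigma2_pheno phenotypic mean and variance (defaults 3.12 and
#'   1.56^2, a lactation somatic-cell-score scale).
#' @param h2 heritability (default 0.3).
#' @param rep permanent-environment fraction of phenotypic variance
#'   (default 0.15); `h2 + rep` must be below 1.
#' @param n_lactations records per female (default 3, first three
#'   lactations).
#' @param n_herds herd-year levels; effects are drawn with SD
#'   `herd_sd_frac` phenotypic SD.
#' @param herd_sd_frac fixed-effect level SD as a fraction of the
#'   phenotypic SD (default 0.5).
#' @param recomb_rate_cM_per_Mb genetic map density (default 1).
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_founders = 600L, founder_males = 50L,
                       n_generations = 4L, n_sires_per_gen = 25L,
                       n_dams_per_sire = 24L, n_snps = 2000L,
                       n_chromosomes = 4L, snp_spacing_mb = 0.064,
                       founder_ld_rho = 0.895, maf_floor = 0.05,
                       causal_index = NULL, causal_maf_target = 0.2,
                       causal_variance_fraction = 0.12, mu = 3.12,
                       sigma2_pheno = 1.56^2, h2 = 0.3, rep = 0.15,
                       n_lactations = 3L, n_herds = 25L,
                       herd_sd_frac = 0.5, recomb_rate_cM_per_Mb = 1) {
  if (h2 + rep >= 1) stop("h2 + rep must be below 1")
  if (causal_variance_fraction < 0 || causal_variance_fraction >= 1)
    stop("causal_variance_fraction must be in [0, 1)")
  if (founder_ld_rho < 0 || founder_ld_rho >= 1)
    stop("founder_ld_rho must be in [0, 1)")
  if (is.null(causal_index))
    causal_index <- max(1L, as.integer(n_snps / n_chromosomes / 2))
  if (causal_index < 1L || causal_index > n_snps)
    stop("causal_index outside the panel")
  structure(as.list(environment()), class = "sim_config")
}

#' Evenly spaced SNP map
#' @param n_snps,n_chromosomes panel layout.
#' @param spacing_mb marker interval in Mb.
#' @return map data frame (`snp_id`, `chrom`, `pos_bp`).
#' @export
make_map <- function(n_snps, n_chromosomes, spacing_mb = 0.064) {
  per <- ceiling(n_snps / n_chromosomes)
  chrom <- rep(seq_len(n_chromosomes), each = per)[seq_len(n_snps)]
  within <- unlist(lapply(table(chrom), seq_len), use.names = FALSE)
  data.frame(snp_id = sprintf("snp%d_%d", chrom, within), chrom = chrom,
             pos_bp = as.integer(round(within * spacing_mb * 1e6)),
             stringsAsFactors = FALSE)
}

#' Simulate founder haplotypes with first-order Markov LD
#'
#' Along each chromosome a latent Gaussian AR(1) process with correlation
#' `rho` between adjacent loci is thresholded at the per-SNP allele
#' frequency, drawn uniformly on `[maf_floor, 1 - maf_floor]`. `rho = 0`
#' gives independent loci; LD decays monotonically with marker lag.
#'
#' @param n_hap number of haplotypes.
#' @param map SNP map (chromosome structure); or an integer SNP count for a
#'   single chromosome.
#' @param rho latent adjacent-locus correlation in `[0, 1)`.
#' @param maf_floor minimum allele frequency (default 0.05).
#' @param seed RNG seed.
#' @param freqs optional per-SNP frequencies overriding the uniform draw
#'   (e.g. to pin a causal locus).
#' @return 0/1 matrix `n_hap x n_snps` with attribute `"freq"`.
#' @export
simulate_founder_haplotypes <- function(n_hap, map, rho, maf_floor = 0.05,
                                        seed = 1L, freqs = NULL) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  set.seed(seed)
  if (!is.data.frame(map)) map <- make_map(as.integer(map), 1L)
  m <- nrow(map)
  p <- if (is.null(freqs)) runif(m, maf_floor, 1 - maf_floor) else freqs
  H <- matrix(0L, n_hap, m)
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    z <- matrix(0, n_hap, length(idx))
    z[, 1L] <- rnorm(n_hap)
    if (length(idx) > 1L)
      for (j in 2L:length(idx))
        z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * rnorm(n_hap)
    H[, idx] <- (z < rep(qnorm(p[idx]), each = n_hap)) * 1L
  }
  colnames(H) <- map$snp_id
  attr(H, "freq") <- p
  H
}

#' Calibrate the founder LD parameter against a target adjacent r-squared
#'
#' Bisection on `rho`, measuring mean adjacent-marker r-squared by direct
#' counting over simulated haplotypes.
#'
#' @param target_r2 target mean adjacent r-squared (default 0.25, the
#'   shortest-distance bin of a medium-density chip).
#' @param n_hap,n_snps simulation size per evaluation.
#' @param maf_floor,seed as in [simulate_founder_haplotypes()].
#' @param iter bisection iterations.
#' @return the calibrated `rho`.
#' @export
calibrate_ld_rho <- function(target_r2 = 0.25, n_hap = 2000L, n_snps = 400L,
                             maf_floor = 0.05, seed = 1L, iter = 12L) {
  measure <- function(rho) {
    H <- simulate_founder_haplotypes(n_hap, n_snps, rho, maf_floor, seed)
    mean_adjacent_r2(H)
  }
  lo <- 0; hi <- 0.995
  for (k in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (measure(mid) < target_r2) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Mean r-squared between adjacent columns of a haplotype/genotype matrix
#' @param H matrix whose columns are loci.
#' @return mean squared correlation over adjacent polymorphic pairs.
#' @export
mean_adjacent_r2 <- function(H) {
  v <- apply(H, 2, var)
  r2 <- vapply(seq_len(ncol(H) - 1L), function(j) {
    if (v[j] == 0 || v[j + 1L] == 0) return(NA_real_)
    cor(H[, j], H[, j + 1L])^2
  }, numeric(1))
  mean(r2, na.rm = TRUE)
}

#' Drop founder haplotypes through a pedigree
#'
#' Founders receive consecutive haplotype pairs; every other animal inherits
#' one recombined gamete per parent, with crossover counts Poisson at
#' Haldane map distance (`recomb_rate_cM_per_Mb`, default 1 cM/Mb) and
#' uniform crossover positions. An animal with exactly one known parent
#' draws the unknown gamete from the founder haplotype pool.
#'
#' @param ped sorted pedigree.
#' @param founder_haps founder haplotype matrix (rows = haplotypes); at
#'   least two per founder.
#' @param map SNP map.
#' @param recomb_rate_cM_per_Mb recombination rate.
#' @param seed RNG seed.
#' @return a [genotype_panel()] over all pedigree animals, with the
#'   haplotype pair matrices attached as attributes `"hap1"`/`"hap2"`.
#' @export
drop_genes <- function(ped, founder_haps, map, recomb_rate_cM_per_Mb = 1,
                       seed = 1L) {
  set.seed(seed)
  check_sorted(ped)
  n <- nrow(ped)
  m <- nrow(map)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  founders <- which(is.na(si) & is.na(di))
  if (2L * length(founders) > nrow(founder_haps))
    stop("need at least two founder haplotypes per founder")
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  H1[founders, ] <- founder_haps[2L * seq_along(founders) - 1L, ]
  H2[founders, ] <- founder_haps[2L * seq_along(founders), ]

  chroms <- unique(map$chrom)
  chr_idx <- lapply(chroms, function(c) which(map$chrom == c))
  chr_len <- vapply(chr_idx, function(ix)
    diff(range(map$pos_bp[ix])) / 1e6, numeric(1))
  chr_pos <- lapply(chr_idx, function(ix) map$pos_bp[ix] / 1e6)

  gamete <- function(h1, h2) {
    g <- integer(m)
    for (c in seq_along(chroms)) {
      ix <- chr_idx[[c]]
      nx <- rpois(1L, chr_len[c] * recomb_rate_cM_per_Mb / 100)
      cur <- sample(c(1L, 2L), 1L)
      if (nx == 0L) {
        g[ix] <- if (cur == 1L) h1[ix] else h2[ix]
      } else {
        br <- sort(runif(nx, min(chr_pos[[c]]), max(chr_pos[[c]])))
        seg <- findInterval(chr_pos[[c]], br)
        use1 <- ((seg %% 2L) == 0L) == (cur == 1L)  # alternates per crossover
        g[ix] <- ifelse(use1, h1[ix], h2[ix])
      }
    }
    g
  }
  pool_gamete <- function() founder_haps[sample(nrow(founder_haps), 1L), ]

  for (i in setdiff(seq_len(n), founders)) {
    H1[i, ] <- if (!is.na(si[i])) gamete(H1[si[i], ], H2[si[i], ])
               else pool_gamete()
    H2[i, ] <- if (!is.na(di[i])) gamete(H1[di[i], ], H2[di[i], ])
               else pool_gamete()
  }
  calls <- H1 + H2
  rownames(calls) <- ped$animal
  panel <- genotype_panel(calls, map)
  attr(panel, "hap1") <- H1
  attr(panel, "hap2") <- H2
  panel
}

#' Allele substitution effect for a target variance fraction
#'
#' Inverts the explained-variance identity: for the realised causal-locus
#' frequency `f`, returns `alpha = sqrt(fraction * sigma2_g / (2 f (1-f)))`
#' so that `alpha^2 2 f (1-f) / sigma2_g = fraction` exactly.
#'
#' @param panel genotype panel.
#' @param causal_index causal SNP column.
#' @param sigma2_g total genetic variance.
#' @param fraction target variance fraction in `[0, 1)`.
#' @return alpha (trait units per allele copy).
#' @export
scale_causal_effect <- function(panel, causal_index, sigma2_g, fraction) {
  if (fraction == 0) return(0)
  f <- allele_freq(panel$calls[, causal_index])
  if (f <= 0 || f >= 1) stop("causal locus is monomorphic")
  sqrt(fraction * sigma2_g / (2 * f * (1 - f)))
}

#' Somatic cell count to somatic cell score
#'
#' `SCS = log2(SCC / base) + 3` with base 100 (thousand cells/mL).
#'
#' @param scc somatic cell count (positive).
#' @param base reference count (default 100).
#' @return the score.
#' @export
scc_to_scs <- function(scc, base = 100) {
  if (any(scc <= 0)) stop("SCC must be positive")
  log2(scc / base) + 3
}

#' Repeatability-model phenotypes for females
#'
#' Forward simulation of `y = mu + herd-year + g + p + e` per female and
#' lactation, with `p ~ N(0, sigma2_p)` per animal and
#' `e ~ N(0, sigma2_e)` per record; variances derive from `h2` and `rep`.
#'
#' @param ped sorted pedigree.
#' @param true_bv named vector of true breeding values.
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return a [phenotype_table()] with a `hy` fixed factor; herd-year
#'   effects attached as attribute `"hy_effects"`.
#' @export
assign_phenotypes <- function(ped, true_bv, config, seed = 1L) {
  set.seed(seed)
  vp <- config$sigma2_pheno
  s2p <- config$rep * vp
  s2e <- (1 - config$h2 - config$rep) * vp
  females <- ped$animal[!is.na(ped$sex) & ped$sex == "F"]
  nf <- length(females)
  hy_eff <- rnorm(config$n_herds, 0, config$herd_sd_frac * sqrt(vp))
  herd <- sample.int(config$n_herds, nf, replace = TRUE)
  pe <- rnorm(nf, 0, sqrt(s2p))
  rec <- expand.grid(fi = seq_len(nf), parity = seq_len(config$n_lactations))
  y <- config$mu + hy_eff[herd[rec$fi]] + true_bv[females[rec$fi]] +
    pe[rec$fi] + rnorm(nrow(rec), 0, sqrt(s2e))
  out <- phenotype_table(females[rec$fi], as.numeric(y),
                         parity = rec$parity,
                         fixed = data.frame(hy = herd[rec$fi]),
                         trait = "trait")
  attr(out, "hy_effects") <- hy_eff
  out
}

# Hierarchical AI mating structure; returns a pedigree.
.breed_pedigree <- function(config) {
  id <- function(g, k) sprintf("G%d_%04d", g, k)
  animal <- id(0L, seq_len(config$n_founders))
  sex <- c(rep("M", config$founder_males),
           rep("F", config$n_founders - config$founder_males))
  sire <- dam <- rep(NA_character_, config$n_founders)
  year <- rep(2000L, config$n_founders)
  gen <- rep(0L, config$n_founders)
  for (g in seq_len(config$n_generations)) {
    prev <- gen == g - 1L
    males <- animal[prev & sex == "M"]
    females <- animal[prev & sex == "F"]
    sires <- sample(males, min(config$n_sires_per_gen, length(males)))
    k <- 0L
    for (s in sires) {
      dams <- sample(females, config$n_dams_per_sire, replace = TRUE)
      for (dm in dams) {
        k <- k + 1L
        animal <- c(animal, id(g, k))
        sire <- c(sire, s)
        dam <- c(dam, dm)
        sex <- c(sex, sample(c("M", "F"), 1L))
        year <- c(year, 2000L + g)
        gen <- c(gen, g)
      }
    }
  }
  ped <- pedigree(animal, sire, dam, year, sex)
  attr(ped, "generation") <- gen[match(ped$animal, animal)]
  ped
}

#' Simulate a complete study population
#'
#' Breeds the pedigree, drops LD-structured founder haplotypes through it,
#' pins the causal-locus founder frequency, scales the causal effect to the
#' configured variance fraction, and builds true breeding values from the
#' genome itself: normal effects at every background marker plus the causal
#' term, so Mendelian sampling is the one implied by the dropped gametes
#' and marker-based evaluations have genuine signal to recover.
#' Repeatability-model phenotypes are generated for females. Males are the
#' genotyped cohort; the sires of the last generation are the validation
#' cohort (their daughters are the last generation's phenotyped females).
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; the dataset is reproducible bit-for-bit.
#' @return object of class `"synthetic_dataset"`: list with `pedigree`,
#'   `panel` (all animals), `genotyped_ids`, `causal_index`, `causal_snp`,
#'   `alpha`, `true_bv`, `phenotypes`, `validation_ids`, `dyd_true`,
#'   `varcomp_true`, `config`.
#' @export
simulate_population <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  ped <- .breed_pedigree(config)
  map <- make_map(config$n_snps, config$n_chromosomes,
                  config$snp_spacing_mb)
  n_founders <- sum(is.na(ped$sire) & is.na(ped$dam))
  freqs <- runif(config$n_snps, config$maf_floor, 1 - config$maf_floor)
  freqs[config$causal_index] <- config$causal_maf_target
  haps <- simulate_founder_haplotypes(2L * n_founders, map,
                                      config$founder_ld_rho,
                                      config$maf_floor,
                                      seed = seed + 1L, freqs = freqs)
  panel <- drop_genes(ped, haps, map, config$recomb_rate_cM_per_Mb,
                      seed = seed + 2L)

  vp <- config$sigma2_pheno
  s2g <- config$h2 * vp
  frac <- config$causal_variance_fraction
  alpha <- scale_causal_effect(panel, config$causal_index, s2g, frac)
  s2poly <- (1 - frac) * s2g

  # polygenic values are carried by the genome: normal effects at every
  # non-causal marker, rescaled so the founder-base polygenic variance is
  # exactly (1 - fraction) * sigma2_g; gene dropping then gives each
  # descendant the Mendelian-sampling deviation its gametes imply
  set.seed(seed + 3L)
  n <- nrow(ped)
  founders <- which(is.na(ped$sire) & is.na(ped$dam))
  bg <- setdiff(seq_len(config$n_snps), config$causal_index)
  u <- rnorm(length(bg))
  Mbg <- panel$calls[, bg, drop = FALSE]
  poly_raw <- as.numeric(Mbg %*% u)
  v0 <- var(poly_raw[founders])
  scale_u <- if (v0 > 0 && s2poly > 0) sqrt(s2poly / v0) else 0
  poly <- (poly_raw - mean(poly_raw[founders])) * scale_u
  fq <- allele_freq(panel$calls[founders, config$causal_index])
  causal_dev <- panel$calls[, config$causal_index] - 2 * fq
  true_bv <- setNames(poly + alpha * causal_dev, ped$animal)
  snp_effects_true <- setNames(rep(0, config$n_snps), panel$map$snp_id)
  snp_effects_true[bg] <- u * scale_u
  snp_effects_true[config$causal_index] <- alpha

  phen <- assign_phenotypes(ped, true_bv, config, seed = seed + 4L)

  gen <- attr(ped, "generation")
  genotyped <- ped$animal[!is.na(ped$sex) & ped$sex == "M"]
  last <- ped$animal[gen == config$n_generations]
  validation <- unique(ped$sire[ped$animal %in% last])
  validation <- validation[!is.na(validation)]

  structure(list(
    pedigree = ped, panel = panel, genotyped_ids = genotyped,
    causal_index = config$causal_index,
    causal_snp = panel$map$snp_id[config$causal_index],
    alpha = alpha, true_bv = true_bv,
    snp_effects_true = snp_effects_true, phenotypes = phen,
    validation_ids = validation,
    dyd_true = setNames(true_bv[validation], validation),
    varcomp_true = variance_components(s2g,
                                       (1 - config$h2 - config$rep) * vp,
                                       config$rep * vp),
    config = config, seed = seed), class = "synthetic_dataset")
}

#' @export
#' @method print synthetic_dataset
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("synthetic_dataset: %d animals, %d SNPs, causal locus %s",
                     " (alpha = %.3f), %d phenotype records, %d validation sires\n"),
              nrow(x$pedigree), nrow(x$panel$map), x$causal_snp, x$alpha,
              nrow(x$phenotypes), length(x$validation_ids)))
  invisible(x)
}

#' Training phenotypes (validation daughters withheld)
#'
#' Drops the records of the last generation's females — the validation
#' sires' daughters — so their information cannot reach the sires' EBVs.
#'
#' @param dataset a [simulate_population()] result.
#' @return a phenotype table.
#' @export
training_phenotypes <- function(dataset) {
  gen <- attr(dataset$pedigree, "generation")
  last <- dataset$pedigree$animal[gen == dataset$config$n_generations]
  out <- dataset$phenotypes[!dataset$phenotypes$animal %in% last, ,
                            drop = FALSE]
  attr(out, "trait") <- attr(dataset$phenotypes, "trait")
  attr(out, "fixed") <- attr(dataset$phenotypes, "fixed")
  class(out) <- class(dataset$phenotypes)
  out
}

#' Marker panel of the genotyped animals
#'
#' @param dataset a [simulate_population()] result.
#' @param include_causal keep the causal SNP among the markers? With
#'   `FALSE` (default) the chip mimics a panel that does not carry the
#'   causal mutation.
#' @param ids animals to keep (default: the genotyped males).
#' @return a [genotype_panel()].
#' @export
marker_panel <- function(dataset, include_causal = FALSE,
                         ids = dataset$genotyped_ids) {
  snps <- seq_len(nrow(dataset$panel$map))
  if (!include_causal) snps <- snps[-dataset$causal_index]
  panel_subset(dataset$panel, ids = ids, snps = snps)
}

#' Mask a locus and restore it with a pluggable imputation rule
#'
#' Masks the locus in `floor(fraction_masked * n)` randomly chosen animals
#' and fills the gap with an imputation rule (default: rounded parental
#' mean, falling back to the rounded population mean), then scores the
#' result with the allele-level concordance rate.
#'
#' @param panel genotype panel.
#' @param locus SNP id or column index.
#' @param fraction_masked fraction of animals to mask, in (0, 1).
#' @param ped optional pedigree for the parental-mean rule.
#' @param imputer optional `function(panel, locus_col, masked_idx)`
#'   returning imputed calls for the masked animals.
#' @param seed RNG seed.
#' @return list with `true_calls`, `imputed_calls`, `masked_ids`,
#'   `n_errors` (allele mismatches) and `cr` (concordance rate).
#' @export
mask_and_restore <- function(panel, locus, fraction_masked = 1 / 3,
                             ped = NULL, imputer = NULL, seed = 1L) {
  if (fraction_masked <= 0 || fraction_masked >= 1)
    stop("fraction_masked must be in (0, 1)")
  set.seed(seed)
  j <- if (is.character(locus)) match(locus, panel$map$snp_id) else locus
  n <- length(panel$ids)
  n_mask <- floor(fraction_masked * n)
  masked_idx <- sort(sample.int(n, n_mask))
  truth <- panel$calls[masked_idx, j]
  if (is.null(imputer)) {
    p <- allele_freq(panel$calls[, j])
    imputed <- vapply(masked_idx, function(i) {
      if (!is.null(ped)) {
        row <- match(panel$ids[i], ped$animal)
        par <- c(ped$sire[row], ped$dam[row])
        par <- par[!is.na(par) & par %in% panel$ids]
        if (length(par))
          return(round(mean(panel$calls[par, j], na.rm = TRUE)))
      }
      round(2 * p)
    }, numeric(1))
  } else {
    imputed <- imputer(panel, j, masked_idx)
  }
  n_err <- sum(abs(imputed - truth))
  list(true_calls = truth, imputed_calls = imputed,
       masked_ids = panel$ids[masked_idx], n_errors = n_err,
       cr = concordance_rate(n_err, n_mask))
}
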