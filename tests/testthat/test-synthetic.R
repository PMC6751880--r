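test_that("founder haplotypes: independence limit and monotone LD decay", {
  H0 <- simulate_founder_haplotypes(2000, make_map(80, 1), rho = 0, seed = 2)
  expect_lt(abs(mean_adjacent_r2(H0)), 0.02)

  H9 <- simulate_founder_haplotypes(2000, make_map(80, 1), rho = 0.9,
                                    seed = 2)
  lag_r2 <- function(H, lag) {
    mean(vapply(seq_len(ncol(H) - lag), function(j)
      cor(H[, j], H[, j + lag])^2, numeric(1)))
  }
  expect_gt(lag_r2(H9, 1), lag_r2(H9, 5))  # monotone decay on average
  expect_error(simulate_founder_haplotypes(10, 5, rho = 1), "rho")
})

test_that("the default rho is calibrated to adjacent r2 of about 0.25", {
  H <- simulate_founder_haplotypes(2000, make_map(300, 1),
                                   rho = sim_config()$founder_ld_rho,
                                   seed = 4)
  expect_equal(mean_adjacent_r2(H), 0.25, tolerance = 0.05 / 0.25)
})

test_that("gene dropping is Mendelian at every locus", {
  d <- tiny_dataset()
  ped <- d$pedigree
  calls <- d$panel$calls
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  for (i in which(!is.na(si) & !is.na(di))) {
    kid <- calls[i, ]
    s <- calls[si[i], ]
    dm <- calls[di[i], ]
    # a parent homozygote forces at least one matching allele in the child
    expect_true(all(kid[s == 0 & dm == 0] == 0))
    expect_true(all(kid[s == 2 & dm == 2] == 2))
    expect_true(all(kid[s == 2 & dm == 0] == 1))
    expect_true(all(kid[s == 0] <= 1))
    expect_true(all(kid[s == 2] >= 1))
  }
})

test_that("zero recombination transmits unrecombined parental haplotypes", {
  ped <- trio_pedigree()
  haps <- simulate_founder_haplotypes(4, make_map(40, 1), rho = 0.5,
                                      seed = 9)
  pan <- drop_genes(ped, haps, make_map(40, 1),
                    recomb_rate_cM_per_Mb = 0, seed = 1)
  kid1 <- attr(pan, "hap1")[3, ]
  expect_true(any(vapply(1:2, function(h)
    all(kid1 == attr(pan, "hap1")[1, ]) ||
      all(kid1 == attr(pan, "hap2")[1, ]), logical(1))))
})

test_that("causal effect scaling inverts the explained-variance identity", {
  d <- tiny_dataset()
  expect_equal(scale_causal_effect(d$panel, 1, 1, 0), 0)
  # f = 0.5, sigma2_g = 1, fraction = 0.5 -> alpha = 1
  calls <- matrix(rep(c(0L, 2L), 50), ncol = 1,
                  dimnames = list(paste0("a", 1:100), "s"))
  pan <- genotype_panel(calls, data.frame(snp_id = "s", chrom = 1,
                                          pos_bp = 1L))
  expect_equal(scale_causal_effect(pan, 1, 1, 0.5), 1)
  # f = 0.2, fraction = 0.12 -> sqrt(0.12 / 0.32)
  calls2 <- matrix(as.integer(c(rep(1, 40), rep(0, 60))), ncol = 1,
                   dimnames = list(paste0("a", 1:100), "s"))
  pan2 <- genotype_panel(calls2, data.frame(snp_id = "s", chrom = 1,
                                            pos_bp = 1L))
  expect_equal(scale_causal_effect(pan2, 1, 1, 0.12), sqrt(0.12 / 0.32),
               tolerance = 1e-10)
  mono <- genotype_panel(matrix(0L, 4, 1,
                                dimnames = list(paste0("a", 1:4), "s")),
                         data.frame(snp_id = "s", chrom = 1, pos_bp = 1L))
  expect_error(scale_causal_effect(mono, 1, 1, 0.1), "monomorphic")
})

test_that("realized causal fraction and phenotypic variance match the config", {
  cfg <- sim_config(n_founders = 700, founder_males = 60, n_generations = 2,
                    n_sires_per_gen = 20, n_dams_per_sire = 33,
                    n_snps = 150, n_chromosomes = 1, n_lactations = 2,
                    n_herds = 10)
  d <- simulate_population(cfg, seed = 8)
  f <- allele_freq(d$panel$calls[, d$causal_index])
  frac <- d$alpha^2 * 2 * f * (1 - f) / var(d$true_bv)
  expect_equal(frac, 0.12, tolerance = 0.03 / 0.12)
  # var(true_bv) within 20% of configured sigma2_g
  expect_equal(var(d$true_bv), d$varcomp_true$sigma2_g, tolerance = 0.2)
  # realized phenotypic variance within 10% of the configured total
  # (includes the fixed herd-year spread)
  vres <- var(d$phenotypes$value) -
    var(attr(d$phenotypes, "hy_effects"))
  expect_equal(vres, cfg$sigma2_pheno, tolerance = 0.12)
})

test_that("offspring true BV regresses on mid-parent with slope about 1", {
  cfg <- sim_config(n_founders = 700, founder_males = 60, n_generations = 3,
                    n_sires_per_gen = 20, n_dams_per_sire = 33,
                    n_snps = 60, n_chromosomes = 1, n_lactations = 1,
                    n_herds = 5)
  d <- simulate_population(cfg, seed = 12)
  ped <- d$pedigree
  both <- !is.na(ped$sire) & !is.na(ped$dam)
  mid <- 0.5 * (d$true_bv[ped$sire[both]] + d$true_bv[ped$dam[both]])
  off <- d$true_bv[ped$animal[both]]
  b <- coef(lm(off ~ mid))[2]
  expect_equal(unname(b), 1, tolerance = 0.1)
})

test_that("noiseless limit: records equal mu + true BV exactly", {
  cfg <- tiny_config(h2 = 1 - 1e-9, rep = 0, herd_sd_frac = 0)
  d <- simulate_population(cfg, seed = 5)
  expect_equal(d$phenotypes$value,
               unname(cfg$mu + d$true_bv[d$phenotypes$animal]),
               tolerance = 1e-3)
})

test_that("SCC to SCS transform", {
  expect_equal(scc_to_scs(100), 3)
  expect_equal(scc_to_scs(200), 4)
  expect_equal(scc_to_scs(50), 2)
  expect_error(scc_to_scs(0), "positive")
})

test_that("mask_and_restore masks floor(fraction x n) and scores CR", {
  d <- tiny_dataset()
  pan <- panel_subset(d$panel, ids = d$panel$ids[1:150])
  mr <- mask_and_restore(pan, d$causal_index, 1 / 3, ped = d$pedigree,
                         seed = 2)
  expect_equal(length(mr$masked_ids), 50L)
  expect_equal(mr$cr, concordance_rate(mr$n_errors, 50))

  oracle <- function(panel, j, idx) panel$calls[idx, j]
  expect_equal(mask_and_restore(pan, 1, 0.5, imputer = oracle, seed = 1)$cr,
               1)
  all2 <- genotype_panel(matrix(2L, 30, 1,
                                dimnames = list(paste0("x", 1:30), "s")),
                         data.frame(snp_id = "s", chrom = 1, pos_bp = 1L))
  zero <- function(panel, j, idx) rep(0, length(idx))
  expect_equal(mask_and_restore(all2, 1, 0.5, imputer = zero, seed = 1)$cr,
               0)
  # one third of 4296 genotypes -> 1432 masked
  expect_equal(floor(4296 / 3), 1432L)
})

test_that("a fixed seed reproduces the dataset bit-for-bit", {
  d1 <- simulate_population(tiny_config(), seed = 42)
  d2 <- simulate_population(tiny_config(), seed = 42)
  expect_identical(d1$panel$calls, d2$panel$calls)
  expect_identical(d1$true_bv, d2$true_bv)
  expect_identical(d1$phenotypes$value, d2$phenotypes$value)
  d3 <- simulate_population(tiny_config(), seed = 43)
  expect_false(identical(d1$phenotypes$value, d3$phenotypes$value))
})
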