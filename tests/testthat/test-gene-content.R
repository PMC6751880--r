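test_that("gene-content vector maps genotyped calls and missingness", {
  d <- tiny_dataset()
  pan <- panel_subset(d$panel, ids = d$genotyped_ids)
  yT <- gene_content_vector(pan, d$causal_snp, ped = d$pedigree)
  expect_equal(length(yT), nrow(d$pedigree))
  expect_true(all(is.na(yT[setdiff(d$pedigree$animal, pan$ids)])))
  expect_equal(unname(yT[pan$ids]),
               unname(as.numeric(pan$calls[, match(d$causal_snp,
                                                   pan$map$snp_id)])))
  expect_error(gene_content_vector(pan, "no_such_snp"), "locus")
})

test_that("sigma2_gT arithmetic, including the imputed-population frequency", {
  expect_equal(sigma2_gT(c(1, 1)), 0.5)                       # f = 0.5
  expect_equal(sigma2_gT(c(0, 0, NA)), 0)                      # f = 0
  # f = 0.14 (the imputed-population minor allele frequency) -> 0.2408
  y <- c(rep(2, 14), rep(0, 86))
  expect_equal(sigma2_gT(y), 0.2408, tolerance = 1e-10)
})

test_that("substitution effect, explained variance and r_g quotients", {
  expect_equal(substitution_effect(0.5, 0.25), 2)
  expect_equal(substitution_effect(0, 0.3), 0)
  expect_equal(substitution_effect(-0.1, 0.2), -0.5)
  expect_error(substitution_effect(0.1, 0), "positive")

  expect_equal(explained_variance(1, 0.5, 1), 0.5)
  expect_equal(explained_variance(0, 0.5, 1), 0)
  expect_error(explained_variance(1, 0.5, 0), "positive")

  expect_equal(genetic_correlation(0.3, 1, 0.3), 1)
  expect_equal(genetic_correlation(0, 1, 1), 0)
  expect_equal(genetic_correlation(-0.06, 1, 0.3), -0.2)
  expect_warning(genetic_correlation(2, 1, 1), "\\[-1, 1\\]")
})

test_that("explained variance equals r_g squared from shared estimates", {
  for (seed in 1:5) {
    set.seed(seed)
    sg <- runif(1, 0.2, 2)
    sT <- runif(1, 0.05, 0.5)
    cv <- runif(1, -1, 1) * sqrt(sg * sT) * 0.9
    al <- substitution_effect(cv, sT)
    ev <- explained_variance(al, sT, sg)
    rg <- genetic_correlation(cv, sqrt(sg), sqrt(sT))
    expect_equal(ev, rg^2, tolerance = 1e-10)
  }
})

test_that("the EBV decomposition is exact and gT tracks observed dosages", {
  d <- tiny_dataset()
  tr <- training_phenotypes(d)
  pan <- panel_subset(d$panel, ids = d$genotyped_ids)
  yT <- gene_content_vector(pan, d$causal_snp, ped = d$pedigree)
  s22 <- sigma2_gT(yT)
  vc <- variance_components_bivariate(
    matrix(c(0.7, d$alpha * s22, d$alpha * s22, s22), 2),
    sigma2_e = 1.3, sigma2_eT = 0.01 * s22, sigma2_p = 0.35)
  sp <- model_spec("trait", fixed = "hy", pe = TRUE, varcomp = vc)
  gc <- fit_gene_content(sp, tr, yT, d$pedigree)
  expect_true(gc$converged)
  # decomposition identity, elementwise exact
  expect_equal(gc$ebv_trait, gc$ebv_polygen + gc$ebv_major,
               tolerance = 1e-12)
  expect_equal(gc$explained_variance, gc$r_g^2, tolerance = 1e-10)
  # with a nearly-zero gene-content residual, genotyped animals' gT
  # shrinks to the observed dosage minus the fitted mean
  obs <- names(yT)[!is.na(yT)]
  expect_gt(cor(gc$ebv_gene_content[obs], yT[obs] - gc$mu_T), 0.99)
})

test_that("a zero-effect locus yields a small substitution effect", {
  devs <- vapply(1:3, function(seed) {
    cfg <- tiny_config(causal_variance_fraction = 0)
    d <- simulate_population(cfg, seed = 30 + seed)
    tr <- training_phenotypes(d)
    yT <- gene_content_vector(panel_subset(d$panel,
                                           ids = d$genotyped_ids),
                              d$causal_snp, ped = d$pedigree)
    sp <- model_spec("trait", fixed = "hy", pe = TRUE)
    vc <- gibbs_bivariate(sp, tr, yT, d$pedigree, chain = 500,
                          burnin = 150, thin = 2, seed = 7)
    vc$alpha
  }, numeric(1))
  # alpha in trait-SD units stays small for a null locus
  expect_lt(median(abs(devs)) / 1.56, 0.35)
})

test_that("genetic trends are linear in the decomposition and flat for alpha = 0", {
  d <- tiny_dataset()
  tr <- training_phenotypes(d)
  pan <- panel_subset(d$panel, ids = d$genotyped_ids)
  yT <- gene_content_vector(pan, d$causal_snp, ped = d$pedigree)
  s22 <- sigma2_gT(yT)
  vc <- variance_components_bivariate(
    matrix(c(0.7, 0.15, 0.15, s22), 2), 1.3, 0.01 * s22, 0.35)
  sp <- model_spec("trait", fixed = "hy", pe = TRUE, varcomp = vc)
  gc <- fit_gene_content(sp, tr, yT, d$pedigree)
  tt <- genetic_trend(gc, d$pedigree, "trait")
  tp <- genetic_trend(gc, d$pedigree, "polygen")
  tm <- genetic_trend(gc, d$pedigree, "major")
  expect_lt(max(abs(tt$mean_ebv - (tp$mean_ebv + tm$mean_ebv))), 1e-10)

  vc0 <- variance_components_bivariate(
    matrix(c(0.7, 0, 0, s22), 2), 1.3, 0.01 * s22, 0.35)
  sp0 <- model_spec("trait", fixed = "hy", pe = TRUE, varcomp = vc0)
  gc0 <- fit_gene_content(sp0, tr, yT, d$pedigree)
  t0 <- genetic_trend(gc0, d$pedigree, "major")
  expect_equal(t0$mean_ebv, rep(0, nrow(t0)), tolerance = 1e-10)
})
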