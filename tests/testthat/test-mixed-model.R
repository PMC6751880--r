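vc1 <- variance_components(sigma2_g = 0.6, sigma2_e = 1.4, sigma2_p = 0.3)

test_that("unrelated single-record animals give the closed-form shrinkage", {
  # n founders, one record each, mean-only model:
  # mu_hat = ybar, g_i = (y_i - ybar) * sigma2_g / (sigma2_g + sigma2_e)
  set.seed(1)
  ped <- pedigree(paste0("a", 1:12))
  y <- rnorm(12, 5, 1)
  ph <- phenotype_table(ped$animal, y)
  sp <- model_spec("t", pe = FALSE,
                   varcomp = variance_components(0.5, 1.5))
  r <- fit(sp, ph, ped)
  expect_equal(unname(r$fixed), mean(y), tolerance = 1e-8)
  expect_equal(unname(r$ebv), (y - mean(y)) * 0.5 / 2, tolerance = 1e-8)
})

test_that("EBVs vanish as the genetic variance goes to zero", {
  d <- tiny_dataset()
  sp <- model_spec("trait", fixed = "hy", pe = TRUE,
                   varcomp = variance_components(1e-8, 1.4, 0.3))
  r <- fit(sp, training_phenotypes(d), d$pedigree)
  expect_lt(max(abs(r$ebv)), 1e-6)
})

test_that("PCG matches a dense direct solve on mixed fixtures", {
  for (seed in 1:4) {
    ped <- random_pedigree(60, seed = seed)
    set.seed(seed + 100)
    ids <- sample(ped$animal, 40)
    ph <- phenotype_table(rep(ids, 2), rnorm(80, 3),
                          fixed = data.frame(hy = sample(3, 80, TRUE)))
    attr(ph, "fixed") <- "hy"
    sp <- model_spec("t", fixed = "hy", pe = TRUE, varcomp = vc1)
    sys <- build_mme(sp, ph, ped, a_inverse(ped))
    sol <- solve_pcg(sys)
    expect_true(sol$converged)
    expect_lt(max(abs(sol$x - solve(as.matrix(sys$C), sys$rhs))), 1e-8)
  }
})

test_that("solutions are invariant to record order", {
  d <- tiny_dataset()
  tr <- training_phenotypes(d)
  sp <- model_spec("trait", fixed = "hy", pe = TRUE,
                   varcomp = d$varcomp_true)
  r1 <- fit(sp, tr, d$pedigree)
  set.seed(2)
  perm <- sample(nrow(tr))
  tr2 <- tr[perm, , drop = FALSE]
  attr(tr2, "trait") <- attr(tr, "trait")
  attr(tr2, "fixed") <- attr(tr, "fixed")
  class(tr2) <- class(tr)
  r2 <- fit(sp, tr2, d$pedigree)
  expect_equal(r1$ebv, r2$ebv, tolerance = 1e-7)
})

test_that("duplicating every record keeps the EBV ranking and adds accuracy", {
  d <- tiny_dataset()
  tr <- training_phenotypes(d)
  sp <- model_spec("trait", fixed = "hy", pe = TRUE,
                   varcomp = d$varcomp_true)
  r1 <- fit(sp, tr, d$pedigree)
  tr2 <- rbind(as.data.frame(tr), as.data.frame(tr))
  tr2 <- phenotype_table(tr2$animal, tr2$value, tr2$parity,
                         fixed = tr2["hy"], trait = "trait")
  r2 <- fit(sp, tr2, d$pedigree)
  phen_ids <- unique(tr$animal)
  expect_gt(cor(r1$ebv[phen_ids], r2$ebv[phen_ids], method = "spearman"),
            0.99)
  expect_gte(cor(r2$ebv[phen_ids], d$true_bv[phen_ids]),
             cor(r1$ebv[phen_ids], d$true_bv[phen_ids]) - 0.02)
})

test_that("a bivariate fit with diagonal G0 reduces to the single-trait fit", {
  d <- tiny_dataset()
  tr <- training_phenotypes(d)
  yT <- gene_content_vector(panel_subset(d$panel, ids = d$genotyped_ids),
                            d$causal_snp, ped = d$pedigree)
  s22 <- sigma2_gT(yT)
  vc_b <- variance_components_bivariate(diag(c(0.6, s22)), sigma2_e = 1.4,
                                        sigma2_eT = 0.01 * s22,
                                        sigma2_p = 0.3)
  spb <- model_spec("trait", fixed = "hy", pe = TRUE, varcomp = vc_b)
  gc <- fit_gene_content(spb, tr, yT, d$pedigree)
  sp1 <- model_spec("trait", fixed = "hy", pe = TRUE, varcomp = vc1)
  r1 <- fit(sp1, tr, d$pedigree)
  expect_lt(max(abs(gc$ebv_trait - r1$ebv)), 1e-6)
})

test_that("noiseless data are fitted exactly", {
  cfg <- tiny_config(h2 = 1 - 1e-9, rep = 0, herd_sd_frac = 0)
  d <- simulate_population(cfg, seed = 6)
  ph <- d$phenotypes
  sp <- model_spec("trait", pe = FALSE,
                   varcomp = variance_components(d$varcomp_true$sigma2_g,
                                                 1e-6))
  r <- fit(sp, ph, d$pedigree, tol = 1e-12)
  phen <- unique(ph$animal)
  expect_gt(cor(r$ebv[phen], d$true_bv[phen]), 0.99)
  yd <- yield_deviation(ph, r)
  expect_gt(cor(yd[phen], d$true_bv[phen]), 0.99)
})

test_that("yield deviations subtract the fitted fixed part (and PE)", {
  ped <- pedigree(c("m", "a"), sire = c(NA, "m"))
  ph <- phenotype_table(c("a", "a"), c(4, 6))
  sp <- model_spec("t", pe = FALSE, varcomp = variance_components(1, 1))
  r <- fit(sp, ph, ped)
  yd <- yield_deviation(ph, r)
  expect_equal(unname(yd["a"]), 5 - unname(r$fixed), tolerance = 1e-8)
  # identical records: the average equals either record's deviation
  expect_equal(unname(yd["a"]),
               4 - unname(r$fixed) + 1, tolerance = 1e-8)
})

test_that("DYD arithmetic: mate adjustment and daughter threshold", {
  ped <- pedigree(c("s", "d1", "o1"), sire = c(NA, NA, "s"),
                  dam = c(NA, NA, "d1"))
  fake <- list(ebv = setNames(c(0, 0, 0), ped$animal))
  # single daughter, YD = 1, dam EBV = 0 -> DYD = 2
  out <- dyd(ped, setNames(1, "o1"), fake, "s", min_daughters = 1)
  expect_equal(unname(out["s"]), 2)
  # daughters' YD all equal to half the dam EBV -> DYD = 0
  fake$ebv["d1"] <- 0.8
  out <- dyd(ped, setNames(0.4, "o1"), fake, "s", min_daughters = 1)
  expect_equal(unname(out["s"]), 0)
  # below the daughter threshold: excluded
  out <- dyd(ped, setNames(1, "o1"), fake, "s", min_daughters = 10)
  expect_equal(attr(out, "excluded"), "s")
})

test_that("noiseless DYDs track sire true breeding values", {
  cfg <- tiny_config(n_founders = 120, founder_males = 10, h2 = 0.95,
                     rep = 0, n_dams_per_sire = 12, n_lactations = 2,
                     herd_sd_frac = 0)
  d <- simulate_population(cfg, seed = 10)
  sp <- model_spec("trait", pe = FALSE,
                   varcomp = variance_components(d$varcomp_true$sigma2_g,
                                                 max(d$varcomp_true$sigma2_e,
                                                     1e-4)))
  r <- fit(sp, d$phenotypes, d$pedigree)
  yd <- yield_deviation(d$phenotypes, r)
  sires <- d$validation_ids
  out <- dyd(d$pedigree, yd, r, sires, min_daughters = 3)
  out <- out[!is.na(out)]
  expect_gt(cor(out, d$true_bv[names(out)]), 0.8)
})

test_that("H relationship without genotypes is an error", {
  d <- tiny_dataset()
  sp <- model_spec("trait", fixed = "hy", pe = TRUE, relationship = "H",
                   varcomp = d$varcomp_true)
  expect_error(fit(sp, training_phenotypes(d), d$pedigree), "no genotypes")
})
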