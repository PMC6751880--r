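test_that("window statistics match hand computation", {
  raw <- c(1, 3, 2, 2)
  expect_equal(window_weights(raw, "mean", 2), c(2, 2, 2, 2))
  expect_equal(window_weights(raw, "max", 2), c(3, 3, 2, 2))
  expect_equal(window_weights(raw, "sum", 2), c(4, 4, 4, 4))
  expect_equal(window_weights(raw, "classical", 2), raw)
  expect_error(window_weights(raw, "mean", 0), "positive")
})

test_that("windows never cross chromosomes; trailing windows stand alone", {
  map <- data.frame(snp_id = paste0("s", 1:5), chrom = c(1, 1, 1, 2, 2),
                    pos_bp = c(1, 2, 3, 1, 2))
  raw <- c(1, 5, 3, 10, 2)
  # chr1: windows (1,5) and trailing (3); chr2: (10,2)
  expect_equal(window_weights(raw, "max", 2, map), c(5, 5, 3, 10, 10))
  expect_equal(window_weights(raw, "sum", 2, map), c(6, 6, 3, 12, 12))
})

test_that("normalisation conserves the SNP count and is idempotent", {
  expect_equal(normalize_weights(c(3, 3, 2, 2)), c(1.2, 1.2, 0.8, 0.8))
  expect_equal(normalize_weights(rep(4, 6)), rep(1, 6))
  w <- normalize_weights(runif(20))
  expect_equal(normalize_weights(w), w, tolerance = 1e-12)
  expect_equal(sum(normalize_weights(c(0, 0, 5))), 3, tolerance = 1e-9)
  expect_error(normalize_weights(c(0, 0)), "all-zero")
})

test_that("back-solved effects satisfy the projection identity", {
  set.seed(5)
  m <- 80; ng <- 25
  calls <- matrix(rbinom(ng * m, 2, 0.4), ng, m,
                  dimnames = list(paste0("a", seq_len(ng)), NULL))
  pan <- genotype_panel(calls, make_map(m, 1))
  ghat <- rnorm(ng)
  # external frequencies keep Z full row rank
  eff <- backsolve_snp_effects(ghat, pan, freqs = rep(0.4, m))
  Z <- center_genotypes(pan, rep(0.4, m))$Z
  expect_lt(max(abs(as.numeric(Z %*% eff$a_hat) - ghat)), 1e-8)
  expect_equal(eff$var_explained, eff$a_hat^2 * 2 * 0.4 * 0.6,
               tolerance = 1e-12)
  # zero EBVs give zero effects
  z <- backsolve_snp_effects(rep(0, ng), pan, freqs = rep(0.4, m))
  expect_equal(unname(z$a_hat), rep(0, m))
})

test_that("rank-deficient back-solve matches the least-norm oracle", {
  skip_if_not_installed("MASS")
  set.seed(6)
  m <- 40; ng <- 12
  calls <- matrix(rbinom(ng * m, 2, 0.4), ng, m,
                  dimnames = list(paste0("a", seq_len(ng)), NULL))
  calls[ng, ] <- calls[ng - 1, ]  # duplicated animal: MDM' singular
  pan <- genotype_panel(calls, make_map(m, 1))
  ghat <- rnorm(ng)
  ghat[ng] <- ghat[ng - 1]
  eff <- backsolve_snp_effects(ghat, pan, freqs = rep(0.4, m))
  Z <- center_genotypes(pan, rep(0.4, m))$Z
  S <- tcrossprod(Z)
  oracle <- as.numeric(crossprod(Z, MASS::ginv(S) %*% ghat))
  expect_equal(unname(eff$a_hat), oracle, tolerance = 1e-6)
})

test_that("total explained variance is invariant to allele-coding flips", {
  d <- tiny_dataset()
  pan <- polymorphic_panel(panel_subset(d$panel, ids = d$genotyped_ids))
  ghat <- d$true_bv[pan$ids]
  e1 <- backsolve_snp_effects(ghat, pan)
  flipped <- pan
  flipped$calls[, 5] <- 2L - flipped$calls[, 5]
  e2 <- backsolve_snp_effects(ghat, flipped)
  expect_equal(sum(e1$var_explained), sum(e2$var_explained),
               tolerance = 1e-8)
})

test_that("one iteration is ssGBLUP; equal raw weights keep it that way", {
  d <- tiny_dataset()
  tr <- training_phenotypes(d)
  pan <- polymorphic_panel(panel_subset(d$panel, ids = d$genotyped_ids))
  sp <- model_spec("trait", fixed = "hy", pe = TRUE, relationship = "H",
                   varcomp = d$varcomp_true)
  ss <- fit(sp, tr, d$pedigree, pan)
  w1 <- run_wssgblup(sp, tr, d$pedigree, pan, method = "classical",
                     iterations = 1)
  expect_equal(w1$result$ebv, ss$ebv, tolerance = 1e-10)
  expect_equal(w1$weights, rep(1, nrow(pan$map)))

  # weights conserved at every iteration
  w2 <- run_wssgblup(sp, tr, d$pedigree, pan, method = "mean", n = 10,
                     iterations = 2)
  for (w in w2$weight_trajectory)
    expect_equal(sum(w), nrow(pan$map), tolerance = 1e-6)
})

test_that("qtl_scan merges supra-threshold windows deterministically", {
  map <- make_map(60, 2)
  ve <- rep(0, 60)
  expect_equal(nrow(qtl_scan(ve, map, sigma2_g = 1, window = 20)), 0L)

  # a spike of variance at SNPs 10:12 on chromosome 1
  ve[10:12] <- c(0.004, 0.006, 0.004)
  out <- qtl_scan(ve, map, sigma2_g = 1, window = 20, threshold_pct = 1)
  expect_equal(nrow(out), 1L)
  expect_equal(out$chrom, 1L)
  expect_equal(out$pct_genetic_variance, 1.4, tolerance = 1e-10)
  expect_true(out$start_bp <= map$pos_bp[10] && out$end_bp >= map$pos_bp[12])
  expect_identical(out, qtl_scan(ve, map, 1, 20, 1))

  # threshold zero: one merged region per chromosome with >= 20 SNPs
  all0 <- qtl_scan(rep(1e-9, 60), map, 1, 20, 0)
  expect_equal(nrow(all0), 2L)
  expect_warning(qtl_scan(rep(0, 10), make_map(10, 1), 1, 20), "fewer")
})

test_that("the second iteration recovers the simulated QTL window", {
  d <- tiny_dataset(seed = 21)
  tr <- training_phenotypes(d)
  pan <- polymorphic_panel(panel_subset(d$panel, ids = d$genotyped_ids))
  sp <- model_spec("trait", fixed = "hy", pe = TRUE, relationship = "H",
                   varcomp = d$varcomp_true)
  res <- run_wssgblup(sp, tr, d$pedigree, pan, method = "max", n = 10,
                      iterations = 2)
  ve <- res$effects$var_explained
  # the causal SNP sits in the top decile of explained variance
  causal_col <- match(d$causal_snp, pan$map$snp_id)
  expect_gt(ve[causal_col], quantile(ve, 0.9))
})
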