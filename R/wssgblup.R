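# The weighted single-step loop: back-solve SNP effects from genomic EBVs,
# convert to per-SNP variances, form windowed weights, renormalise, rebuild
# G and H-inverse, re-fit. Two iterations is the default: the first is plain
# ssGBLUP (all weights 1), the second uses the variance-derived weights.

#' Back-solve SNP effects from genomic EBVs
#'
#' \deqn{\hat a = D M' (M D M')^{-1} \hat g_{gen}}
#' with M the centered genotype matrix of the genotyped animals and D the
#' diagonal weight matrix that built G. Per-SNP explained variances are
#' \eqn{\hat\sigma^2_{a,i} = \hat a_i^2\, 2 p_i (1 - p_i)}.
#'
#' @param ghat_gen EBVs of the genotyped animals (named, panel order).
#' @param panel genotype panel of the genotyped animals.
#' @param weights per-SNP weights D (default all 1).
#' @param freqs optional per-SNP allele frequencies.
#' @return object of class `"snp_effects"`: list with `a_hat`,
#'   `var_explained` (both named by SNP), `freqs`, `weights`.
#' @export
backsolve_snp_effects <- function(ghat_gen, panel, weights = NULL,
                                  freqs = NULL) {
  cz <- center_genotypes(panel, freqs)
  Z <- cz$Z
  m <- ncol(Z)
  d <- if (is.null(weights)) rep(1, m) else as.numeric(weights)
  if (length(d) != m) stop("weights length must equal SNP count")
  if (length(ghat_gen) != nrow(Z))
    stop("ghat_gen length must equal number of genotyped animals")
  S <- tcrossprod(sweep(Z, 2, d, "*"), Z)
  # With frequencies computed from the genotyped animals themselves, Z's
  # columns sum to zero and S is singular (null vector 1): use a least-norm
  # solve whenever the direct solve fails or leaves a residual.
  sol <- tryCatch(solve(S, ghat_gen), error = function(e) NULL)
  ok <- !is.null(sol) &&
    max(abs(S %*% sol - ghat_gen)) <= 1e-8 * max(1, max(abs(ghat_gen)))
  if (!ok) {
    sv <- svd(S)
    pos <- sv$d > max(sv$d) * 1e-10
    sol <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], ghat_gen)) / sv$d[pos])
  }
  a <- d * as.numeric(crossprod(Z, sol))
  names(a) <- colnames(Z)
  ve <- a^2 * 2 * cz$p * (1 - cz$p)
  structure(list(a_hat = a, var_explained = ve, freqs = cz$p, weights = d),
            class = "snp_effects")
}

#' Windowed SNP weights
#'
#' Decomposes each chromosome into non-overlapping windows of `n` adjacent
#' SNPs (trailing partial windows keep their own statistic) and assigns
#' every SNP in a window the window's mean, maximum or sum of the raw
#' weights. `"classical"` returns the raw per-SNP weights unchanged.
#'
#' @param raw per-SNP raw weights (typically the explained variances).
#' @param method `"classical"`, `"mean"`, `"max"` or `"sum"`.
#' @param n window size in SNPs (ignored by `"classical"`).
#' @param map SNP map (for chromosome boundaries); windows never cross
#'   chromosomes. May be `NULL` for a single chromosome.
#' @return per-SNP weight vector.
#' @export
window_weights <- function(raw, method = c("classical", "mean", "max", "sum"),
                           n = 1L, map = NULL) {
  method <- match.arg(method)
  if (method == "classical") return(raw)
  if (n <= 0) stop("window size n must be positive")
  chrom <- if (is.null(map)) rep(1L, length(raw)) else map$chrom
  out <- numeric(length(raw))
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    win <- (seq_along(idx) - 1L) %/% n
    stat <- switch(method,
                   mean = tapply(raw[idx], win, mean),
                   max = tapply(raw[idx], win, max),
                   sum = tapply(raw[idx], win, sum))
    out[idx] <- as.numeric(stat)[win + 1L]
  }
  out
}

#' Normalise SNP weights to sum to the number of SNPs
#'
#' Weights are rescaled so that their sum equals the SNP count, floored at
#' `eps` (to keep the weighted G invertible when a window's variance is
#' zero) and rescaled once more.
#'
#' @param w nonnegative weight vector.
#' @param eps weight floor (default 1e-8).
#' @return normalised weights summing to `length(w)`.
#' @export
normalize_weights <- function(w, eps = 1e-8) {
  if (any(w < 0)) stop("weights must be nonnegative")
  s <- sum(w)
  if (s <= 0) stop("cannot normalise an all-zero weight vector")
  w <- w * (length(w) / s)
  w <- pmax(w, eps)
  w * (length(w) / sum(w))
}

#' Run the weighted single-step GBLUP loop
#'
#' Iteration 1 is ssGBLUP (all weights 1). Each later iteration back-solves
#' SNP effects from the previous EBVs with the weights that built the
#' previous G, converts them to explained variances, applies the window
#' method, renormalises, rebuilds G and H-inverse and re-fits. Prediction
#' accuracy peaks at two iterations, the default.
#'
#' @param spec a [model_spec()] (relationship is forced to `"H"`).
#' @param pheno phenotype table.
#' @param ped sorted pedigree.
#' @param panel genotype panel of the genotyped animals.
#' @param method,n window method and size, see [window_weights()].
#' @param iterations number of fits (default 2).
#' @param blend_beta,tol,max_iter,a_inv,a22_mat passed to [fit()].
#' @return list with `result` (final [fit()] output), `effects` (final
#'   [backsolve_snp_effects()]), `weights` (final weight vector) and
#'   `weight_trajectory` (one vector per iteration).
#' @export
run_wssgblup <- function(spec, pheno, ped, panel,
                         method = c("classical", "mean", "max", "sum"),
                         n = 1L, iterations = 2L, blend_beta = 0.05,
                         tol = 1e-10, max_iter = 10000L, a_inv = NULL,
                         a22_mat = NULL) {
  method <- match.arg(method)
  spec$relationship <- "H"
  if (is.null(a_inv)) a_inv <- a_inverse(ped)
  if (is.null(a22_mat)) a22_mat <- a22(ped, panel$ids)
  m <- nrow(panel$map)
  d <- rep(1, m)
  trajectory <- list()
  res <- NULL
  for (it in seq_len(iterations)) {
    if (it > 1L) {
      eff <- backsolve_snp_effects(res$ghat_gen, panel, weights = d)
      d <- normalize_weights(window_weights(eff$var_explained, method, n,
                                            panel$map))
    }
    trajectory[[it]] <- d
    res <- fit(spec, pheno, ped, panel, weights = d,
               blend_beta = blend_beta, tol = tol, max_iter = max_iter,
               a_inv = a_inv, a22_mat = a22_mat)
  }
  effects <- backsolve_snp_effects(res$ghat_gen, panel, weights = d)
  list(result = res, effects = effects, weights = d,
       weight_trajectory = trajectory)
}

#' Scan for QTL regions from per-SNP explained variances
#'
#' Slides a window of `window` adjacent SNPs along each chromosome; a
#' window explaining at least `threshold_pct` percent of the genetic
#' variance is supra-threshold, and overlapping supra-threshold windows are
#' merged into one region reporting the maximal window value. Chromosomes
#' with fewer SNPs than the window are skipped with a warning.
#'
#' @param effects a [backsolve_snp_effects()] result (or a numeric vector
#'   of per-SNP explained variances).
#' @param map SNP map aligned with the effects.
#' @param sigma2_g genetic variance of the trait (the denominator).
#' @param window window size in SNPs (default 20).
#' @param threshold_pct reporting threshold in percent (default 1).
#' @return data frame of class `"qtl_regions"`: `chrom`, `start_bp`,
#'   `end_bp`, `pct_genetic_variance` (maximal window value), `n_snps`,
#'   `peak_start_bp`, `peak_end_bp` (the maximal window's span).
#' @export
qtl_scan <- function(effects, map, sigma2_g, window = 20L,
                     threshold_pct = 1) {
  ve <- if (inherits(effects, "snp_effects")) effects$var_explained
        else as.numeric(effects)
  if (sigma2_g <= 0) stop("sigma2_g must be positive")
  if (length(ve) != nrow(map)) stop("effects/map length mismatch")
  regions <- list()
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    if (length(idx) < window) {
      warning("chromosome ", chr, " has fewer than ", window,
              " SNPs; skipped")
      next
    }
    v <- ve[idx]
    csum <- cumsum(c(0, v))
    nw <- length(idx) - window + 1L
    wsum <- csum[(window + 1L):(length(idx) + 1L)] - csum[1:nw]
    pct <- 100 * wsum / sigma2_g
    supra <- which(pct >= threshold_pct)
    if (!length(supra)) next
    # merge windows whose SNP spans overlap
    grp <- cumsum(c(1L, diff(supra) >= window))
    for (g in unique(grp)) {
      w <- supra[grp == g]
      first <- idx[min(w)]
      last <- idx[max(w) + window - 1L]
      best <- w[which.max(pct[w])]
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = chr,
        start_bp = map$pos_bp[first],
        end_bp = map$pos_bp[last],
        pct_genetic_variance = max(pct[w]),
        n_snps = window,
        peak_start_bp = map$pos_bp[idx[best]],
        peak_end_bp = map$pos_bp[idx[best + window - 1L]])
    }
  }
  out <- if (length(regions)) do.call(rbind, regions)
         else data.frame(chrom = integer(0), start_bp = integer(0),
                         end_bp = integer(0),
                         pct_genetic_variance = numeric(0),
                         n_snps = integer(0), peak_start_bp = integer(0),
                         peak_end_bp = integer(0))
  rownames(out) <- NULL
  class(out) <- c("qtl_regions", "data.frame")
  out
}
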