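# Gibbs samplers for the (co)variance components. Location effects are
# drawn jointly from their multivariate-normal full conditional via a sparse
# Cholesky factorisation whose symbolic analysis is reused across
# iterations (a block implementation); variances are drawn from scaled
# inverse chi-square full conditionals, and the 2x2 genetic (co)variance of
# the bivariate gene-content system from an inverse Wishart (or, when the
# gene-content variance is held at 2f(1-f), from the conditional
# regression/residual factorisation of the fixed-variance row).

# sample theta ~ N(C^{-1} rhs, C^{-1}) using a CHOLMOD factor
.draw_location <- function(Ch, rhs) {
  mu <- as.numeric(solve(Ch, rhs, system = "A"))
  z <- rnorm(length(rhs))
  u <- solve(Ch, solve(Ch, z, system = "Lt"), system = "Pt")
  mu + as.numeric(u)
}

.draw_var <- function(qf, df, nu0, S0) {
  (qf + nu0 * S0) / rchisq(1L, df = df + nu0)
}

#' Gibbs sampler for single-trait variance components
#'
#' Repeatability animal model `y = X beta + Z g + W p + e` with
#' `g ~ N(0, K sigma2_g)`. Alternates a joint draw of all location effects
#' with scaled inverse chi-square draws of `sigma2_g`, `sigma2_p` and
#' `sigma2_e` using the quadratic forms `g' K^{-1} g`, `p'p` and `e'e`.
#' Priors are weakly informative scaled inverse chi-squares with
#' `prior_df` degrees of freedom and scale equal to the starting values
#' (an equal split of the phenotypic variance).
#'
#' @param spec a [model_spec()] (fixed factors and the `pe` switch are
#'   used; its variance components, when present, serve as starting values).
#' @param pheno phenotype table.
#' @param ped sorted pedigree.
#' @param kinv sparse relationship inverse (default: A-inverse of `ped`).
#' @param chain,burnin,thin chain controls (defaults 10000/2000/10).
#' @param seed RNG seed (the chain is reproducible bit-for-bit).
#' @param prior_df prior degrees of freedom (default 4).
#' @return a `variance_components` object whose components are posterior
#'   means, with `samples` (post burn-in, thinned), `posterior_sd`, `ci90`
#'   and chain metadata attached.
#' @export
gibbs_single_trait <- function(spec, pheno, ped, kinv = a_inverse(ped),
                               chain = 10000L, burnin = 2000L, thin = 10L,
                               seed = 1L, prior_df = 4) {
  if (chain <= burnin) stop("chain must exceed burnin")
  set.seed(seed)
  pe <- spec$pe
  des <- .design_single(pheno, ped, fixed = spec$fixed, pe = pe)
  T <- if (pe) cbind(des$X, des$Z, des$W) else cbind(des$X, des$Z)
  TtT <- forceSymmetric(crossprod(T), "U")
  Tty <- as.numeric(crossprod(T, des$y))
  q <- ncol(T)
  npe <- length(des$pe_ids)
  gsel <- des$p + seq_len(des$n)
  pesel <- if (pe) des$p + des$n + seq_len(npe) else integer(0)
  Kx <- bdiag(c(list(Diagonal(des$p, x = 0), kinv),
                if (pe) list(Diagonal(npe, x = 0))))
  Px <- Diagonal(q, x = as.numeric(seq_len(q) %in% pesel))

  vp <- var(des$y)
  ncomp <- if (pe) 3 else 2
  s_g <- if (!is.null(spec$varcomp)) spec$varcomp$sigma2_g else vp / ncomp
  s_p <- if (pe) {
    if (!is.null(spec$varcomp) && !is.null(spec$varcomp$sigma2_p))
      spec$varcomp$sigma2_p else vp / ncomp
  } else NULL
  s_e <- if (!is.null(spec$varcomp)) spec$varcomp$sigma2_e else vp / ncomp
  S0 <- list(g = s_g, p = s_p, e = s_e)

  Ch <- NULL
  keep <- seq(burnin + thin, chain, by = thin)
  samples <- matrix(NA_real_, length(keep), 4,
                    dimnames = list(NULL, c("sigma2_g", "sigma2_p",
                                            "sigma2_e", "h2")))
  k <- 0L
  for (it in seq_len(chain)) {
    C <- forceSymmetric(TtT * (1 / s_e) + Kx * (1 / s_g) +
                          (if (pe) Px * (1 / s_p) else Px * 0), "U")
    if (is.null(Ch)) Ch <- Cholesky(C, LDL = FALSE, perm = TRUE)
    else Ch <- update(Ch, C)
    theta <- .draw_location(Ch, Tty * (1 / s_e))
    g <- theta[gsel]
    s_g <- .draw_var(as.numeric(crossprod(g, kinv %*% g)), des$n,
                     prior_df, S0$g)
    if (pe) {
      pvec <- theta[pesel]
      s_p <- .draw_var(sum(pvec^2), npe, prior_df, S0$p)
    }
    e <- des$y - as.numeric(T %*% theta)
    s_e <- .draw_var(sum(e^2), des$nrec, prior_df, S0$e)
    if (it > burnin && (it - burnin) %% thin == 0L) {
      k <- k + 1L
      sp <- if (pe) s_p else 0
      samples[k, ] <- c(s_g, sp, s_e, s_g / (s_g + sp + s_e))
    }
  }
  samples <- as.data.frame(samples[seq_len(k), , drop = FALSE])
  pm <- colMeans(samples)
  out <- variance_components(pm[["sigma2_g"]], pm[["sigma2_e"]],
                             if (pe) pm[["sigma2_p"]] else NULL)
  out$samples <- samples
  out$posterior_mean <- as.list(pm)
  out$posterior_sd <- as.list(vapply(samples, sd, numeric(1)))
  out$ci90 <- lapply(samples, quantile, probs = c(0.05, 0.95), names = FALSE)
  out$chain_meta <- list(chain = chain, burnin = burnin, thin = thin,
                         seed = seed, prior_df = prior_df)
  class(out) <- c("gibbs_varcomp", class(out))
  out
}

#' Gibbs sampler for the bivariate gene-content model
#'
#' Trait-of-interest records and the 0/1/2 allele count of genotyped
#' animals as a second trait sharing the pedigree covariance through a 2x2
#' genetic (co)variance matrix G0. When `fix_sigma2_gT = TRUE` (default)
#' the gene-content genetic variance is held at `2 f (1 - f)` with `f` the
#' observed allele frequency, and the G0 update draws the regression of the
#' trait's breeding values on the gene-content breeding values together
#' with the conditional (polygenic) variance. The gene-content residual
#' variance is fixed at `0.01 * sigma2_gT` unless `estimate_eT = TRUE`.
#'
#' @param spec a [model_spec()] for the trait of interest.
#' @param pheno phenotype table.
#' @param y_T named vector of gene contents (0/1/2; `NA` for ungenotyped),
#'   see [gene_content_vector()].
#' @param ped sorted pedigree.
#' @param kinv sparse relationship inverse (pedigree A-inverse: the
#'   gene-content model deliberately uses no chip information).
#' @param fix_sigma2_gT hold the gene-content genetic variance at
#'   `2 f (1 - f)`?
#' @param estimate_eT free the gene-content residual variance?
#' @param chain,burnin,thin,seed,prior_df chain controls as in
#'   [gibbs_single_trait()].
#' @return a `variance_components` object with posterior-mean `G0`,
#'   `alpha` (allele substitution effect), `r_g`, `explained_variance`, the
#'   per-sample chain and metadata.
#' @export
gibbs_bivariate <- function(spec, pheno, y_T, ped, kinv = a_inverse(ped),
                            fix_sigma2_gT = TRUE, estimate_eT = FALSE,
                            chain = 10000L, burnin = 2000L, thin = 10L,
                            seed = 1L, prior_df = 4) {
  if (chain <= burnin) stop("chain must exceed burnin")
  set.seed(seed)
  yT_obs <- y_T[!is.na(y_T)]
  if (length(yT_obs) < 2) stop("fewer than 2 genotyped animals")
  f <- mean(yT_obs) / 2
  if (f <= 0 || f >= 1) stop("causal locus monomorphic among genotyped")
  s22_obs <- 2 * f * (1 - f)

  pe <- spec$pe
  des <- .design_single(pheno, ped, fixed = spec$fixed, pe = pe)
  n <- des$n; npe <- length(des$pe_ids); p1 <- des$p
  nT <- length(yT_obs)
  tidx <- match(names(yT_obs), ped$animal)
  zero <- function(nr, nc) sparseMatrix(i = integer(0), j = integer(0),
                                        x = double(0), dims = c(nr, nc))
  T1 <- cbind(des$X, zero(des$nrec, 1L), des$Z, zero(des$nrec, n))
  if (pe) T1 <- cbind(T1, des$W)
  ZT <- sparseMatrix(i = seq_len(nT), j = tidx, x = 1, dims = c(nT, n))
  T2 <- cbind(zero(nT, p1), Matrix(1, nT, 1, sparse = TRUE), zero(nT, n), ZT)
  if (pe) T2 <- cbind(T2, zero(nT, npe))
  T11 <- forceSymmetric(crossprod(T1), "U")
  T22 <- forceSymmetric(crossprod(T2), "U")
  r1 <- as.numeric(crossprod(T1, des$y))
  r2 <- as.numeric(crossprod(T2, c(yT_obs)))
  q <- p1 + 1L + 2L * n + if (pe) npe else 0L
  g1sel <- p1 + 1L + seq_len(n)
  gTsel <- p1 + 1L + n + seq_len(n)
  pesel <- if (pe) p1 + 1L + 2L * n + seq_len(npe) else integer(0)
  Px <- Diagonal(q, x = as.numeric(seq_len(q) %in% pesel))
  pad <- function(K22) bdiag(c(list(Diagonal(p1 + 1L, x = 0), K22),
                               if (pe) list(Diagonal(npe, x = 0))))

  # starting values
  vp <- var(des$y)
  ncomp <- if (pe) 3 else 2
  s11 <- if (!is.null(spec$varcomp)) spec$varcomp$sigma2_g else vp / ncomp
  s_p <- if (pe) vp / ncomp else NULL
  s_e1 <- if (!is.null(spec$varcomp)) spec$varcomp$sigma2_e else vp / ncomp
  s22 <- s22_obs
  cv <- 0.1 * sqrt(s11 * s22)
  s_eT <- if (estimate_eT) 0.01 * s22 else 0.01 * s22
  S0 <- list(cond = s11 * (1 - 0.1^2), e1 = s_e1, p = s_p, eT = s_eT,
             G0 = matrix(c(s11, cv, cv, s22), 2))

  Ch <- NULL
  keep_n <- length(seq(burnin + thin, chain, by = thin))
  cols <- c("sigma2_g", "sigma2_gT", "cov_g_gT", "sigma2_p", "sigma2_e",
            "sigma2_eT", "alpha", "r_g", "explained_variance", "h2")
  samples <- matrix(NA_real_, keep_n, length(cols),
                    dimnames = list(NULL, cols))
  k <- 0L
  for (it in seq_len(chain)) {
    G0 <- matrix(c(s11, cv, cv, s22), 2)
    g0i <- solve(G0)
    K22 <- rbind(cbind(kinv * g0i[1, 1], kinv * g0i[1, 2]),
                 cbind(kinv * g0i[2, 1], kinv * g0i[2, 2]))
    C <- forceSymmetric(T11 * (1 / s_e1) + T22 * (1 / s_eT) + pad(K22) +
                          (if (pe) Px * (1 / s_p) else Px * 0), "U")
    if (is.null(Ch)) {
      Ch <- Cholesky(C, LDL = FALSE, perm = TRUE)
    } else {
      Ch <- tryCatch(update(Ch, C),
                     error = function(e) Cholesky(C, LDL = FALSE,
                                                  perm = TRUE))
    }
    theta <- .draw_location(Ch, r1 * (1 / s_e1) + r2 * (1 / s_eT))
    g1 <- theta[g1sel]
    gT <- theta[gTsel]
    Q <- cbind(g1, gT)
    W2 <- crossprod(Q, as.matrix(kinv %*% Q))
    if (fix_sigma2_gT) {
      # regression/residual factorisation with the (T,T) variance held fixed
      w112 <- W2[1, 1] - W2[1, 2]^2 / W2[2, 2]
      s_cond <- .draw_var(w112, n, prior_df, S0$cond)
      b <- rnorm(1L, W2[1, 2] / W2[2, 2], sqrt(s_cond / W2[2, 2]))
      cv <- b * s22
      s11 <- s_cond + b^2 * s22
    } else {
      V0 <- prior_df * S0$G0
      Wdraw <- rWishart(1L, df = n + prior_df, Sigma = solve(W2 + V0))[, , 1L]
      G0n <- solve(Wdraw)
      s11 <- G0n[1, 1]; s22 <- G0n[2, 2]; cv <- G0n[1, 2]
    }
    if (pe) {
      pvec <- theta[pesel]
      s_p <- .draw_var(sum(pvec^2), npe, prior_df, S0$p)
    }
    e1 <- des$y - as.numeric(T1 %*% theta)
    s_e1 <- .draw_var(sum(e1^2), des$nrec, prior_df, S0$e1)
    if (estimate_eT) {
      eT <- c(yT_obs) - as.numeric(T2 %*% theta)
      s_eT <- .draw_var(sum(eT^2), nT, prior_df, S0$eT)
    }
    if (it > burnin && (it - burnin) %% thin == 0L) {
      k <- k + 1L
      al <- cv / s22
      sp <- if (pe) s_p else 0
      samples[k, ] <- c(s11, s22, cv, sp, s_e1, s_eT, al,
                        cv / sqrt(s11 * s22), al^2 * s22 / s11,
                        s11 / (s11 + sp + s_e1))
    }
  }
  samples <- as.data.frame(samples[seq_len(k), , drop = FALSE])
  pm <- colMeans(samples)
  G0pm <- matrix(c(pm[["sigma2_g"]], pm[["cov_g_gT"]],
                   pm[["cov_g_gT"]], pm[["sigma2_gT"]]), 2)
  out <- variance_components_bivariate(G0pm, pm[["sigma2_e"]],
                                       pm[["sigma2_eT"]],
                                       if (pe) pm[["sigma2_p"]] else NULL)
  out$alpha <- pm[["alpha"]]
  out$r_g <- pm[["r_g"]]
  out$explained_variance <- pm[["explained_variance"]]
  out$freq_T <- f
  out$samples <- samples
  out$posterior_mean <- as.list(pm)
  out$posterior_sd <- as.list(vapply(samples, sd, numeric(1)))
  out$ci90 <- lapply(samples, quantile, probs = c(0.05, 0.95), names = FALSE)
  out$chain_meta <- list(chain = chain, burnin = burnin, thin = thin,
                         seed = seed, prior_df = prior_df,
                         fix_sigma2_gT = fix_sigma2_gT)
  class(out) <- c("gibbs_varcomp", class(out))
  out
}

#' @export
#' @method print gibbs_varcomp
print.gibbs_varcomp <- function(x, ...) {
  cat("Gibbs posterior means:\n")
  for (nm in intersect(c("sigma2_g", "sigma2_gT", "cov_g_gT", "sigma2_p",
                         "sigma2_e"), names(x$posterior_mean)))
    cat(sprintf("  %-10s %.5f\n", nm, x$posterior_mean[[nm]]))
  cat(sprintf("  chain %d, burn-in %d, thin %d, seed %d\n",
              x$chain_meta$chain, x$chain_meta$burnin, x$chain_meta$thin,
              x$chain_meta$seed))
  invisible(x)
}
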