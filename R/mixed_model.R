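# Henderson's mixed-model equations for the four evaluation models:
# single-trait animal model with or without a permanent-environment term
# (repeatability model), and the bivariate system that carries the causal
# locus' allele count as a second trait. Solved by Jacobi-preconditioned
# conjugate gradients. Identifiability of the fixed part uses corner-point
# coding (intercept + treatment contrasts), which leaves EBVs unaffected.

#' Variance components container
#'
#' @param sigma2_g additive genetic variance (trait units squared).
#' @param sigma2_e residual variance.
#' @param sigma2_p permanent-environment variance (`NULL` for single-record
#'   traits).
#' @return an object of class `"variance_components"`.
#' @export
variance_components <- function(sigma2_g, sigma2_e, sigma2_p = NULL) {
  stopifnot(sigma2_g >= 0, sigma2_e > 0, is.null(sigma2_p) || sigma2_p >= 0)
  structure(list(sigma2_g = sigma2_g, sigma2_p = sigma2_p,
                 sigma2_e = sigma2_e), class = "variance_components")
}

#' Bivariate (trait x gene-content) variance components
#'
#' @param G0 2x2 genetic (co)variance matrix; `[1,1]` the trait, `[2,2]` the
#'   gene-content trait.
#' @param sigma2_e trait residual variance.
#' @param sigma2_eT gene-content residual variance (small: gene content is
#'   observed nearly without error).
#' @param sigma2_p permanent-environment variance or `NULL`.
#' @return an object of class `"variance_components"` with a `G0` field.
#' @export
variance_components_bivariate <- function(G0, sigma2_e, sigma2_eT,
                                          sigma2_p = NULL) {
  G0 <- as.matrix(G0)
  stopifnot(all(dim(G0) == 2L), isSymmetric(G0, tol = 1e-10))
  if (min(eigen(G0, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("G0 must be positive definite")
  structure(list(G0 = G0, sigma2_g = G0[1, 1], sigma2_gT = G0[2, 2],
                 cov_g_gT = G0[1, 2], sigma2_p = sigma2_p,
                 sigma2_e = sigma2_e, sigma2_eT = sigma2_eT),
            class = "variance_components")
}

#' Heritability from variance components
#'
#' `h2 = sigma2_g / (sigma2_g + sigma2_p + sigma2_e)`.
#'
#' @param vc a `variance_components` object, or the genetic variance.
#' @param sigma2_p,sigma2_e used when `vc` is numeric.
#' @return the heritability.
#' @export
heritability <- function(vc, sigma2_p = 0, sigma2_e = NULL) {
  if (inherits(vc, "variance_components")) {
    g <- vc$sigma2_g
    p <- if (is.null(vc$sigma2_p)) 0 else vc$sigma2_p
    e <- vc$sigma2_e
  } else {
    g <- vc; p <- sigma2_p; e <- sigma2_e
  }
  tot <- g + p + e
  if (!is.finite(tot) || tot <= 0) stop("total variance must be positive")
  g / tot
}

#' Model specification for an evaluation
#'
#' @param trait trait name (matches the phenotype table).
#' @param fixed fixed-effect factor column names.
#' @param pe include a permanent-environment term (repeatability model)?
#' @param relationship `"A"` (pedigree) or `"H"` (single-step).
#' @param varcomp a [variance_components()] object.
#' @return an object of class `"model_spec"`.
#' @export
model_spec <- function(trait, fixed = character(), pe = TRUE,
                       relationship = c("A", "H"), varcomp = NULL) {
  relationship <- match.arg(relationship)
  structure(list(trait = trait, fixed = fixed, pe = pe,
                 relationship = relationship, varcomp = varcomp),
            class = "model_spec")
}

# Design matrices for the single-trait model, in pedigree order.
.design_single <- function(pheno, ped, fixed = attr(pheno, "fixed"),
                           pe = TRUE) {
  if (!nrow(pheno)) stop("no phenotype records")
  align_ids(ped, pheno = pheno)
  nrec <- nrow(pheno)
  n <- nrow(ped)
  aidx <- match(pheno$animal, ped$animal)
  if (is.null(fixed)) fixed <- character()
  if (length(fixed)) {
    fd <- droplevels(as.data.frame(pheno[, fixed, drop = FALSE]))
    X <- Matrix(model.matrix(~ ., data = fd), sparse = TRUE)
  } else {
    X <- Matrix(matrix(1, nrec, 1, dimnames = list(NULL, "(Intercept)")),
                sparse = TRUE)
  }
  Z <- sparseMatrix(i = seq_len(nrec), j = aidx, x = 1, dims = c(nrec, n))
  W <- NULL
  pe_ids <- character(0)
  if (pe) {
    pe_ids <- unique(pheno$animal)
    W <- sparseMatrix(i = seq_len(nrec), j = match(pheno$animal, pe_ids),
                      x = 1, dims = c(nrec, length(pe_ids)))
  }
  list(y = pheno$value, X = X, Z = Z, W = W, pe_ids = pe_ids,
       n = n, nrec = nrec, p = ncol(X), fixed_names = colnames(X))
}

#' Assemble the mixed-model equations
#'
#' Single-trait form (R-inverse scaling):
#' \deqn{(T' T / \sigma^2_e + \Sigma^{-1})\,\theta = T' y / \sigma^2_e}
#' with `T = [X Z W]` and `Sigma^{-1}` holding `K^{-1}/sigma2_g` on the
#' breeding-value block and `I/sigma2_p` on the permanent-environment block.
#'
#' @param spec a [model_spec()] with variance components.
#' @param pheno a phenotype table.
#' @param ped a sorted pedigree.
#' @param kinv the sparse relationship inverse (A- or H-inverse), in
#'   pedigree order.
#' @return an object of class `"mme_system"`: list with `C`, `rhs`,
#'   `layout`, `design`.
#' @export
build_mme <- function(spec, pheno, ped, kinv) {
  vc <- spec$varcomp
  if (is.null(vc)) stop("model_spec carries no variance components")
  if (vc$sigma2_g <= 0) stop("sigma2_g must be strictly positive")
  pe <- spec$pe && !is.null(vc$sigma2_p) && vc$sigma2_p > 0
  des <- .design_single(pheno, ped, fixed = spec$fixed, pe = pe)
  T <- if (pe) cbind(des$X, des$Z, des$W) else cbind(des$X, des$Z)
  ie <- 1 / vc$sigma2_e
  npe <- length(des$pe_ids)
  blocks <- list(Diagonal(des$p, x = 0), kinv * (1 / vc$sigma2_g))
  if (pe) blocks <- c(blocks, list(Diagonal(npe) * (1 / vc$sigma2_p)))
  C <- forceSymmetric(crossprod(T) * ie + bdiag(blocks), "U")
  rhs <- as.numeric(crossprod(T, des$y)) * ie
  layout <- list(beta = seq_len(des$p),
                 g = des$p + seq_len(des$n),
                 pe = if (pe) des$p + des$n + seq_len(npe) else NULL)
  structure(list(C = C, rhs = rhs, layout = layout, design = des,
                 ids = ped$animal, pe_ids = des$pe_ids),
            class = "mme_system")
}

# Bivariate system: trait-1 records plus one gene-content record per
# genotyped animal. Residuals are independent across the two record types
# (missing-trait records contribute only to their observed trait's
# equations), so R-inverse is diagonal per record. Unknown order:
# [beta, mu_T, g1, gT, pe].
.build_mme_bivariate <- function(spec, pheno, y_T, ped, kinv) {
  vc <- spec$varcomp
  if (is.null(vc$G0)) stop("bivariate system needs a 2x2 G0")
  pe <- spec$pe && !is.null(vc$sigma2_p) && vc$sigma2_p > 0
  des <- .design_single(pheno, ped, fixed = spec$fixed, pe = pe)
  yT_obs <- y_T[!is.na(y_T)]
  if (length(yT_obs) < 2) stop("fewer than 2 genotyped animals")
  tidx <- match(names(yT_obs), ped$animal)
  if (anyNA(tidx)) stop("gene-content record for unknown animal")
  n <- des$n; npe <- length(des$pe_ids); p1 <- des$p
  nT <- length(yT_obs)
  zero <- function(nr, nc) sparseMatrix(i = integer(0), j = integer(0),
                                        x = double(0), dims = c(nr, nc))
  T1 <- cbind(des$X, zero(des$nrec, 1L), des$Z, zero(des$nrec, n))
  if (pe) T1 <- cbind(T1, des$W)
  ZT <- sparseMatrix(i = seq_len(nT), j = tidx, x = 1, dims = c(nT, n))
  T2 <- cbind(zero(nT, p1), Matrix(1, nT, 1, sparse = TRUE), zero(nT, n), ZT)
  if (pe) T2 <- cbind(T2, zero(nT, npe))
  ie1 <- 1 / vc$sigma2_e
  ieT <- 1 / vc$sigma2_eT
  g0i <- solve(vc$G0)
  kron <- rbind(cbind(kinv * g0i[1, 1], kinv * g0i[1, 2]),
                cbind(kinv * g0i[2, 1], kinv * g0i[2, 2]))
  blocks <- list(Diagonal(p1 + 1L, x = 0), kron)
  if (pe) blocks <- c(blocks, list(Diagonal(npe) * (1 / vc$sigma2_p)))
  C <- forceSymmetric(crossprod(T1) * ie1 + crossprod(T2) * ieT +
                        bdiag(blocks), "U")
  rhs <- as.numeric(crossprod(T1, des$y)) * ie1 +
    as.numeric(crossprod(T2, c(yT_obs))) * ieT
  layout <- list(beta = seq_len(p1), mu_T = p1 + 1L,
                 g = p1 + 1L + seq_len(n), gT = p1 + 1L + n + seq_len(n),
                 pe = if (pe) p1 + 1L + 2L * n + seq_len(npe) else NULL)
  structure(list(C = C, rhs = rhs, layout = layout, design = des,
                 ids = ped$animal, pe_ids = des$pe_ids, yT_obs = yT_obs),
            class = "mme_system")
}

#' Preconditioned conjugate-gradient solver
#'
#' Jacobi (diagonal) preconditioner; convergence when the relative residual
#' norm drops below `tol`.
#'
#' @param C symmetric coefficient matrix (sparse), or an `"mme_system"`.
#' @param rhs right-hand side (ignored when `C` is a system).
#' @param tol relative-residual tolerance (default 1e-10).
#' @param max_iter iteration cap; reaching it flags non-convergence.
#' @param x0 optional starting vector.
#' @return list with `x`, `converged`, `n_iter`, `rel_resid`.
#' @export
solve_pcg <- function(C, rhs = NULL, tol = 1e-10, max_iter = 10000L,
                      x0 = NULL) {
  if (inherits(C, "mme_system")) {
    rhs <- C$rhs
    C <- C$C
  }
  q <- length(rhs)
  d <- diag(C)
  d[d <= 0] <- 1
  x <- if (is.null(x0)) numeric(q) else x0
  bnorm <- sqrt(sum(rhs^2))
  if (bnorm == 0)
    return(list(x = numeric(q), converged = TRUE, n_iter = 0L,
                rel_resid = 0))
  r <- rhs - as.numeric(C %*% x)
  z <- r / d
  p <- z
  rz <- sum(r * z)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Cp <- as.numeric(C %*% p)
    alpha <- rz / sum(p * Cp)
    x <- x + alpha * p
    r <- r - alpha * Cp
    if (sqrt(sum(r^2)) / bnorm < tol) {
      converged <- TRUE
      break
    }
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, converged = converged, n_iter = it,
       rel_resid = sqrt(sum(r^2)) / bnorm)
}

#' Fit a single-trait evaluation model
#'
#' Dispatches to the pedigree A-inverse or the single-step H-inverse
#' according to the model specification, assembles the MME and solves by
#' PCG.
#'
#' @param spec a [model_spec()] with variance components.
#' @param pheno phenotype table.
#' @param ped sorted pedigree.
#' @param panel genotype panel of the genotyped animals (required for
#'   relationship `"H"`).
#' @param weights optional per-SNP weights for the (weighted) G.
#' @param blend_beta blending proportion for G* (default 0.05).
#' @param tol,max_iter PCG controls.
#' @param a_inv,a22_mat optional precomputed A-inverse and genotyped
#'   A-submatrix (they depend only on the pedigree, so repeated fits can
#'   share them).
#' @return an object of class `"evaluation_result"`: `ebv` (named, pedigree
#'   order), `fixed`, `pe`, `converged`, `n_iter`, `ghat_gen` (EBVs of
#'   genotyped animals), plus the record-level fitted fixed part used for
#'   yield deviations.
#' @export
fit <- function(spec, pheno, ped, panel = NULL, weights = NULL,
                blend_beta = 0.05, tol = 1e-10, max_iter = 10000L,
                a_inv = NULL, a22_mat = NULL) {
  if (is.null(a_inv)) a_inv <- a_inverse(ped)
  if (spec$relationship == "H") {
    if (is.null(panel)) stop("relationship H requested with no genotypes")
    align_ids(ped, panel = panel)
    G <- g_matrix(panel, weights = weights)
    A22 <- if (is.null(a22_mat)) a22(ped, panel$ids) else a22_mat
    kinv <- h_inverse(a_inv, blend(G, A22, blend_beta), A22, panel$ids)
  } else {
    kinv <- a_inv
  }
  sys <- build_mme(spec, pheno, ped, kinv)
  sol <- solve_pcg(sys, tol = tol, max_iter = max_iter)
  th <- sol$x
  ebv <- setNames(th[sys$layout$g], ped$animal)
  pe_hat <- if (!is.null(sys$layout$pe))
    setNames(th[sys$layout$pe], sys$pe_ids) else NULL
  beta <- setNames(th[sys$layout$beta], sys$design$fixed_names)
  structure(list(ebv = ebv, fixed = beta, pe = pe_hat,
                 converged = sol$converged, n_iter = sol$n_iter,
                 record_fixed = as.numeric(sys$design$X %*% beta),
                 pheno = pheno, spec = spec,
                 ghat_gen = if (!is.null(panel)) ebv[panel$ids] else NULL,
                 genotyped_ids = if (!is.null(panel)) panel$ids else NULL),
            class = "evaluation_result")
}

#' @export
#' @method print evaluation_result
print.evaluation_result <- function(x, ...) {
  cat(sprintf("evaluation_result: %d EBVs (%s relationship), %s in %d PCG iterations\n",
              length(x$ebv), x$spec$relationship,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Per-animal yield deviations
#'
#' `YD = y - X beta_hat - pe_hat`, averaged per animal over its records.
#'
#' @param pheno the phenotype table used in the fit.
#' @param result the fitted [fit()] result.
#' @return named numeric vector (animals with records only).
#' @export
yield_deviation <- function(pheno, result) {
  adj <- pheno$value - result$record_fixed
  if (!is.null(result$pe)) adj <- adj - result$pe[pheno$animal]
  yd <- tapply(adj, pheno$animal, mean)
  setNames(as.numeric(yd), names(yd))
}

#' Daughter yield deviations for a set of sires
#'
#' `DYD_s = mean over daughters d of 2 (YD_d - 0.5 ghat_dam(d))`: the
#' daughters' mate-adjusted average, on the sire breeding-value scale. Dams
#' with unknown identity contribute no adjustment.
#'
#' @param ped sorted pedigree.
#' @param yd per-animal yield deviations (from [yield_deviation()]).
#' @param result a fitted result supplying dam EBVs (ideally from a fit that
#'   excludes the validation daughters' records).
#' @param sire_ids sires to evaluate.
#' @param min_daughters minimum phenotyped daughters (default 10); sires
#'   below the threshold are dropped and listed in the `"excluded"`
#'   attribute.
#' @return named numeric vector of DYDs.
#' @export
dyd <- function(ped, yd, result, sire_ids, min_daughters = 10) {
  out <- numeric(0)
  excluded <- character(0)
  dam_of <- setNames(ped$dam, ped$animal)
  for (s in sire_ids) {
    daughters <- ped$animal[!is.na(ped$sire) & ped$sire == s &
                              ped$animal %in% names(yd)]
    if (length(daughters) < min_daughters) {
      excluded <- c(excluded, s)
      next
    }
    dams <- dam_of[daughters]
    dam_ebv <- ifelse(is.na(dams), 0, result$ebv[dams])
    out[s] <- mean(2 * (yd[daughters] - 0.5 * dam_ebv))
  }
  attr(out, "excluded") <- excluded
  out
}
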