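# Weighted genomic relationship matrix (VanRaden method 1 with observed
# allele frequencies), blending with A22 for invertibility, and assembly of
# the single-step H-inverse.

#' Centered genotype matrix Z = M - 2p
#'
#' Missing calls are mean-imputed to 2p per SNP before centering. Used both
#' for G construction and for the SNP-effect back-solve, so the projection
#' identity between the two holds exactly.
#'
#' @param panel a [genotype_panel()] (or a plain 0/1/2 matrix).
#' @param freqs optional per-SNP allele frequencies; computed from the panel
#'   when missing.
#' @return list with `Z` (centered matrix), `p` (frequencies).
#' @export
center_genotypes <- function(panel, freqs = NULL) {
  M <- if (inherits(panel, "genotype_panel")) panel$calls else as.matrix(panel)
  storage.mode(M) <- "double"
  if (is.null(freqs)) freqs <- apply(M, 2, allele_freq)
  if (any(freqs <= 0 | freqs >= 1))
    stop("monomorphic SNP included: remove it or supply interior frequencies")
  if (anyNA(M)) {
    for (j in which(colSums(is.na(M)) > 0))
      M[is.na(M[, j]), j] <- 2 * freqs[j]
  }
  list(Z = sweep(M, 2, 2 * freqs, "-"), p = freqs)
}

#' Weighted genomic relationship matrix
#'
#' \deqn{G = Z D Z' / (\bar d \sum_i 2 p_i (1 - p_i))}
#' with Z the column-centered genotype matrix and D the diagonal SNP-weight
#' matrix. With all weights equal this is the standard VanRaden method-1 G,
#' and G is invariant to rescaling the whole weight vector.
#'
#' @param panel a [genotype_panel()] restricted to genotyped animals.
#' @param weights per-SNP nonnegative weights (default all 1).
#' @param freqs optional per-SNP allele frequencies.
#' @return dense symmetric matrix with animal ids as dimnames.
#' @export
g_matrix <- function(panel, weights = NULL, freqs = NULL) {
  cz <- center_genotypes(panel, freqs)
  m <- ncol(cz$Z)
  d <- if (is.null(weights)) rep(1, m) else as.numeric(weights)
  if (length(d) != m) stop("weights length must equal SNP count")
  if (any(d < 0)) stop("weights must be nonnegative")
  denom <- sum(2 * cz$p * (1 - cz$p)) * mean(d)
  G <- tcrossprod(sweep(cz$Z, 2, d, "*"), cz$Z) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(cz$Z), rownames(cz$Z))
  G
}

#' Blend G with the pedigree submatrix A22
#'
#' `G* = (1 - beta) G + beta A22` guarantees invertibility.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationship submatrix, same animals and order.
#' @param beta blending proportion (default 0.05).
#' @return blended matrix.
#' @export
blend <- function(G, A22, beta = 0.05) {
  if (!all(dim(G) == dim(A22))) stop("dimension mismatch between G and A22")
  if (!is.null(rownames(G)) && !is.null(rownames(A22)) &&
      !identical(rownames(G), rownames(A22)))
    stop("G and A22 must index the same animals in the same order")
  (1 - beta) * G + beta * A22
}

#' Single-step H-inverse
#'
#' \deqn{H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G^{*-1} - A_{22}^{-1}
#' \end{bmatrix}}
#' on the genotyped block, in pedigree order. With no genotyped animals this
#' is exactly A-inverse.
#'
#' @param a_inv sparse A-inverse in pedigree order (dimnames required).
#' @param g_star blended genomic relationship matrix.
#' @param a22 pedigree submatrix of the genotyped animals.
#' @param genotyped_ids ids of the genotyped animals (row order of
#'   `g_star`/`a22`).
#' @return sparse symmetric H-inverse in pedigree order.
#' @export
h_inverse <- function(a_inv, g_star, a22, genotyped_ids = rownames(g_star)) {
  if (is.null(genotyped_ids) || !length(genotyped_ids))
    return(a_inv)
  ids <- rownames(a_inv)
  idx <- match(genotyped_ids, ids)
  if (anyNA(idx)) stop("genotyped id not present in A-inverse: ",
                       genotyped_ids[which(is.na(idx))[1L]])
  g_inv <- tryCatch(chol2inv(chol(g_star)), error = function(e)
    stop("G* is singular; blend G with A22 (see blend()) before inverting"))
  a22_inv <- chol2inv(chol(a22))
  delta <- g_inv - a22_inv
  delta <- (delta + t(delta)) / 2
  ng <- length(idx)
  D <- sparseMatrix(i = rep(idx, times = ng), j = rep(idx, each = ng),
                    x = as.numeric(delta), dims = dim(a_inv),
                    dimnames = dimnames(a_inv))
  forceSymmetric(as(a_inv, "generalMatrix") + D, "U")
}
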