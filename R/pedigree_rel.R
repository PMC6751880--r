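# Numerator relationship matrix machinery: Meuwissen-Luo inbreeding,
# tabular A, Henderson's sparse A-inverse with inbreeding, and the genotyped
# submatrix A22. Pedigree order (oldest first) is the canonical id order for
# every matrix and solution vector in the package.

# Mendelian-sampling variances d_i given parent inbreeding; NA parent = founder.
.mendelian_var <- function(si, di, F) {
  n <- length(si)
  d <- rep(1, n)
  both <- !is.na(si) & !is.na(di)
  one <- xor(is.na(si), is.na(di))
  d[both] <- 0.5 - 0.25 * (F[si[both]] + F[di[both]])
  k <- ifelse(is.na(si), di, si)
  d[one] <- 0.75 - 0.25 * F[k[one]]
  d
}

#' Pedigree inbreeding coefficients (Meuwissen-Luo)
#'
#' Computes \eqn{F_i = a(sire_i, dam_i)/2} for every animal by accumulating
#' path coefficients over ancestors, using the \eqn{A = LDL'} decomposition.
#' Animals with an unknown parent are non-inbred.
#'
#' @param ped a sorted [pedigree()].
#' @return numeric vector of inbreeding coefficients named by animal id.
#' @export
inbreeding <- function(ped) {
  check_sorted(ped)
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  F <- numeric(n)
  Dv <- numeric(n)
  for (i in seq_len(n)) {
    Dv[i] <- .mendelian_var(si[i], di[i], F)[1L]
    if (is.na(si[i]) || is.na(di[i])) next  # F stays 0
    # a_ii = sum_j L_ij^2 D_j over ancestors j of i
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      lj <- L[j]
      if (lj == 0) next
      aii <- aii + lj * lj * Dv[j]
      if (!is.na(si[j])) L[si[j]] <- L[si[j]] + 0.5 * lj
      if (!is.na(di[j])) L[di[j]] <- L[di[j]] + 0.5 * lj
    }
    F[i] <- aii - 1
  }
  names(F) <- ped$animal
  F
}

#' Dense numerator relationship matrix A (tabular method)
#'
#' @param ped a sorted [pedigree()].
#' @return symmetric matrix with `a_ii = 1 + F_i`, dimnames = animal ids.
#' @export
a_matrix <- function(ped) {
  check_sorted(ped)
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    if (i > 1L) {
      j <- seq_len(i - 1L)
      v <- numeric(i - 1L)
      if (!is.na(si[i])) v <- v + 0.5 * A[si[i], j]
      if (!is.na(di[i])) v <- v + 0.5 * A[di[i], j]
      A[i, j] <- v
      A[j, i] <- v
    }
    A[i, i] <- 1 + if (!is.na(si[i]) && !is.na(di[i]))
      0.5 * A[si[i], di[i]] else 0
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' \eqn{1/d_i} to its own diagonal and scaled entries to its parent block,
#' where \eqn{d_i} is the Mendelian-sampling variance.
#'
#' @param ped a sorted [pedigree()].
#' @param F optional precomputed inbreeding coefficients.
#' @return sparse symmetric `Matrix` (class `dsCMatrix`) in pedigree order.
#' @export
a_inverse <- function(ped, F = inbreeding(ped)) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  a <- 1 / .mendelian_var(si, di, F)

  ii <- list(); jj <- list(); xx <- list()
  add <- function(i, j, x) {
    k <- length(ii) + 1L
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x
  }
  idx <- seq_len(n)
  add(idx, idx, a)
  for (pcol in list(si, di)) {
    has <- !is.na(pcol)
    add(idx[has], pcol[has], -0.5 * a[has])
    add(pcol[has], idx[has], -0.5 * a[has])
    add(pcol[has], pcol[has], 0.25 * a[has])
  }
  both <- !is.na(si) & !is.na(di)
  add(si[both], di[both], 0.25 * a[both])
  add(di[both], si[both], 0.25 * a[both])

  M <- sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                    dims = c(n, n), dimnames = list(ped$animal, ped$animal))
  forceSymmetric(M, "U")
}

#' Relationship submatrix of genotyped animals (A22)
#'
#' Computed without forming the full A: the pedigree is pruned to the
#' ancestor closure of the requested animals, the tabular method is run on
#' that sub-pedigree, and the result is sliced.
#'
#' @param ped a sorted [pedigree()].
#' @param genotyped_ids animal ids to keep.
#' @return dense symmetric matrix in the order of `genotyped_ids`.
#' @export
a22 <- function(ped, genotyped_ids) {
  genotyped_ids <- as.character(genotyped_ids)
  if (!all(genotyped_ids %in% ped$animal))
    stop("unknown id in genotyped_ids: ",
         setdiff(genotyped_ids, ped$animal)[1L])
  keep <- ped$animal %in% .ancestor_closure(ped, genotyped_ids)
  sub <- ped[keep, , drop = FALSE]
  class(sub) <- class(ped)
  A <- a_matrix(sub)
  A[genotyped_ids, genotyped_ids, drop = FALSE]
}

.ancestor_closure <- function(ped, ids) {
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  inset <- ped$animal %in% ids
  # pedigree is sorted, so one backward sweep closes the set
  for (i in rev(seq_len(nrow(ped)))) {
    if (inset[i]) {
      if (!is.na(si[i])) inset[si[i]] <- TRUE
      if (!is.na(di[i])) inset[di[i]] <- TRUE
    }
  }
  ped$animal[inset]
}

#' Export a relationship matrix as id-id-value triplets
#' @param M matrix (dense or sparse) with dimnames.
#' @param path output TSV path.
#' @param lower_only write only the lower triangle (default TRUE).
#' @export
write_triplets <- function(M, path, lower_only = TRUE) {
  T <- as(as(Matrix(M, sparse = TRUE), "generalMatrix"), "TsparseMatrix")
  i <- T@i + 1L; j <- T@j + 1L
  keep <- if (lower_only) i >= j else rep(TRUE, length(i))
  out <- data.frame(id1 = rownames(M)[i[keep]], id2 = colnames(M)[j[keep]],
                    value = T@x[keep], stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
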