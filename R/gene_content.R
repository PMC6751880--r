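# The multiple-trait Gene Content method: the 0/1/2 allele count at a known
# causal locus is carried as a second trait of a bivariate pedigree-based
# evaluation, so partially genotyped populations still propagate major-gene
# information through the relationship matrix. The fitted breeding values
# decompose exactly into a major-gene part (gT * alpha) and a polygenic
# remainder. Only the pedigree relationship is used: combining the gene
# content trait with a marker-based H would duplicate the locus information.

#' Gene-content vector for a locus
#'
#' @param panel genotype panel of the genotyped animals.
#' @param locus SNP id or column index of the causal locus.
#' @param ped optional pedigree; when given, the result covers all animals
#'   with `NA` for the ungenotyped.
#' @return named vector of 0/1/2 allele counts (`NA` = ungenotyped).
#' @export
gene_content_vector <- function(panel, locus, ped = NULL) {
  j <- if (is.character(locus)) match(locus, panel$map$snp_id) else locus
  if (is.na(j) || j < 1 || j > nrow(panel$map))
    stop("locus not present in panel")
  y <- setNames(as.numeric(panel$calls[, j]), panel$ids)
  if (!is.null(ped)) {
    full <- setNames(rep(NA_real_, nrow(ped)), ped$animal)
    full[names(y)] <- y
    y <- full
  }
  y
}

#' Genetic variance of the gene-content trait
#'
#' `2 f (1 - f)` with `f` the counted-allele frequency among observed
#' (genotyped) animals.
#'
#' @param y_T gene-content vector (`NA` allowed).
#' @return the variance.
#' @export
sigma2_gT <- function(y_T) {
  obs <- y_T[!is.na(y_T)]
  if (!length(obs)) stop("no observed gene contents")
  f <- mean(obs) / 2
  2 * f * (1 - f)
}

#' Allele substitution effect
#'
#' `alpha = cov(g, gT) / sigma2_gT`: the expected change in the trait per
#' copy of the counted allele.
#'
#' @param cov_g_gT genetic covariance between trait and gene content.
#' @param sigma2_gT genetic variance of the gene-content trait.
#' @return alpha, in trait units per allele copy.
#' @export
substitution_effect <- function(cov_g_gT, sigma2_gT) {
  if (sigma2_gT <= 0) stop("sigma2_gT must be positive")
  cov_g_gT / sigma2_gT
}

#' Fraction of genetic variance explained by the major gene
#'
#' `alpha^2 * sigma2_gT / sigma2_g`; equals the squared genetic correlation
#' when all three inputs come from the same (co)variance estimates.
#'
#' @param alpha allele substitution effect.
#' @param sigma2_gT gene-content genetic variance.
#' @param sigma2_g trait genetic variance.
#' @return fraction in \[0, 1\].
#' @export
explained_variance <- function(alpha, sigma2_gT, sigma2_g) {
  if (sigma2_g <= 0) stop("sigma2_g must be positive")
  alpha^2 * sigma2_gT / sigma2_g
}

#' Genetic correlation between trait and gene content
#'
#' @param cov_g_gT genetic covariance.
#' @param sigma_g,sigma_gT genetic standard deviations.
#' @return correlation; values outside \[-1, 1\] (possible with
#'   non-positive-definite estimates) are reported with a warning.
#' @export
genetic_correlation <- function(cov_g_gT, sigma_g, sigma_gT) {
  if (sigma_g <= 0 || sigma_gT <= 0) stop("standard deviations must be positive")
  r <- cov_g_gT / (sigma_g * sigma_gT)
  if (abs(r) > 1)
    warning("genetic correlation outside [-1, 1]: (co)variances are not positive definite")
  r
}

#' Fit the Gene Content model and decompose breeding values
#'
#' Solves the bivariate MME (trait + gene content, pedigree relationship
#' only, the gene-content trait carrying a single mean as fixed effect) and
#' returns the exact decomposition
#' `EBV_trait = EBV_polygen + EBV_major` with `EBV_major = gT_hat * alpha`.
#'
#' @param spec a [model_spec()] for the trait; its `varcomp` must be
#'   bivariate (see [variance_components_bivariate()] or
#'   [gibbs_bivariate()]).
#' @param pheno phenotype table.
#' @param y_T gene-content vector over the pedigree (`NA` = ungenotyped).
#' @param ped sorted pedigree.
#' @param tol,max_iter PCG controls.
#' @return object of class `"gene_content_result"` with `ebv_trait`,
#'   `ebv_gene_content`, `ebv_major` (the gene part), `ebv_polygen`,
#'   `alpha_hat`, `r_g`, `explained_variance`, `sigma2_gT`, `mu_T`,
#'   `converged`.
#' @export
fit_gene_content <- function(spec, pheno, y_T, ped, tol = 1e-10,
                             max_iter = 10000L) {
  vc <- spec$varcomp
  if (is.null(vc$G0)) stop("fit_gene_content needs bivariate variance components")
  obs <- y_T[!is.na(y_T)]
  if (length(unique(obs)) < 2 && (all(obs == 0) || all(obs == 2)))
    stop("causal locus monomorphic among genotyped animals")
  kinv <- a_inverse(ped)
  sys <- .build_mme_bivariate(spec, pheno, y_T, ped, kinv)
  sol <- solve_pcg(sys, tol = tol, max_iter = max_iter)
  th <- sol$x
  g <- setNames(th[sys$layout$g], ped$animal)
  gT <- setNames(th[sys$layout$gT], ped$animal)
  alpha <- substitution_effect(vc$G0[1, 2], vc$G0[2, 2])
  major <- gT * alpha
  r_g <- genetic_correlation(vc$G0[1, 2], sqrt(vc$G0[1, 1]),
                             sqrt(vc$G0[2, 2]))
  structure(list(ebv_trait = g, ebv_gene_content = gT, ebv_major = major,
                 ebv_polygen = g - major, alpha_hat = alpha, r_g = r_g,
                 explained_variance = explained_variance(alpha, vc$G0[2, 2],
                                                         vc$G0[1, 1]),
                 sigma2_gT = vc$G0[2, 2], mu_T = th[sys$layout$mu_T],
                 fixed = setNames(th[sys$layout$beta],
                                  sys$design$fixed_names),
                 pe = if (!is.null(sys$layout$pe))
                   setNames(th[sys$layout$pe], sys$pe_ids) else NULL,
                 converged = sol$converged, n_iter = sol$n_iter),
            class = "gene_content_result")
}

#' @export
#' @method print gene_content_result
print.gene_content_result <- function(x, ...) {
  cat(sprintf("gene_content_result: alpha = %.4f, r_g = %.3f, explained variance = %.2f%%\n",
              x$alpha_hat, x$r_g, 100 * x$explained_variance))
  invisible(x)
}

#' Genetic trend of an EBV component by birth year
#'
#' @param result a [fit_gene_content()] result (or any named EBV vector via
#'   `component = NULL`).
#' @param ped sorted pedigree with birth years.
#' @param component `"trait"`, `"polygen"` or `"major"`.
#' @param cohort optional animal ids restricting the trend (e.g. reference
#'   sires).
#' @return data frame with `birth_year`, `mean_ebv`, `n`.
#' @export
genetic_trend <- function(result, ped, component = c("trait", "polygen",
                                                     "major"),
                          cohort = NULL) {
  ebv <- if (is.numeric(result)) result else {
    component <- match.arg(component)
    switch(component, trait = result$ebv_trait,
           polygen = result$ebv_polygen, major = result$ebv_major)
  }
  keep <- ped$animal %in% names(ebv) & !is.na(ped$birth_year)
  if (!is.null(cohort)) keep <- keep & ped$animal %in% cohort
  sub <- ped[keep, ]
  v <- ebv[sub$animal]
  out <- aggregate(list(mean_ebv = unname(v)),
                   by = list(birth_year = sub$birth_year), FUN = mean)
  out$mean_ebv <- as.numeric(out$mean_ebv)
  out$n <- as.integer(table(sub$birth_year)[as.character(out$birth_year)])
  out <- out[order(out$birth_year), , drop = FALSE]
  rownames(out) <- NULL
  out
}
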