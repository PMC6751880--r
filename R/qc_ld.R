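# Marker quality control and linkage disequilibrium. QC mirrors routine chip
# pipelines: SNPs failing MAF >= 1%, HWE P >= 1e-5 or call rate >= 97% are
# removed. LD is the squared Pearson correlation of genotype dosages
# (composite LD; phased haplotypes are not carried through the pipeline).

#' Allele frequency of the alternate (counted) allele
#' @param calls vector of 0/1/2 calls, `NA` allowed.
#' @return frequency in \[0, 1\].
#' @export
allele_freq <- function(calls) {
  obs <- calls[!is.na(calls)]
  if (!length(obs)) stop("all calls missing: allele frequency undefined")
  sum(obs) / (2 * length(obs))
}

#' Hardy-Weinberg chi-square test
#'
#' One-degree-of-freedom goodness of fit of observed genotype counts against
#' the HWE expectation at the observed allele frequency. A monomorphic SNP
#' returns p = 1 (no test possible).
#'
#' @param n0,n1,n2 counts of the 0/1/2 genotype classes.
#' @return the p-value.
#' @export
hwe_chisq <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n < 1) stop("empty genotype counts")
  p <- (2 * n2 + n1) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  x2 <- sum((c(n0, n1, n2) - e)^2 / e)
  pchisq(x2, df = 1, lower.tail = FALSE)
}

#' SNP quality control
#'
#' @param panel a [genotype_panel()].
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_min minimum HWE p-value (default 1e-5).
#' @param cr_min minimum per-SNP call rate (default 0.97).
#' @return list with `report` (per-SNP data frame: `snp_id`, `maf`,
#'   `call_rate`, `hwe_p`, `kept`, `reason`) and `panel` (the filtered
#'   panel).
#' @export
snp_qc <- function(panel, maf_min = 0.01, hwe_min = 1e-5, cr_min = 0.97) {
  calls <- panel$calls
  if (!nrow(panel$map)) stop("empty panel")
  n <- nrow(calls)
  nm <- colSums(!is.na(calls))
  cr <- nm / n
  p <- colSums(calls, na.rm = TRUE) / pmax(2 * nm, 1)
  maf <- pmin(p, 1 - p)
  hwe <- vapply(seq_len(ncol(calls)), function(j) {
    x <- calls[, j]
    hwe_chisq(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
              sum(x == 2, na.rm = TRUE))
  }, numeric(1))
  kept <- maf >= maf_min & hwe >= hwe_min & cr >= cr_min
  reason <- vapply(seq_along(kept), function(j) {
    r <- c(if (maf[j] < maf_min) "maf", if (hwe[j] < hwe_min) "hwe",
           if (cr[j] < cr_min) "call_rate")
    paste(r, collapse = ";")
  }, character(1))
  report <- data.frame(snp_id = panel$map$snp_id, maf = maf, call_rate = cr,
                       hwe_p = hwe, kept = kept, reason = reason,
                       stringsAsFactors = FALSE)
  list(report = report,
       panel = panel_subset(panel, snps = which(kept)))
}

#' LD between two SNPs as squared dosage correlation
#'
#' Pairwise-complete observations; symmetric in its arguments and invariant
#' to flipping either SNP's allele coding.
#'
#' @param x,y vectors of 0/1/2 calls.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) stop("fewer than 2 paired non-missing calls")
  if (var(x[ok]) == 0 || var(y[ok]) == 0)
    stop("monomorphic SNP: LD undefined")
  cor(x[ok], y[ok])^2
}

#' LD decay profile binned by physical distance
#'
#' All within-chromosome SNP pairs up to `max_dist_mb` are binned by distance
#' (contiguous bins of `bin_width_mb`); the profile reports the mean
#' r-squared of each non-empty bin.
#'
#' @param panel a [genotype_panel()].
#' @param bin_width_mb bin width in Mb (default 0.02, the chip-study
#'   convention).
#' @param max_dist_mb maximum pair distance in Mb (default 10).
#' @return data frame of class `"ld_profile"` with `bin_start_mb`,
#'   `bin_end_mb`, `mean_r2`, `n_pairs`.
#' @export
ld_decay_profile <- function(panel, bin_width_mb = 0.02, max_dist_mb = 10) {
  map <- panel$map
  dists <- numeric(0)
  r2s <- numeric(0)
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    if (length(idx) < 2) next
    pos <- map$pos_bp[idx] / 1e6
    X <- panel$calls[, idx, drop = FALSE]
    poly <- apply(X, 2, function(v) var(v, na.rm = TRUE) > 0)
    # correlation over polymorphic columns; pairwise-complete
    Xp <- X[, poly, drop = FALSE]
    posp <- pos[poly]
    if (ncol(Xp) < 2) next
    R <- suppressWarnings(cor(Xp, use = "pairwise.complete.obs"))
    ut <- upper.tri(R)
    D <- abs(outer(posp, posp, "-"))
    keep <- ut & D <= max_dist_mb & !is.na(R)
    dists <- c(dists, D[keep])
    r2s <- c(r2s, R[keep]^2)
  }
  if (!length(dists))
    return(structure(data.frame(bin_start_mb = numeric(0),
                                bin_end_mb = numeric(0),
                                mean_r2 = numeric(0), n_pairs = integer(0)),
                     class = c("ld_profile", "data.frame")))
  bin <- floor(dists / bin_width_mb)
  agg <- tapply(r2s, bin, mean)
  cnt <- tapply(r2s, bin, length)
  b <- as.integer(names(agg))
  out <- data.frame(bin_start_mb = b * bin_width_mb,
                    bin_end_mb = (b + 1) * bin_width_mb,
                    mean_r2 = as.numeric(agg),
                    n_pairs = as.integer(cnt))
  out <- out[order(out$bin_start_mb), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ld_profile", "data.frame")
  out
}

#' Imputation concordance rate
#'
#' `CR = 1 - n_errors / (2 * n_individuals)`: the error rate counts allele
#' mismatches, two possible per imputed individual.
#'
#' @param n_errors number of allele errors.
#' @param n_individuals number of imputed individuals.
#' @return the concordance rate in \[0, 1\].
#' @export
concordance_rate <- function(n_errors, n_individuals) {
  if (n_individuals <= 0) stop("n_individuals must be positive")
  if (n_errors < 0 || n_errors > 2 * n_individuals)
    stop("n_errors must lie in [0, 2 * n_individuals]")
  1 - n_errors / (2 * n_individuals)
}
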