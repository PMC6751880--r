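# Validation-cohort accuracy and the gain arithmetic of method-comparison
# tables: per-trait relative gains in percent, their unweighted mean over
# traits and the maximum over traits.

#' Prediction accuracy as a Pearson correlation
#'
#' Correlation between candidate EBVs and a reference (daughter yield
#' deviations on real data, true breeding values on simulated data).
#'
#' @param ebv,reference paired numeric vectors (matched by name when both
#'   are named).
#' @return the correlation.
#' @export
prediction_accuracy <- function(ebv, reference) {
  if (!is.null(names(ebv)) && !is.null(names(reference)))
    reference <- reference[names(ebv)]
  if (length(ebv) < 3) stop("need at least 3 paired animals")
  if (sd(ebv) == 0 || sd(reference) == 0)
    stop("constant vector: accuracy undefined")
  cor(ebv, reference)
}

#' Relative gain in percent
#' @param base,new accuracies.
#' @return `100 * (new - base) / base`.
#' @export
gain_pct <- function(base, new) {
  if (any(base == 0)) stop("zero base accuracy: gain undefined")
  100 * (new - base) / base
}

#' Summarise per-trait gains
#' @param gains numeric vector of per-trait gains (percent).
#' @param digits rounding for the report (default 2).
#' @return list with `mean` and `max`, rounded.
#' @export
gain_summary <- function(gains, digits = 2) {
  list(mean = round(mean(gains), digits), max = round(max(gains), digits))
}

#' Method-comparison gain table
#'
#' Given a methods-by-traits accuracy matrix, computes for each requested
#' (base, new) comparison the per-trait relative gains in percent (on the
#' unrounded accuracies), their unweighted mean over traits and the maximum
#' over traits. Gains are reported at 2 decimals.
#'
#' @param accuracies numeric matrix, rownames = methods, colnames = traits.
#' @param comparisons list of `c(base, new)` method-name pairs.
#' @return data frame of class `"gain_table"`: one row per comparison with
#'   per-trait gain columns plus `mean_gain` and `max_gain`.
#' @export
gain_table <- function(accuracies, comparisons) {
  accuracies <- as.matrix(accuracies)
  rows <- lapply(comparisons, function(cmp) {
    if (!all(cmp %in% rownames(accuracies)))
      stop("comparison references unknown method: ",
           paste(setdiff(cmp, rownames(accuracies)), collapse = ", "))
    g <- gain_pct(accuracies[cmp[1L], ], accuracies[cmp[2L], ])
    s <- gain_summary(g)
    out <- data.frame(base = cmp[1L], new = cmp[2L], t(round(g, 2)),
                      mean_gain = s$mean, max_gain = s$max,
                      check.names = FALSE, stringsAsFactors = FALSE)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gain_table", "data.frame")
  out
}

#' Allele-frequency trend by birth year
#'
#' @param calls named 0/1/2 vector of allele counts (the counted allele).
#' @param ped sorted pedigree with birth years.
#' @param cohort optional ids restricting the cohort (e.g. AI rams).
#' @return data frame with `birth_year`, `freq`, `n`.
#' @export
maf_trend <- function(calls, ped, cohort = NULL) {
  keep <- ped$animal %in% names(calls)[!is.na(calls)] &
    !is.na(ped$birth_year)
  if (!is.null(cohort)) keep <- keep & ped$animal %in% cohort
  sub <- ped[keep, ]
  if (!nrow(sub))
    return(data.frame(birth_year = integer(0), freq = numeric(0),
                      n = integer(0)))
  v <- unname(calls[sub$animal])
  out <- aggregate(list(freq = v), by = list(birth_year = sub$birth_year),
                   FUN = function(x) sum(x) / (2 * length(x)))
  out$freq <- as.numeric(out$freq)
  out$n <- as.integer(table(sub$birth_year)[as.character(out$birth_year)])
  out <- out[order(out$birth_year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validation study on a synthetic dataset
#'
#' Withholds the youngest generation's records (the validation sires'
#' daughters), fits pedigree BLUP, ssGBLUP and the requested windowed
#' WssGBLUP variants on the training records, and scores each method by the
#' correlation between the validation sires' EBVs and their true breeding
#' values (or DYDs computed from the withheld daughters).
#'
#' @param dataset a [simulate_population()] result.
#' @param vc variance components (default: the simulation's true values).
#' @param wss_methods window methods to run (besides ssGBLUP).
#' @param window window sizes in SNPs; the full methods-by-sizes grid is
#'   run, mirroring the per-trait grid search of weighted single-step
#'   studies.
#' @param iterations WssGBLUP iterations (default 2).
#' @param include_causal include the causal SNP among the markers?
#' @param reference `"truth"` (true breeding values) or `"dyd"`.
#' @param tol PCG tolerance (1e-8 is ample for accuracy comparisons).
#' @return named vector of accuracies: `blup`, `ssgblup`, one
#'   `wssgblup_<method><window>` entry per grid point, and `wssgblup_best`
#'   (the grid maximum, the analogue of a table's best-method row).
#' @export
validation_study <- function(dataset, vc = dataset$varcomp_true,
                             wss_methods = c("mean", "max", "sum"),
                             window = c(10L, 40L), iterations = 2L,
                             include_causal = FALSE,
                             reference = c("truth", "dyd"), tol = 1e-8) {
  reference <- match.arg(reference)
  ped <- dataset$pedigree
  train <- training_phenotypes(dataset)
  panel <- marker_panel(dataset, include_causal = include_causal)
  vids <- dataset$validation_ids
  spec_a <- model_spec(attr(train, "trait"), fixed = attr(train, "fixed"),
                       pe = TRUE, relationship = "A", varcomp = vc)
  spec_h <- spec_a
  spec_h$relationship <- "H"

  a_inv <- a_inverse(ped)
  a22_mat <- a22(ped, panel$ids)
  ref <- if (reference == "truth") dataset$true_bv[vids] else {
    full_fit <- fit(spec_a, dataset$phenotypes, ped, tol = tol,
                    a_inv = a_inv)
    yd <- yield_deviation(dataset$phenotypes, full_fit)
    d <- dyd(ped, yd, full_fit, vids, min_daughters = 5)
    d[!is.na(d)]
  }
  score <- function(res) prediction_accuracy(res$ebv[names(ref)], ref)

  acc <- c(blup = score(fit(spec_a, train, ped, tol = tol, a_inv = a_inv)),
           ssgblup = score(fit(spec_h, train, ped, panel, tol = tol,
                               a_inv = a_inv, a22_mat = a22_mat)))
  for (m in wss_methods) {
    for (n in window) {
      r <- run_wssgblup(spec_h, train, ped, panel, method = m, n = n,
                        iterations = iterations, tol = tol, a_inv = a_inv,
                        a22_mat = a22_mat)
      acc[paste0("wssgblup_", m, n)] <- score(r$result)
    }
  }
  acc["wssgblup_best"] <- max(acc[grep("^wssgblup_", names(acc))])
  acc
}
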