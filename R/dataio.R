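# Plain-TSV dialects for pedigree, genotypes and phenotypes, plus the
# identifier alignment every downstream matrix relies on. Unknown parents are
# written as "0" and held internally as NA.

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) && grepl("\t", first)) "\t" else ","
}

#' Construct a validated, topologically sorted pedigree
#'
#' A pedigree is a data frame with columns `animal`, `sire`, `dam`,
#' `birth_year` and `sex` ("M", "F" or `NA`). Unknown parents are `NA`.
#' Animals are re-ordered so that every parent precedes its offspring;
#' parents that are referenced but have no record of their own are appended
#' as founders.
#'
#' @param animal character vector of unique animal ids.
#' @param sire,dam character vectors of parent ids (`NA`, `""` or `"0"` for
#'   unknown).
#' @param birth_year optional integer vector.
#' @param sex optional vector with entries "M"/"F" (anything else becomes
#'   `NA`).
#' @return A `data.frame` of class `"pedigree"`, topologically sorted.
#' @export
pedigree <- function(animal, sire = NA, dam = NA, birth_year = NA, sex = NA) {
  animal <- as.character(animal)
  n <- length(animal)
  clean <- function(x) {
    x <- as.character(x)
    x <- rep_len(x, n)
    x[!is.na(x) & (x == "0" | x == "")] <- NA_character_
    x
  }
  sire <- clean(sire)
  dam <- clean(dam)
  if (anyDuplicated(animal))
    stop("duplicate animal id: ", animal[duplicated(animal)][1L])
  birth_year <- suppressWarnings(as.integer(rep_len(birth_year, n)))
  sex <- as.character(rep_len(sex, n))
  sex[!sex %in% c("M", "F")] <- NA_character_

  # append referenced-but-absent parents as founders
  miss <- setdiff(c(sire, dam), c(animal, NA_character_))
  if (length(miss)) {
    animal <- c(animal, miss)
    sire <- c(sire, rep(NA_character_, length(miss)))
    dam <- c(dam, rep(NA_character_, length(miss)))
    birth_year <- c(birth_year, rep(NA_integer_, length(miss)))
    sex <- c(sex, ifelse(miss %in% sire, "M",
                         ifelse(miss %in% dam, "F", NA_character_)))
    n <- length(animal)
  }

  ord <- .topo_order(animal, sire, dam)
  ped <- data.frame(animal = animal[ord], sire = sire[ord], dam = dam[ord],
                    birth_year = birth_year[ord], sex = sex[ord],
                    stringsAsFactors = FALSE)
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn's algorithm; errors on cycles naming one offending id.
.topo_order <- function(animal, sire, dam) {
  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        if (p == i) stop("pedigree cycle detected at animal ", animal[i])
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  # stable order: among available animals keep file/birth order
  out <- integer(0)
  while (length(queue)) {
    queue <- sort(queue)
    i <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) < n) {
    bad <- setdiff(seq_len(n), out)[1L]
    stop("pedigree cycle detected at animal ", animal[bad])
  }
  out
}

#' Check that a pedigree is topologically sorted
#' @param ped a pedigree.
#' @return `TRUE` invisibly, or an error.
#' @export
check_sorted <- function(ped) {
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  i <- seq_len(nrow(ped))
  if (any(si >= i, na.rm = TRUE) || any(di >= i, na.rm = TRUE))
    stop("pedigree is not sorted (a parent follows its offspring)")
  invisible(TRUE)
}

#' Read a pedigree file
#'
#' Tab- or comma-separated with a header; columns `animal`, `sire`, `dam`,
#' `birth_year` and optionally `sex`. `"0"` or an empty field marks an
#' unknown parent.
#'
#' @param path file path.
#' @return a sorted [pedigree()].
#' @export
read_pedigree <- function(path) {
  tab <- read.table(path, header = TRUE, sep = .detect_sep(path),
                    colClasses = "character", stringsAsFactors = FALSE)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(tab)))
    stop("pedigree file must have columns animal, sire, dam")
  pedigree(tab$animal, tab$sire, tab$dam,
           if ("birth_year" %in% names(tab)) tab$birth_year else NA,
           if ("sex" %in% names(tab)) tab$sex else NA)
}

#' Write a pedigree as TSV
#' @param ped a pedigree.
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a genotype panel
#'
#' Holds a 0/1/2 matrix of alternate-allele counts (rows = animals, columns =
#' SNPs) together with its map. The map is sorted by (chromosome, position)
#' and the call columns are permuted to match.
#'
#' @param calls integer matrix with values in \{0,1,2,NA\}; rownames are
#'   animal ids.
#' @param map data frame with columns `snp_id`, `chrom`, `pos_bp` (1-based).
#' @return an object of class `"genotype_panel"`: list with `ids`, `calls`,
#'   `map`.
#' @export
genotype_panel <- function(calls, map) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls))) stop("calls must have animal ids as rownames")
  if (anyDuplicated(rownames(calls))) stop("duplicate animal id in genotypes")
  bad <- !(calls %in% c(0L, 1L, 2L, NA))
  if (any(bad)) {
    w <- which(matrix(bad, nrow(calls)), arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype call at (%d,%d): must be 0/1/2/NA",
                 w[1L], w[2L]))
  }
  storage.mode(calls) <- "integer"
  need <- c("snp_id", "chrom", "pos_bp")
  if (!all(need %in% names(map))) stop("map needs snp_id, chrom, pos_bp")
  map <- data.frame(snp_id = as.character(map$snp_id),
                    chrom = as.integer(map$chrom),
                    pos_bp = as.integer(map$pos_bp),
                    stringsAsFactors = FALSE)
  if (ncol(calls) != nrow(map)) stop("map/genotype SNP count mismatch")
  if (is.null(colnames(calls))) colnames(calls) <- map$snp_id
  if (!setequal(colnames(calls), map$snp_id))
    stop("map and genotype SNP ids do not match")
  ord <- order(map$chrom, map$pos_bp)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  calls <- calls[, map$snp_id, drop = FALSE]
  if (nrow(map) > 1L) {
    same <- map$chrom[-1L] == map$chrom[-nrow(map)]
    if (any(same & diff(map$pos_bp) <= 0L))
      stop("pos_bp must be strictly increasing within chromosome")
  }
  structure(list(ids = rownames(calls), calls = calls, map = map),
            class = "genotype_panel")
}

#' @export
#' @method print genotype_panel
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d animals x %d SNPs on %d chromosome(s)\n",
              length(x$ids), nrow(x$map) , length(unique(x$map$chrom))))
  invisible(x)
}

#' Read genotypes and a SNP map
#'
#' The genotype file has one row per animal: first column the animal id,
#' remaining columns one SNP each (0/1/2 or NA). The map file has columns
#' `snp_id`, `chrom`, `pos_bp`.
#'
#' @param geno_path,map_path file paths.
#' @return a [genotype_panel()].
#' @export
read_genotypes <- function(geno_path, map_path) {
  g <- read.table(geno_path, header = TRUE, sep = .detect_sep(geno_path),
                  check.names = FALSE, stringsAsFactors = FALSE)
  m <- read.table(map_path, header = TRUE, sep = .detect_sep(map_path),
                  stringsAsFactors = FALSE)
  ids <- as.character(g[[1L]])
  calls <- as.matrix(g[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(calls) <- "double")
  ok <- is.na(calls) | calls %in% c(0, 1, 2)
  if (!all(ok)) {
    w <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf("parse error in %s at row %d, column %d: genotype must be 0/1/2/NA",
                 geno_path, w[1L], w[2L]))
  }
  rownames(calls) <- ids
  genotype_panel(calls, m)
}

#' Write a genotype panel as TSV (genotypes + map)
#' @param panel a genotype panel.
#' @param geno_path,map_path output paths.
#' @export
write_genotypes <- function(panel, geno_path, map_path) {
  out <- data.frame(animal = panel$ids, panel$calls, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, geno_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(panel$map, map_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(geno_path)
}

#' Subset a genotype panel by animal and/or SNP
#' @param panel a genotype panel.
#' @param ids animal ids to keep (default all).
#' @param snps SNP ids or column indices to keep (default all).
#' @return a genotype panel.
#' @export
panel_subset <- function(panel, ids = panel$ids, snps = NULL) {
  if (!all(ids %in% panel$ids)) stop("unknown animal id in panel subset")
  keep <- if (is.null(snps)) seq_len(nrow(panel$map))
          else if (is.character(snps)) match(snps, panel$map$snp_id)
          else snps
  genotype_panel(panel$calls[ids, keep, drop = FALSE],
                 panel$map[keep, , drop = FALSE])
}

#' Read a long-format phenotype table
#'
#' @param path file path (TSV/CSV with header). Must contain an `animal`
#'   column, the trait column and any configured fixed-factor columns; a
#'   `parity` column is kept when present.
#' @param trait name of the numeric trait column.
#' @param fixed character vector of fixed-effect factor column names.
#' @return a `data.frame` of class `"phenotype_table"` with columns
#'   `animal`, `value`, `parity` and one (re-coded) factor column per fixed
#'   effect. Attributes `trait` and `fixed` record the configuration.
#' @export
read_phenotypes <- function(path, trait, fixed = character()) {
  tab <- read.table(path, header = TRUE, sep = .detect_sep(path),
                    stringsAsFactors = FALSE)
  for (col in c("animal", trait, fixed))
    if (!col %in% names(tab))
      stop("configured column '", col, "' not found in ", path)
  val <- tab[[trait]]
  if (!is.numeric(val)) {
    suppressWarnings(num <- as.numeric(val))
    if (nrow(tab) && anyNA(num) && !all(is.na(val)))
      stop("non-numeric value in trait column '", trait, "'")
    val <- num
  }
  phenotype_table(tab$animal, val,
                  parity = if ("parity" %in% names(tab)) tab$parity else NA,
                  fixed = tab[fixed], trait = trait)
}

#' Construct a phenotype table
#' @param animal animal ids (repeated records allowed).
#' @param value numeric trait records.
#' @param parity integer parity/lactation number.
#' @param fixed data frame (or list) of fixed-effect factor columns.
#' @param trait trait name.
#' @return a `phenotype_table`.
#' @export
phenotype_table <- function(animal, value, parity = NA, fixed = list(),
                            trait = "trait") {
  n <- length(animal)
  out <- data.frame(animal = as.character(animal), value = as.numeric(value),
                    parity = suppressWarnings(as.integer(rep_len(parity, n))),
                    stringsAsFactors = FALSE)
  fixed <- as.data.frame(fixed, stringsAsFactors = FALSE)
  for (f in names(fixed)) out[[f]] <- factor(fixed[[f]])  # dense level codes
  rownames(out) <- NULL
  attr(out, "trait") <- trait
  attr(out, "fixed") <- names(fixed)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Write a phenotype table as TSV
#' @param pheno a phenotype table.
#' @param path output path.
#' @export
write_phenotypes <- function(pheno, path) {
  write.table(as.data.frame(pheno), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Check identifier alignment across pedigree, genotypes and phenotypes
#'
#' Every genotyped or phenotyped animal must resolve to exactly one pedigree
#' row.
#'
#' @param ped a pedigree.
#' @param panel optional genotype panel.
#' @param pheno optional phenotype table.
#' @return `TRUE` invisibly, or an error naming an offending id.
#' @export
align_ids <- function(ped, panel = NULL, pheno = NULL) {
  if (!is.null(panel)) {
    miss <- setdiff(panel$ids, ped$animal)
    if (length(miss)) stop("genotyped animal not in pedigree: ", miss[1L])
  }
  if (!is.null(pheno)) {
    miss <- setdiff(pheno$animal, ped$animal)
    if (length(miss)) stop("phenotyped animal not in pedigree: ", miss[1L])
  }
  invisible(TRUE)
}
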