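# Shared fixtures, all generated in code.

# sire, dam, offspring trio (parents first after sorting)
trio_pedigree <- function() {
  pedigree(animal = c("S", "D", "O"), sire = c(NA, NA, "S"),
           dam = c(NA, NA, "D"), birth_year = c(2000, 2000, 2002),
           sex = c("M", "F", "F"))
}

# random multi-generation pedigree with known structure
random_pedigree <- function(n = 50, n_founders = 10, seed = 1) {
  set.seed(seed)
  animal <- paste0("A", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  sex <- c(rep(c("M", "F"), length.out = n_founders),
           sample(c("M", "F"), n - n_founders, replace = TRUE))
  for (i in (n_founders + 1):n) {
    males <- which(sex[1:(i - 1)] == "M")
    females <- which(sex[1:(i - 1)] == "F")
    if (length(males)) sire[i] <- animal[sample(males, 1)]
    if (length(females)) dam[i] <- animal[sample(females, 1)]
  }
  pedigree(animal, sire, dam, birth_year = 2000 + (seq_len(n) > n_founders),
           sex = sex)
}

# small synthetic dataset reused across tests (cheap: ~160 animals)
tiny_config <- function(...) {
  args <- list(n_founders = 80, founder_males = 12, n_generations = 2,
               n_sires_per_gen = 6, n_dams_per_sire = 7, n_snps = 120,
               n_chromosomes = 2, n_lactations = 2, n_herds = 5)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

tiny_dataset_cache <- new.env()
tiny_dataset <- function(seed = 3) {
  key <- paste0("d", seed)
  if (is.null(tiny_dataset_cache[[key]]))
    tiny_dataset_cache[[key]] <- simulate_population(tiny_config(), seed = seed)
  tiny_dataset_cache[[key]]
}

# drop monomorphic SNPs so G construction is valid
polymorphic_panel <- function(panel) {
  keep <- which(apply(panel$calls, 2, function(x) var(x, na.rm = TRUE) > 0))
  panel_subset(panel, snps = keep)
}

expect_named_equal <- function(x, y, tol = 1e-8) {
  expect_equal(as.numeric(x[names(y)]), as.numeric(y), tolerance = tol)
}
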