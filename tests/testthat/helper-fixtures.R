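# Shared fixtures: all built in code at test time.

as_mat <- function(x) {
  m <- unclass(x)
  attr(m, "kind") <- NULL
  attr(m, "a") <- NULL
  attr(m, "b") <- NULL
  m
}

trio_ped <- function() {
  pedigree(c("S", "D", "O"), c(NA, NA, "S"), c(NA, NA, "D"),
           unknown_code = NA_character_)
}

# Full-sib mating: C is the offspring of two full sibs (F = 0.25)
fullsib_loop_ped <- function() {
  pedigree(c("P1", "P2", "B1", "B2", "C"),
           c(NA, NA, "P1", "P1", "B1"),
           c(NA, NA, "P2", "P2", "B2"),
           unknown_code = NA_character_)
}

# Random pedigree with overlapping generations and inbred loops:
# non-founders draw two distinct parents among all earlier individuals,
# so full-sib and parent-offspring matings (hence inbreeding) occur.
random_pedigree <- function(n, n_founders = max(4L, n %/% 10L), seed = 1L) {
  set.seed(seed)
  id <- sprintf("I%04d", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in (n_founders + 1L):n) {
    par <- sample(i - 1L, 2L)
    sire[i] <- id[par[1L]]
    dam[i] <- id[par[2L]]
  }
  pedigree(id, sire, dam, unknown_code = NA_character_)
}

random_genotypes <- function(ids, n_snps, seed = 1L) {
  set.seed(seed)
  p <- runif(n_snps, 0.1, 0.5)
  g <- vapply(p, function(pp) rbinom(length(ids), 2L, pp), integer(length(ids)))
  dimnames(g) <- list(ids, sprintf("L%04d", seq_len(n_snps)))
  genotype_matrix(g)
}

small_pop <- function(seed, ...) {
  simulate_population(sim_config_small(seed = seed, ...))
}

# Tiny configuration for fast closure checks
tiny_cfg <- function(seed, ...) {
  sim_config(n_founders = 12, n_families = 8,
             genotyped_family_count = 2, genotyped_family_sizes = c(6, 10),
             n_large_families = 3, large_family_sizes = c(11, 14),
             small_family_sizes = c(4, 8), n_snps = 80,
             seed = seed, ...)
}

qc_pop <- function(pop, ...) {
  qc <- qc_genotypes(pop$genotypes, pop$ped, ...)
  pop$genotypes <- qc$genotypes
  pop$genotyped_ids <- rownames(qc$genotypes)
  pop
}
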