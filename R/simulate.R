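#' Configuration for the synthetic breeding population
#'
#' The default configuration emulates a citrus-style fruit-tree breeding
#' population: ~106 parental cultivars crossed into ~122 pair-cross F1
#' families (~1830 F1 in total), of which 9 families (~42 members each,
#' ~377 F1) plus all parents are genotyped; among the non-genotyped
#' families, 50 are large (more than 10 members, the targets of the
#' family-mean validation) and the rest small. Phenotypes are recorded
#' one to four times per individual across four harvest years, with
#' moderate-to-high heritability (default h2 = 0.6, inside the
#' 0.57-0.82 range typical for fruit-quality traits).
#'
#' @param n_founders number of parental cultivars.
#' @param n_families number of pair-cross families.
#' @param genotyped_family_count leading families flagged genotyped
#'   (all founders are genotyped as well).
#' @param genotyped_family_sizes size range (or per-family sizes) of the
#'   genotyped families.
#' @param n_large_families number of non-genotyped families drawn from
#'   `large_family_sizes`; the remainder use `small_family_sizes`.
#' @param large_family_sizes,small_family_sizes size ranges
#'   c(min, max), or explicit per-family size vectors.
#' @param family_sizes optional explicit sizes for every family
#'   (length `n_families`); overrides the three grouped settings.
#' @param n_snps number of simulated biallelic loci.
#' @param founder_allele_freq_range founder reference-allele frequency
#'   interval within (0, 1].
#' @param sigma_u2,sigma_e2 additive and residual variances
#'   (defaults give h2 = 0.6).
#' @param mu intercept (trait units).
#' @param year_labels harvest years.
#' @param year_effects fixed year effects, one per year label
#'   (first = reference).
#' @param records_per_individual c(min, max) records per individual,
#'   each in a distinct year.
#' @param missing_rate fraction of genotype calls masked as missing
#'   (emulates genotyping-by-sequencing missingness).
#' @param n_qtl when > 0, breeding values are genic: this many loci get
#'   additive effects scaled to `sigma_u2` (default 0: infinitesimal
#'   model, breeding values drawn from N(0, A sigma_u2)).
#' @param trait trait label stamped on the records.
#' @param seed integer seed; fully determines the population.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_founders = 106, n_families = 122,
                       genotyped_family_count = 9,
                       genotyped_family_sizes = c(38, 46),
                       n_large_families = 50,
                       large_family_sizes = c(11, 35),
                       small_family_sizes = c(2, 9),
                       family_sizes = NULL,
                       n_snps = 2500,
                       founder_allele_freq_range = c(0.05, 0.5),
                       sigma_u2 = 0.6, sigma_e2 = 0.4,
                       mu = 10, year_labels = as.character(2009:2012),
                       year_effects = c(0, 0.8, -0.5, 0.4),
                       records_per_individual = c(1, 4),
                       missing_rate = 0.02, n_qtl = 0,
                       trait = "FW", seed = 1L) {
  if (n_founders < 2) stop("need at least 2 founders")
  if (genotyped_family_count > n_families)
    stop("genotyped_family_count exceeds n_families")
  if (genotyped_family_count + n_large_families > n_families &&
      is.null(family_sizes))
    stop("genotyped + large family counts exceed n_families")
  if (!is.null(family_sizes) && length(family_sizes) != n_families)
    stop("family_sizes must have one entry per family")
  if (sigma_u2 < 0 || sigma_e2 < 0) stop("variances must be >= 0")
  if (length(year_effects) != length(year_labels))
    stop("year_effects must match year_labels")
  if (max(records_per_individual) > length(year_labels))
    stop("records_per_individual cannot exceed the number of years")
  structure(list(
    n_founders = n_founders, n_families = n_families,
    genotyped_family_count = genotyped_family_count,
    genotyped_family_sizes = genotyped_family_sizes,
    n_large_families = n_large_families,
    large_family_sizes = large_family_sizes,
    small_family_sizes = small_family_sizes,
    family_sizes = family_sizes,
    n_snps = n_snps,
    founder_allele_freq_range = founder_allele_freq_range,
    sigma_u2 = sigma_u2, sigma_e2 = sigma_e2, mu = mu,
    year_labels = as.character(year_labels),
    year_effects = stats::setNames(year_effects, as.character(year_labels)),
    records_per_individual = records_per_individual,
    missing_rate = missing_rate, n_qtl = n_qtl,
    trait = trait, seed = as.integer(seed)), class = "sim_config")
}

#' Scaled-down configuration for fast end-to-end runs
#'
#' 30 founders, 24 families of 8-20 members (4 genotyped), 500 SNPs:
#' the same structure as [sim_config] at a size that keeps a full
#' cross-validation run interactive.
#'
#' @param ... overrides passed to [sim_config].
#' @export
sim_config_small <- function(...) {
  defaults <- list(n_founders = 30, n_families = 24,
                   genotyped_family_count = 4,
                   genotyped_family_sizes = c(12, 20),
                   n_large_families = 12,
                   large_family_sizes = c(11, 20),
                   small_family_sizes = c(8, 10),
                   n_snps = 500)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

draw_sizes <- function(spec, k) {
  if (k == 0L) return(integer(0))
  if (length(spec) == 2L && is.null(names(spec)))
    sample(seq(spec[1L], spec[2L]), k, replace = TRUE)
  else rep_len(as.integer(spec), k)
}

#' Simulate a pair-cross pedigree
#'
#' Founders are unrelated, non-inbred parental cultivars; each family
#' crosses two distinct founders (parents recur across families but no
#' parent pair is reused). The first `genotyped_family_count` families
#' are flagged genotyped, as are all founders.
#'
#' @param cfg a [sim_config].
#' @param seed seed (default `cfg$seed`); `NULL` leaves the RNG state
#'   untouched (for use inside a seeded pipeline).
#' @return list with `ped` (a sorted `pedigree`), `families` (data
#'   frame as in [gs_dataset]) and `genotyped_ids` (founders + members
#'   of genotyped families).
#' @export
simulate_pedigree <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  founders <- sprintf("P%03d", seq_len(cfg$n_founders))
  sizes <- if (!is.null(cfg$family_sizes)) as.integer(cfg$family_sizes) else {
    ng <- cfg$n_families - cfg$genotyped_family_count - cfg$n_large_families
    c(draw_sizes(cfg$genotyped_family_sizes, cfg$genotyped_family_count),
      draw_sizes(cfg$large_family_sizes, cfg$n_large_families),
      draw_sizes(cfg$small_family_sizes, ng))
  }
  if (any(sizes < 1L)) stop("family sizes must be >= 1")
  # distinct parent pairs so families never merge
  pairs <- matrix(NA_character_, cfg$n_families, 2L)
  seen <- character(0)
  for (f in seq_len(cfg$n_families)) {
    repeat {
      p <- sort(sample(founders, 2L))
      key <- paste(p, collapse = "|")
      if (!key %in% seen) { seen <- c(seen, key); pairs[f, ] <- p; break }
    }
  }
  id <- founders; sire <- rep(NA_character_, length(founders))
  dam <- sire; fam_of <- rep(NA_character_, length(founders))
  members <- vector("list", cfg$n_families)
  for (f in seq_len(cfg$n_families)) {
    kids <- sprintf("F%03d_%02d", f, seq_len(sizes[f]))
    members[[f]] <- kids
    id <- c(id, kids)
    sire <- c(sire, rep(pairs[f, 1L], sizes[f]))
    dam <- c(dam, rep(pairs[f, 2L], sizes[f]))
  }
  ped <- pedigree(id, sire, dam, unknown_code = NA_character_)
  genotyped <- seq_len(cfg$n_families) <= cfg$genotyped_family_count
  families <- data.frame(family_id = sprintf("FAM%03d", seq_len(cfg$n_families)),
                         sire = pairs[, 1L], dam = pairs[, 2L],
                         n_members = sizes, genotyped = genotyped,
                         stringsAsFactors = FALSE)
  families$members <- members
  gids <- c(founders, unlist(members[genotyped]))
  list(ped = ped, families = families, genotyped_ids = gids)
}

#' Gene-drop SNP genotypes down a pedigree
#'
#' Founder genotypes are drawn binomial(2, p_j) with per-locus founder
#' frequencies p_j uniform in `freq_range`; every non-founder inherits
#' one allele from each known parent, chosen uniformly at random per
#' locus and independently across loci (no linkage). An unknown parent
#' contributes a fresh founder-population allele.
#'
#' @param ped a sorted `pedigree`.
#' @param n_snps number of loci.
#' @param freq_range founder reference-allele frequency interval.
#' @param seed seed, or `NULL` to use the current RNG state.
#' @return genotype matrix for all individuals with attribute
#'   `founder_freq` (the true p_j).
#' @export
gene_drop <- function(ped, n_snps, freq_range = c(0.05, 0.5), seed = NULL) {
  check_sorted(ped)
  if (n_snps < 1) stop("n_snps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped); L <- as.integer(n_snps)
  p <- stats::runif(L, freq_range[1L], freq_range[2L])
  pos <- stats::setNames(seq_len(n), ped$id)
  si <- pos[ped$sire]; di <- pos[ped$dam]
  pat <- matrix(0L, n, L); mat <- matrix(0L, n, L)
  for (i in seq_len(n)) {
    pat[i, ] <- if (is.na(si[i])) stats::rbinom(L, 1L, p) else {
      pick <- stats::runif(L) < 0.5
      ifelse(pick, pat[si[i], ], mat[si[i], ])
    }
    mat[i, ] <- if (is.na(di[i])) stats::rbinom(L, 1L, p) else {
      pick <- stats::runif(L) < 0.5
      ifelse(pick, pat[di[i], ], mat[di[i], ])
    }
  }
  g <- pat + mat
  dimnames(g) <- list(ped$id, sprintf("SNP%05d", seq_len(L)))
  storage.mode(g) <- "integer"
  attr(g, "founder_freq") <- p
  g
}

#' Simulate repeated phenotype records
#'
#' Breeding values are drawn from N(0, A sigma_u2) through a Cholesky
#' factor of A (or, in QTL mode, as a genic sum of locus effects);
#' each record is intercept + year effect + breeding value + residual,
#' with each individual measured in 1-4 distinct years.
#'
#' @param ped a sorted `pedigree`.
#' @param A its numerator relationship matrix ([build_A]).
#' @param cfg a [sim_config].
#' @param seed seed, or `NULL` to use the current RNG state.
#' @param genotypes full genotype matrix, required for QTL mode.
#' @return phenotype table with attributes `true_u` (breeding values)
#'   and `true_vc` (the generating [varcomp]).
#' @export
simulate_phenotypes <- function(ped, A, cfg, seed = cfg$seed,
                                genotypes = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  check_sorted(ped)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  R <- tryCatch(chol(as_bare(A) + diag(1e-10, n)), error = function(e)
    stop("A is not positive definite"))
  if (cfg$n_qtl > 0) {
    if (is.null(genotypes)) stop("QTL mode needs the full genotype matrix")
    qtl <- sample(ncol(genotypes), cfg$n_qtl)
    b <- stats::rnorm(cfg$n_qtl)
    p <- attr(genotypes, "founder_freq")[qtl]
    b <- b * sqrt(cfg$sigma_u2 / sum(2 * p * (1 - p) * b^2))
    W <- sweep(genotypes[ped$id, qtl, drop = FALSE], 2L, 2 * p)
    u <- as.vector(W %*% b)
  } else {
    u <- sqrt(cfg$sigma_u2) * as.vector(crossprod(R, stats::rnorm(n)))
  }
  names(u) <- ped$id
  lo <- cfg$records_per_individual[1L]; hi <- cfg$records_per_individual[2L]
  k <- sample(seq(lo, hi), n, replace = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    yrs <- sample(cfg$year_labels, k[i])
    rows[[i]] <- data.frame(individual = ped$id[i], year = yrs,
                            stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rows)
  rec$trait <- cfg$trait
  rec$value <- cfg$mu + cfg$year_effects[rec$year] +
    u[rec$individual] + stats::rnorm(nrow(rec), 0, sqrt(cfg$sigma_e2))
  rownames(rec) <- NULL
  attr(rec, "true_u") <- u
  attr(rec, "true_vc") <- varcomp(max(cfg$sigma_u2, 1e-12),
                                  max(cfg$sigma_e2, 1e-12))
  rec
}

#' Simulate a complete population
#'
#' Runs [simulate_pedigree], [gene_drop] and [simulate_phenotypes]
#' under a single seed, masks a fraction of the genotype calls of the
#' genotyped subset as missing, and returns a ready-to-analyse
#' [gs_dataset] together with the simulation truth.
#'
#' @param cfg a [sim_config].
#' @return a `gs_population`: a [gs_dataset] with extra fields
#'   `truth` (true breeding values, variance components, year effects,
#'   founder allele frequencies), `genotypes_all` (complete genotypes
#'   of every individual) and `cfg`.
#' @export
simulate_population <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sim <- simulate_pedigree(cfg, seed = NULL)
  A <- build_A(sim$ped)
  g_all <- gene_drop(sim$ped, cfg$n_snps, cfg$founder_allele_freq_range,
                     seed = NULL)
  ph <- simulate_phenotypes(sim$ped, A, cfg, seed = NULL, genotypes = g_all)
  g <- g_all[sim$genotyped_ids, , drop = FALSE]
  if (cfg$missing_rate > 0) {
    mask <- stats::runif(length(g)) < cfg$missing_rate
    g[mask] <- NA_integer_
  }
  data <- gs_dataset(sim$ped, g, ph)
  data$families <- sim$families       # keep simulated family labels/flags
  data$truth <- list(u = attr(ph, "true_u"), vc = attr(ph, "true_vc"),
                     year_effects = cfg$year_effects,
                     founder_freq = attr(g_all, "founder_freq"))
  data$genotypes_all <- g_all
  data$cfg <- cfg
  class(data) <- c("gs_population", "gs_dataset")
  data
}

#' Write a simulated population to plain-text files
#'
#' Writes `pedigree.csv`, `genotypes.csv`, `phenotypes.csv` and
#' `truth.json` (true breeding values, variance components and year
#' effects) into `dir`.
#'
#' @param pop a `gs_population` from [simulate_population].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(pop, dir) {
  stopifnot(inherits(pop, "gs_population"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("pedigree.csv", "genotypes.csv",
                            "phenotypes.csv", "truth.json"))
  ped_out <- pop$ped
  ped_out$sire[is.na(ped_out$sire)] <- "0"
  ped_out$dam[is.na(ped_out$dam)] <- "0"
  names(ped_out) <- c("individual", "sire", "dam")
  utils::write.csv(ped_out, paths[1L], row.names = FALSE, quote = FALSE)
  g <- data.frame(individual = rownames(pop$genotypes), pop$genotypes,
                  check.names = FALSE)
  utils::write.csv(g, paths[2L], row.names = FALSE, quote = FALSE)
  utils::write.csv(pop$pheno, paths[3L], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(u = as.list(pop$truth$u),
                            sigma_u2 = pop$truth$vc$sigma_u2,
                            sigma_e2 = pop$truth$vc$sigma_e2,
                            year_effects = as.list(pop$truth$year_effects)),
                       paths[4L], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
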