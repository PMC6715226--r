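test_that("QC removes low call-rate and low-MAF loci with a strict boundary", {
  # direct boundary check on a clean 100-founder panel (200 alleles)
  founders <- sprintf("F%03d", 1:100)
  ped <- pedigree(founders, rep(NA, 100), rep(NA, 100), unknown_code = NA)
  set.seed(7)
  g <- matrix(rbinom(400L, 2L, 0.4), 100L, 4L,
              dimnames = list(founders, c("CR", "RARE", "EDGE", "OK")))
  g[1:25, "CR"] <- NA_integer_                   # call rate 0.75
  g[, "RARE"] <- 0L; g[1, "RARE"] <- 1L          # MAF 1/200 = 0.005
  g[, "EDGE"] <- 0L; g[1:2, "EDGE"] <- 1L        # MAF 2/200 = 0.01 exactly
  res <- qc_genotypes(genotype_matrix(g), ped)
  expect_false("CR" %in% colnames(res$genotypes))
  expect_false("RARE" %in% colnames(res$genotypes))
  expect_true("EDGE" %in% colnames(res$genotypes))   # strict "<" keeps 0.01
  expect_true("OK" %in% colnames(res$genotypes))
  expect_equal(res$report$removed[["call_rate"]], 1L)
  expect_equal(res$report$removed[["maf"]], 1L)
  expect_equal(res$report$n_loci_in - sum(res$report$removed),
               res$report$n_loci_out)
  expect_false(anyNA(res$genotypes))
})

test_that("Mendelian-impossible trio calls are blanked then imputed", {
  ids <- c(sprintf("F%02d", 1:40), "SIRE", "DAM", "KID")
  ped <- pedigree(ids, c(rep(NA, 42), "SIRE"), c(rep(NA, 42), "DAM"),
                  unknown_code = NA)
  set.seed(11)
  g <- matrix(rbinom(length(ids) * 3L, 2L, 0.5), length(ids), 3L,
              dimnames = list(ids, c("L1", "L2", "L3")))
  g[c("SIRE", "DAM", "KID"), c("L1", "L3")] <- 1L   # trio consistent there
  g[c("SIRE", "DAM"), "L2"] <- 0L
  g["KID", "L2"] <- 2L                     # impossible: 0 x 0 -> 2
  res <- qc_genotypes(genotype_matrix(g), ped)
  expect_equal(res$report$n_mendelian_blanked, 1L)
  expect_equal(res$genotypes["KID", "L2"], 0L)  # reimputed from the parents
  expect_false(anyNA(res$genotypes))
})

test_that("the full parental genotype table defines impossible offspring calls", {
  # enumeration oracle: offspring call impossible iff its Mendelian
  # transmission probability is zero given the parental pair
  impossible <- function(gs, gd, go) {
    ps <- gs / 2; pd <- gd / 2
    pr <- c((1 - ps) * (1 - pd),
            ps * (1 - pd) + (1 - ps) * pd,
            ps * pd)
    pr[go + 1] == 0
  }
  filler <- sprintf("F%02d", 1:40)
  for (gs in 0:2) for (gd in 0:2) for (go in 0:2) {
    ids <- c(filler, "S", "D", "K")
    ped <- pedigree(ids, c(rep(NA, 42), "S"), c(rep(NA, 42), "D"),
                    unknown_code = NA)
    set.seed(1)
    g <- matrix(rbinom(length(ids), 2L, 0.5), length(ids), 1L,
                dimnames = list(ids, "L1"))
    g["S", 1] <- gs; g["D", 1] <- gd; g["K", 1] <- go
    res <- qc_genotypes(genotype_matrix(g), ped)
    expect_equal(res$report$n_mendelian_blanked,
                 as.integer(impossible(gs, gd, go)),
                 info = sprintf("parents %d x %d, offspring %d", gs, gd, go))
  }
})

test_that("correlated loci are pruned and QC is idempotent", {
  pop <- small_pop(21)
  g <- pop$genotypes
  g <- cbind(g, DUP = g[, 1L])          # planted perfect duplicate
  res1 <- qc_genotypes(genotype_matrix(g), pop$ped)
  expect_gte(res1$report$removed[["correlated"]], 1L)
  r2 <- cor(res1$genotypes)^2
  expect_lte(max(r2[upper.tri(r2)]), 0.99)

  res2 <- qc_genotypes(res1$genotypes, pop$ped)
  expect_identical(res2$genotypes, res1$genotypes)
  expect_equal(sum(res2$report$removed), 0L)
  expect_equal(res2$report$n_imputed, 0L)
})

test_that("build_G matches hand-evaluated VanRaden examples", {
  g <- matrix(c(0L, 2L, 2L, 0L), 2, 2,
              dimnames = list(c("a", "b"), c("l1", "l2")))
  expect_equal(as_mat(build_G(g)),
               matrix(c(2, -2, -2, 2), 2, 2), ignore_attr = TRUE)

  g <- matrix(c(0L, 1L, 2L), 3, 1, dimnames = list(c("a", "b", "c"), "l1"))
  expect_equal(as_mat(build_G(g)),
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3, 3),
               ignore_attr = TRUE)

  expect_error(build_G(matrix(c(2L, 2L), 2, 1,
                              dimnames = list(c("a", "b"), "l1"))),
               "monomorphic")
})

test_that("G columns are centred and G ignores the reference-allele choice", {
  g <- random_genotypes(sprintf("I%02d", 1:30), 200, seed = 8)
  G <- build_G(g)
  expect_lt(max(abs(colSums(as_mat(G)))), 1e-9)

  flip <- sample(c(TRUE, FALSE), ncol(g), replace = TRUE)
  g2 <- g
  g2[, flip] <- 2L - g2[, flip]
  expect_equal(as_mat(build_G(genotype_matrix(g2))), as_mat(G),
               tolerance = 1e-12)
})

test_that("scale_G_to_A22 solves the two-moment system", {
  G <- relmat(diag(2, 2), c("a", "b"), kind = "G_raw")   # mean diag 2, offdiag 0
  A22 <- relmat(matrix(c(1.1, 0.2, 0.2, 1.1), 2, 2), c("a", "b"), kind = "A22")
  Gs <- scale_G_to_A22(G, A22)
  expect_equal(attr(Gs, "b"), 0.45)
  expect_equal(attr(Gs, "a"), 0.2)

  # fixed point: G already matching A22's two means
  Gs2 <- scale_G_to_A22(Gs, A22)
  expect_equal(attr(Gs2, "b"), 1)
  expect_equal(attr(Gs2, "a"), 0, tolerance = 1e-12)

  # defining post-condition on an arbitrary valid input
  g <- random_genotypes(sprintf("I%02d", 1:25), 300, seed = 4)
  ped <- pedigree(rownames(g), rep(NA, 25), rep(NA, 25), unknown_code = NA)
  A22b <- partition_A(build_A(ped), rownames(g))$A22
  Gs3 <- scale_G_to_A22(build_G(g), A22b)
  expect_equal(mean(diag(Gs3)), mean(diag(A22b)), tolerance = 1e-12)
  off <- function(m) mean(as_mat(m)[upper.tri(m)])
  expect_equal(off(Gs3), off(A22b), tolerance = 1e-12)

  I2 <- relmat(diag(1, 2), c("a", "b"), kind = "G_raw")
  expect_error(scale_G_to_A22(relmat(matrix(c(1, 1, 1, 1), 2, 2), c("a", "b"),
                                     kind = "G_raw"), A22), "singular")
})

test_that("gene-dropped G tracks pedigree relationships (slope near 1)", {
  pop <- small_pop(17, n_snps = 2000, missing_rate = 0)
  A <- build_A(pop$ped)
  G <- build_G(pop$genotypes_all, p = pop$truth$founder_freq)
  a <- as_mat(A)[rownames(G), rownames(G)]
  g <- as_mat(G)
  x <- a[upper.tri(a)]; y <- g[upper.tri(g)]
  slope <- coef(lm(y ~ x))[2]
  expect_lt(abs(slope - 1), 0.1)
})
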