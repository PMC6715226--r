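make_pheno <- function(ind, year, value, trait = "FW") {
  data.frame(individual = ind, year = year, trait = trait, value = value,
             stringsAsFactors = FALSE)
}

test_that("build_design constructs incidence and projection correctly", {
  ph <- make_pheno(c("a", "b", "a"), c("2009", "2009", "2009"), 1:3)
  dm <- build_design(ph, c("a", "b", "c"), "FW")
  expect_equal(colnames(dm$X), "(Intercept)")       # single year: no contrast

  ph <- make_pheno(c("a", "b", "a"), c("2009", "2010", "2010"), 1:3)
  dm <- build_design(ph, c("a", "b", "c"), "FW")
  expect_equal(dim(dm$X), c(3L, 2L))
  expect_equal(dim(dm$Z), c(3L, 3L))
  expect_equal(rowSums(dm$Z), rep(1, 3))
  expect_equal(colSums(dm$Z), c(a = 2, b = 1, c = 0))

  M <- design_projection(dm)
  expect_lt(max(abs(M %*% M - M)), 1e-12)
  expect_lt(max(abs(M %*% dm$X)), 1e-12)

  expect_error(build_design(ph, c("a", "b", "c"), "nope"), "no records")
  expect_error(build_design(ph, c("a"), "FW"), "individual")
})

test_that("MME and direct predictors agree on random instances for A, G, H", {
  for (seed in 1:7) {
    set.seed(seed)
    n_ind <- sample(20:60, 1)
    ped <- random_pedigree(n_ind, seed = seed)
    A <- build_A(ped)
    gids <- ped$id[sample(n_ind, ceiling(n_ind / 3))]
    gids <- ped$id[ped$id %in% gids]
    g <- random_genotypes(gids, 150, seed = seed + 50)
    part <- partition_A(A, gids)
    G_star <- scale_G_to_A22(build_G(g), part$A22)
    Gw <- blend_G(G_star, part$A22)
    H <- build_H(A, Gw)

    n_rec <- 3 * n_ind
    ids_rec <- sample(ped$id, n_rec, replace = TRUE)
    ph <- make_pheno(ids_rec,
                     sample(c("y1", "y2", "y3"), n_rec, replace = TRUE),
                     rnorm(n_rec))
    lambda <- runif(1, 0.2, 5)
    for (K in list(A, Gw, H)) {
      ids <- rownames(K)
      dm <- build_design(ph[ph$individual %in% ids, ], ids, "FW")
      s1 <- solve_blup_mme(dm$y, dm, solve(as_mat(K)), lambda)
      s2 <- solve_blup_direct(dm$y, dm, K, lambda)
      expect_lt(max(abs(s1$u - s2$u)), 1e-8)
      expect_lt(max(abs(s1$fixef - s2$fixef)), 1e-8)
      expect_equal(s1$genotypic - s1$u,
                   rep(s1$fixef[["(Intercept)"]], length(s1$u)),
                   ignore_attr = TRUE)
    }
  }
})

test_that("extreme shrinkage drives breeding values to zero", {
  ped <- random_pedigree(30, seed = 2)
  A <- build_A(ped)
  set.seed(3)
  ph <- make_pheno(sample(ped$id, 60, replace = TRUE),
                   sample(c("y1", "y2"), 60, replace = TRUE), rnorm(60))
  dm <- build_design(ph, ped$id, "FW")
  s <- solve_blup_mme(dm$y, dm, build_A_inverse(ped), 1e9)
  expect_lt(max(abs(s$u)), 1e-3)
})

test_that("responses in the fixed-effect column space give zero breeding values", {
  ped <- random_pedigree(25, seed = 4)
  A <- build_A(ped)
  set.seed(5)
  ind <- sample(ped$id, 50, replace = TRUE)
  yr <- sample(c("y1", "y2"), 50, replace = TRUE)
  ph <- make_pheno(ind, yr, 3 + 2 * (yr == "y2"))   # exactly Xb
  dm <- build_design(ph, ped$id, "FW")
  s <- solve_blup_direct(dm$y, dm, A, 1)
  expect_lt(max(abs(s$u)), 1e-10)
})

test_that("relatives without records inherit information through the kernel", {
  # parent of 10 recorded offspring, itself unrecorded; unrelated recorded
  # founders anchor the population mean below the family's records
  others <- sprintf("U%02d", 1:20)
  ids <- c("PAR", "MATE", sprintf("K%02d", 1:10), others)
  ped <- pedigree(ids,
                  c(NA, NA, rep("PAR", 10), rep(NA, 20)),
                  c(NA, NA, rep("MATE", 10), rep(NA, 20)),
                  unknown_code = NA)
  A <- build_A(ped)
  set.seed(6)
  kids <- sprintf("K%02d", 1:10)
  ph <- make_pheno(c(kids, others), "y1",
                   c(2 + rnorm(10, 0, 0.1), rnorm(20, 0, 0.1)))
  dm <- build_design(ph, ped$id, "FW")
  s <- solve_blup_direct(dm$y, dm, A, 1)
  expect_gt(s$u[["PAR"]], 0.1)   # offspring above the mean pull the parent up
})

test_that("identity-kernel BLUP equals the hand-computed ridge solution", {
  ph <- make_pheno(c("a", "b", "c"), "y1", c(1, 2, 3))
  dm <- build_design(ph, c("a", "b", "c"), "FW")
  K <- diag(3); rownames(K) <- colnames(K) <- c("a", "b", "c")
  s <- solve_blup_direct(dm$y, dm, K, 2)
  # u = (y - ybar) / (1 + lambda) for Z = I, X = intercept
  expect_equal(unname(s$u), c(-1, 0, 1) / 3, tolerance = 1e-12)
})

test_that("heritability follows its defining ratio", {
  expect_equal(heritability(varcomp(3, 1)), 0.75)
  expect_equal(heritability(varcomp(0, 1)), 0)
  expect_equal(heritability(varcomp(2, 2)), 0.5)
  expect_equal(heritability(1.5, 0.5), 0.75)
  expect_error(heritability(0, 0), "zero")
})

test_that("spectral REML matches a dense restricted-likelihood evaluation", {
  pop <- small_pop(9, n_snps = 50)
  A <- build_A(pop$ped)
  dm <- build_design(pop$pheno, pop$ped$id, "FW")
  vc <- reml_estimate(dm$y, dm, A)
  expect_equal(vc$loglik, reml_loglik_dense(dm$y, dm, A, vc),
               tolerance = 1e-6)
  # the optimum really is a maximum of the dense likelihood
  for (f in c(0.8, 1.25)) {
    vc2 <- varcomp(vc$sigma_u2 * f, vc$sigma_e2)
    expect_lt(reml_loglik_dense(dm$y, dm, A, vc2), vc$loglik)
  }
})

test_that("REML estimates are invariant to record order", {
  pop <- small_pop(10, n_snps = 50)
  A <- build_A(pop$ped)
  dm1 <- build_design(pop$pheno, pop$ped$id, "FW")
  set.seed(1)
  perm <- sample(nrow(pop$pheno))
  dm2 <- build_design(pop$pheno[perm, ], pop$ped$id, "FW")
  vc1 <- reml_estimate(dm1$y, dm1, A)
  vc2 <- reml_estimate(dm2$y, dm2, A)
  expect_equal(vc1$sigma_u2, vc2$sigma_u2, tolerance = 1e-6)
  expect_equal(vc1$sigma_e2, vc2$sigma_e2, tolerance = 1e-6)
})

test_that("pure-noise responses give near-zero heritability", {
  h2s <- vapply(1:5, function(seed) {
    cfg <- tiny_cfg(seed, sigma_u2 = 1e-12, sigma_e2 = 1)
    pop <- suppressWarnings(simulate_population(cfg))
    A <- build_A(pop$ped)
    dm <- build_design(pop$pheno, pop$ped$id, "FW")
    suppressWarnings(reml_estimate(dm$y, dm, A)$h2)
  }, numeric(1))
  expect_lt(mean(h2s), 0.1)
  expect_lt(max(h2s), 0.2)
})

test_that("REML recovers the generating heritability on a mid-size pedigree", {
  h2_hat <- vapply(1:3, function(seed) {
    pop <- small_pop(seed + 40, n_snps = 2)  # genotypes unused here
    A <- build_A(pop$ped)
    dm <- build_design(pop$pheno, pop$ped$id, "FW")
    reml_estimate(dm$y, dm, A)$h2
  }, numeric(1))
  expect_lt(abs(mean(h2_hat) - 0.6), 0.1)
})

test_that("single-step fits collapse to ABLUP and GBLUP at the parameter limits", {
  pop <- qc_pop(small_pop(12))
  A <- build_A(pop$ped); A_inv <- build_A_inverse(pop$ped)
  part <- partition_A(A, pop$genotyped_ids)
  G_star <- scale_G_to_A22(build_G(pop$genotypes), part$A22)

  # tau = omega = 0: exact ABLUP reproduction
  k0 <- ss_kernel(A, A_inv, G_star, part$A22, h_params(tau = 0))
  f_ab <- fit_blup(pop$pheno, "FW", A, kernel_inv = A_inv)
  f_ss0 <- fit_blup(pop$pheno, "FW", k0$K, kernel_inv = k0$K_inv)
  expect_identical(f_ss0$u, f_ab$u)
  expect_identical(f_ss0$vc$h2, f_ab$vc$h2)

  # all individuals genotyped, alpha = 1, beta = 0, tau = omega = 1: GBLUP
  g_all <- pop$genotypes_all[pop$ped$id, ]
  part_all <- partition_A(A, pop$ped$id)
  Gs_all <- scale_G_to_A22(build_G(g_all), part_all$A22)
  kH <- ss_kernel(A, A_inv, Gs_all, part_all$A22,
                            h_params(alpha = 1, beta = 0, tau = 1))
  f_g <- fit_blup(pop$pheno, "FW", Gs_all, method = "GBLUP")
  f_ss1 <- fit_blup(pop$pheno, "FW", kH$K, kernel_inv = kH$K_inv,
                    vc = f_g$vc)
  expect_lt(max(abs(f_ss1$u - f_g$u[names(f_ss1$u)])), 1e-8)
})
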