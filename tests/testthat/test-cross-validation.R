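test_that("weighted correlation reduces to Pearson and honours weights", {
  set.seed(1)
  x <- rnorm(20); y <- x + rnorm(20)
  wc <- weighted_correlation(x, y)
  expect_equal(wc$r, cor(x, y), tolerance = 1e-12)
  expect_equal(wc$se, sqrt((1 - wc$r^2) / (20 - 2)), tolerance = 1e-12)

  w <- runif(20, 0.5, 3)
  expect_equal(weighted_correlation(x, 2 * x + 1, w)$r, 1, tolerance = 1e-12)

  # brute-force weighted-moment oracle on the hand example
  x <- c(1, 2, 3); y <- c(1, 2, 4); w <- c(1, 1, 2)
  mx <- sum(w * x) / sum(w); my <- sum(w * y) / sum(w)
  r_oracle <- sum(w * (x - mx) * (y - my)) /
    sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
  expect_equal(weighted_correlation(x, y, w)$r, r_oracle, tolerance = 1e-12)

  expect_error(weighted_correlation(c(1, 1, 1), y), "variance")
  expect_error(weighted_correlation(x, y, c(1, -1, 1)), "positive")
  expect_error(weighted_correlation(x, y[1:2]), "length")
})

test_that("year-effect adjustment subtracts the estimated effects", {
  ph <- data.frame(individual = c("a", "b"), year = c("2009", "2010"),
                   trait = "FW", value = c(10, 10))
  eff0 <- c("2009" = 0, "2010" = 0)
  expect_equal(adjust_year_effects(ph, eff0)$value, c(10, 10))
  eff <- c("2009" = 0, "2010" = 2)
  adj <- adjust_year_effects(ph, eff)
  expect_equal(adj$value, c(10, 8))
  expect_error(adjust_year_effects(ph, c("2009" = 0)), "2010")

  # family mean of adjusted records is order-invariant
  set.seed(2)
  ph2 <- data.frame(individual = "a", year = sample(c("2009", "2010"), 8,
                                                    replace = TRUE),
                    trait = "FW", value = rnorm(8))
  m1 <- mean(adjust_year_effects(ph2, eff)$value)
  m2 <- mean(adjust_year_effects(ph2[sample(8), ], eff)$value)
  expect_equal(m1, m2)
})

test_that("genotyped CV runs one cycle per genotyped family without leakage", {
  pop <- qc_pop(small_pop(31))
  cv <- cv_genotyped(pop, "FW", tau_grid = 1)
  n_gen_fam <- sum(pop$families$genotyped)
  expect_equal(cv$GBLUP$n_cycles, n_gen_fam)
  expect_equal(length(cv$GBLUP$per_cycle), n_gen_fam)
  expect_equal(sort(unique(cv$GBLUP$pairs$family)),
               sort(pop$families$family_id[pop$families$genotyped]))

  # no leakage: perturbing the held-out family's phenotypes changes
  # neither its predictions nor its targets in that family's cycle
  fam <- pop$families[pop$families$genotyped, ][1, ]
  members <- fam$members[[1]]
  pop2 <- pop
  idx <- pop2$pheno$individual %in% members
  set.seed(99)
  pop2$pheno$value[idx] <- pop2$pheno$value[idx] + rnorm(sum(idx), 0, 5)
  cv2 <- suppressWarnings(cv_genotyped(pop2, "FW", tau_grid = 1))
  p1 <- cv$ssGBLUP_tau1.00$pairs
  p2 <- cv2$ssGBLUP_tau1.00$pairs
  expect_equal(p2$predicted[p2$family == fam$family_id],
               p1$predicted[p1$family == fam$family_id], tolerance = 1e-10)
  # targets DO change (they come from the full-data fit), predictions do not
  expect_false(isTRUE(all.equal(p2$target, p1$target)))
})

test_that("non-genotyped CV targets only families above the strict size threshold", {
  pop <- qc_pop(small_pop(32))
  fams <- pop$families
  expect_true(any(!fams$genotyped & fams$n_members == 10))  # boundary exists
  cv <- cv_nongenotyped(pop, "FW", tau = 1)
  used <- fams[match(cv$ABLUP$pairs$family, fams$family_id), ]
  expect_true(all(!used$genotyped))
  expect_true(all(used$n_members > 10))
  expect_false(any(fams$family_id[fams$n_members == 10] %in%
                     cv$ABLUP$pairs$family))
  expect_equal(cv$ABLUP$weights, used$n_members)
})

test_that("predictions are identical within an omitted non-genotyped family", {
  pop <- qc_pop(small_pop(33))
  fams <- pop$families
  target <- fams[!fams$genotyped & fams$n_members > 10, ][1, ]
  members <- target$members[[1]]
  train <- pop$pheno[!(pop$pheno$individual %in% members), ]
  A <- build_A(pop$ped); A_inv <- build_A_inverse(pop$ped)
  fit <- fit_blup(train, "FW", A, kernel_inv = A_inv)
  pred <- predict(fit, members, type = "genotypic")
  expect_lt(diff(range(pred)), 1e-10)

  part <- partition_A(A, pop$genotyped_ids)
  G_star <- scale_G_to_A22(build_G(pop$genotypes), part$A22)
  kh <- ss_kernel(A, A_inv, G_star, part$A22, h_params(tau = 0.75))
  fit_h <- fit_blup(train, "FW", kh$K, kernel_inv = kh$K_inv)
  expect_lt(diff(range(predict(fit_h, members, type = "genotypic"))), 1e-10)
})

test_that("tau = omega = 0 single-step CV reproduces the ABLUP CV exactly", {
  pop <- qc_pop(small_pop(34))
  cv <- cv_nongenotyped(pop, "FW", tau = 0)
  expect_identical(cv$ssGBLUP$r, cv$ABLUP$r)
  expect_identical(cv$ssGBLUP$pairs$predicted, cv$ABLUP$pairs$predicted)
})

test_that("best_tau picks the grid value with the highest pooled accuracy", {
  cv <- structure(list(
    GBLUP = list(model = "GBLUP", r = 0.5),
    ssGBLUP_tau1.00 = list(model = "ssGBLUP_tau1.00", r = 0.61),
    ssGBLUP_tau0.75 = list(model = "ssGBLUP_tau0.75", r = 0.63),
    ssGBLUP_tau0.50 = list(model = "ssGBLUP_tau0.50", r = 0.58)),
    class = "cv_result", scheme = "genotyped", trait = "FW")
  expect_equal(best_tau(cv), 0.75)
})
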