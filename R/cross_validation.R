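#' Bundle pedigree, genotypes and phenotypes for genetic evaluation
#'
#' Groups the full-sib offspring of each parent pair into a pair-cross
#' family and flags a family as genotyped when every member has SNP
#' data. Founders (individuals with no known parents) belong to no
#' family.
#'
#' @param ped a sorted `pedigree`.
#' @param genotypes genotype matrix of the genotyped individuals (may
#'   contain missing calls before QC), or `NULL` for pedigree-only data.
#' @param pheno phenotype table (`individual`, `year`, `trait`, `value`).
#' @return a `gs_dataset`: list with `ped`, `genotypes`, `pheno`,
#'   `families` (data frame: `family_id`, `sire`, `dam`, `n_members`,
#'   `genotyped`, list-column `members`) and `genotyped_ids`.
#' @export
gs_dataset <- function(ped, genotypes, pheno) {
  check_sorted(ped)
  if (!is.null(genotypes)) {
    genotypes <- genotype_matrix(genotypes)
    absent <- setdiff(rownames(genotypes), ped$id)
    if (length(absent))
      stop("genotyped individual(s) missing from pedigree: ",
           paste(absent, collapse = ", "))
  }
  stopifnot(all(c("individual", "year", "trait", "value") %in% names(pheno)))
  off <- ped[!is.na(ped$sire) & !is.na(ped$dam), , drop = FALSE]
  gids <- if (is.null(genotypes)) character(0) else rownames(genotypes)
  families <- NULL
  if (nrow(off)) {
    key <- paste(off$sire, off$dam, sep = " x ")
    split_members <- split(off$id, key)
    fam_key <- names(split_members)
    parents <- do.call(rbind, strsplit(fam_key, " x ", fixed = TRUE))
    families <- data.frame(
      family_id = sprintf("FAM%03d", seq_along(fam_key)),
      sire = parents[, 1L], dam = parents[, 2L],
      n_members = lengths(split_members),
      genotyped = vapply(split_members, function(m) all(m %in% gids), logical(1)),
      stringsAsFactors = FALSE, row.names = NULL)
    families$members <- unname(split_members)
  }
  structure(list(ped = ped, genotypes = genotypes, pheno = pheno,
                 families = families, genotyped_ids = gids),
            class = "gs_dataset")
}

#' @export
print.gs_dataset <- function(x, ...) {
  cat(sprintf("gs_dataset: %d individuals, %d genotyped, %d families (%d genotyped)\n",
              nrow(x$ped), length(x$genotyped_ids),
              if (is.null(x$families)) 0L else nrow(x$families),
              if (is.null(x$families)) 0L else sum(x$families$genotyped)))
  cat(sprintf("  %d phenotype records, traits: %s\n", nrow(x$pheno),
              paste(unique(x$pheno$trait), collapse = ", ")))
  invisible(x)
}

#' Weighted Pearson correlation with standard error
#'
#' r = weighted covariance / sqrt(product of weighted variances), all
#' moments taken about the weighted means. The standard error uses
#' sqrt((1 - r^2)/(n_eff - 2)) with the effective sample size
#' n_eff = (sum w)^2 / sum w^2 (equal weights give the usual Pearson r
#' and its textbook standard error).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param w positive weights (default: equal).
#' @return list with `r`, `se` and `n_eff`.
#' @export
weighted_correlation <- function(x, y, w = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 pairs")
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n || any(w <= 0)) stop("weights must be positive, one per pair")
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) stop("zero variance in x or y")
  r <- sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
  n_eff <- 1 / sum(w^2)
  list(r = r, se = sqrt((1 - r^2) / (n_eff - 2)), n_eff = n_eff)
}

#' Adjust phenotype records for estimated year effects
#'
#' Subtracts from each record the year effect estimated by a full-data
#' pedigree-BLUP fit (reference year has effect 0), leaving records on a
#' common-year scale for family-mean comparisons.
#'
#' @param ph phenotype table.
#' @param year_effects named numeric vector (names = year labels)
#'   covering every year in `ph`, e.g. from [year_effects].
#' @return `ph` with `value` replaced by the adjusted value.
#' @export
adjust_year_effects <- function(ph, year_effects) {
  yrs <- as.character(ph$year)
  unknown <- setdiff(unique(yrs), names(year_effects))
  if (length(unknown)) stop("no estimated effect for year(s): ",
                            paste(unknown, collapse = ", "))
  ph$value <- ph$value - year_effects[yrs]
  ph
}

#' Single-step kernel and inverse at given tuning parameters
#'
#' Returns the relationship kernel used by the single-step model
#' together with its inverse: the inverse is assembled directly by
#' [build_H_inverse] and the kernel is its dense inverse (for
#' tau = omega = 1 this equals the combined matrix of [build_H] built
#' from the blended genomic block). tau = omega = 0 collapses exactly to
#' the pedigree model (kernel A, inverse A_inv), so downstream results
#' match the pure pedigree evaluation bit for bit.
#'
#' @param A,A_inv numerator relationship matrix and its inverse.
#' @param G_star rescaled genomic matrix of the genotyped block.
#' @param A22 pedigree block of the genotyped individuals.
#' @param params an [h_params] list.
#' @return list with `K` (kernel) and `K_inv`.
#' @export
ss_kernel <- function(A, A_inv, G_star, A22, params) {
  if (params$tau == 0 && params$omega == 0)
    return(list(K = A, K_inv = A_inv))
  Hinv <- build_H_inverse(A_inv, G_star, A22, params)
  K <- solve(as_bare(Hinv))
  K <- (K + t(K)) / 2
  rownames(K) <- colnames(K) <- rm_ids(Hinv)
  list(K = relmat(K, rm_ids(Hinv), kind = "H"), K_inv = Hinv)
}

# Shared relationship machinery for both CV schemes
cv_matrices <- function(data, alpha, beta) {
  A <- build_A(data$ped)
  A_inv <- build_A_inverse(data$ped)
  part <- partition_A(A, data$genotyped_ids)
  G <- build_G(data$genotypes)
  gids <- rm_ids(part$A22)
  G <- relmat(as_bare(G)[gids, gids, drop = FALSE], gids, kind = "G_raw")
  G_star <- scale_G_to_A22(G, part$A22)
  list(A = A, A_inv = A_inv, A22 = part$A22, G_star = G_star,
       G_blend = blend_G(G_star, part$A22, alpha, beta))
}

#' Leave-one-family-out cross-validation for genotyped individuals
#'
#' Target values are the genotypic values (intercept + breeding value)
#' of the members of the genotyped families, estimated by ABLUP from
#' ALL phenotype records. In each cycle one genotyped family's records
#' are removed from the training response (the individuals stay in the
#' pedigree and genotype matrix) and each model predicts the omitted
#' family's genotypic values. With k genotyped families the scheme runs
#' exactly k cycles. Accuracy is the correlation between targets and
#' predictions pooled over cycles; per-cycle correlations are also
#' reported.
#'
#' @param data a [gs_dataset] with complete (post-QC) genotypes.
#' @param trait trait label.
#' @param tau_grid values of tau (= omega) for the single-step models.
#' @param alpha,beta genomic/pedigree blending weights.
#' @param models subset of `c("GBLUP", "ssGBLUP")`.
#' @param refit_varcomp re-estimate variance components by REML inside
#'   every training cycle (default) or reuse the full-data estimates.
#' @return a `cv_result` list, one element per model (ssGBLUP once per
#'   tau), each with `pairs` (family, individual, target, predicted),
#'   `r`, `se`, `n`, `per_cycle`.
#' @export
cv_genotyped <- function(data, trait, tau_grid = c(1, 0.75, 0.5),
                         alpha = 0.95, beta = 0.05,
                         models = c("GBLUP", "ssGBLUP"),
                         refit_varcomp = TRUE) {
  stopifnot(inherits(data, "gs_dataset"))
  models <- match.arg(models, several.ok = TRUE)
  fams <- data$families[data$families$genotyped, , drop = FALSE]
  if (nrow(fams) < 2L) stop("need at least 2 genotyped families")
  mats <- cv_matrices(data, alpha, beta)
  ped_ids <- data$ped$id

  full_ablup <- fit_blup(data$pheno, trait, mats$A, kernel_inv = mats$A_inv,
                         method = "ABLUP")
  targets <- predict(full_ablup, type = "genotypic")

  model_keys <- c(if ("GBLUP" %in% models) "GBLUP",
                  if ("ssGBLUP" %in% models)
                    sprintf("ssGBLUP_tau%.2f", tau_grid))
  kernels <- list()
  if ("GBLUP" %in% models)
    kernels[["GBLUP"]] <- list(K = mats$G_blend,
                               K_inv = solve(as_bare(mats$G_blend)))
  if ("ssGBLUP" %in% models)
    for (tau in tau_grid)
      kernels[[sprintf("ssGBLUP_tau%.2f", tau)]] <-
        ss_kernel(mats$A, mats$A_inv, mats$G_star, mats$A22,
                  h_params(alpha, beta, tau))

  vc_full <- if (!refit_varcomp)
    lapply(kernels, function(k) fit_blup(data$pheno, trait, k$K,
                                         kernel_inv = k$K_inv)$vc)
  out <- lapply(model_keys, function(key) {
    pairs <- NULL; per_cycle <- numeric(0)
    for (fi in seq_len(nrow(fams))) {
      fam <- fams[fi, ]
      members <- fam$members[[1L]]
      if (!any(names(targets) %in% members))
        stop("genotyped family ", fam$family_id, " has no target values")
      train <- data$pheno[!(as.character(data$pheno$individual) %in% members), ,
                          drop = FALSE]
      k <- kernels[[key]]
      fit <- fit_blup(train, trait, k$K, kernel_inv = k$K_inv,
                      vc = if (refit_varcomp) NULL else vc_full[[key]],
                      method = key)
      pred <- predict(fit, members, type = "genotypic")
      tgt <- targets[members]
      pairs <- rbind(pairs, data.frame(family = fam$family_id,
                                       individual = members,
                                       target = unname(tgt),
                                       predicted = unname(pred)))
      per_cycle <- c(per_cycle,
                     stats::setNames(stats::cor(tgt, pred), fam$family_id))
    }
    wc <- weighted_correlation(pairs$target, pairs$predicted)
    list(model = key, pairs = pairs, r = wc$r, se = wc$se,
         n = nrow(pairs), n_cycles = nrow(fams), per_cycle = per_cycle)
  })
  names(out) <- model_keys
  structure(out, class = "cv_result", scheme = "genotyped", trait = trait)
}

#' Leave-one-family-out cross-validation for non-genotyped individuals
#'
#' Target families are the non-genotyped families with strictly more
#' than `min_members` F1 individuals; their observed year-adjusted
#' family means are the target values. Year effects are estimated once
#' from all records by ABLUP. In each cycle the target family's records
#' are removed and the model's predicted genotypic value for the family
#' (identical across its members, whose records are all absent) is
#' compared with the observed mean. Accuracy is the weighted
#' correlation across families with family sizes as weights.
#'
#' @param data a [gs_dataset] with complete (post-QC) genotypes.
#' @param trait trait label.
#' @param tau tau (= omega) used for the single-step model, typically
#'   the value with the best genotyped-CV accuracy.
#' @param alpha,beta genomic/pedigree blending weights.
#' @param models subset of `c("ABLUP", "ssGBLUP")`.
#' @param min_members strict family-size threshold (default 10: a family
#'   of exactly 10 members is not a target).
#' @param refit_varcomp re-estimate variance components in every cycle.
#' @return a `cv_result` list, one element per model, each with `pairs`
#'   (family, size, observed, predicted), `r`, `se`, `n`, `weights`.
#' @export
cv_nongenotyped <- function(data, trait, tau = 1, alpha = 0.95, beta = 0.05,
                            models = c("ABLUP", "ssGBLUP"),
                            min_members = 10L, refit_varcomp = TRUE) {
  stopifnot(inherits(data, "gs_dataset"))
  models <- match.arg(models, several.ok = TRUE)
  fams <- data$families[!data$families$genotyped &
                          data$families$n_members > min_members, , drop = FALSE]
  if (nrow(fams) < 3L)
    stop("fewer than 3 eligible target families (non-genotyped, > ",
         min_members, " members)")
  mats <- cv_matrices(data, alpha, beta)

  full_ablup <- fit_blup(data$pheno, trait, mats$A, kernel_inv = mats$A_inv,
                         method = "ABLUP")
  ph_adj <- adjust_year_effects(data$pheno[data$pheno$trait == trait, ,
                                           drop = FALSE],
                                year_effects(full_ablup))

  kernels <- list()
  if ("ABLUP" %in% models)
    kernels[["ABLUP"]] <- list(K = mats$A, K_inv = mats$A_inv)
  if ("ssGBLUP" %in% models)
    kernels[["ssGBLUP"]] <- ss_kernel(mats$A, mats$A_inv, mats$G_star,
                                      mats$A22, h_params(alpha, beta, tau))

  vc_full <- if (!refit_varcomp)
    lapply(kernels, function(k) fit_blup(data$pheno, trait, k$K,
                                         kernel_inv = k$K_inv)$vc)
  out <- lapply(names(kernels), function(key) {
    pairs <- NULL
    for (fi in seq_len(nrow(fams))) {
      fam <- fams[fi, ]
      members <- fam$members[[1L]]
      obs_rec <- ph_adj[as.character(ph_adj$individual) %in% members &
                          !is.na(ph_adj$value), , drop = FALSE]
      if (nrow(obs_rec) == 0L) next
      train <- data$pheno[!(as.character(data$pheno$individual) %in% members), ,
                          drop = FALSE]
      k <- kernels[[key]]
      fit <- fit_blup(train, trait, k$K, kernel_inv = k$K_inv,
                      vc = if (refit_varcomp) NULL else vc_full[[key]],
                      method = key)
      pred <- mean(predict(fit, members, type = "genotypic"))
      pairs <- rbind(pairs, data.frame(family = fam$family_id,
                                       size = fam$n_members,
                                       observed = mean(obs_rec$value),
                                       predicted = pred))
    }
    if (is.null(pairs) || nrow(pairs) < 3L)
      stop("fewer than 3 target families with records")
    wc <- weighted_correlation(pairs$observed, pairs$predicted, pairs$size)
    list(model = key, tau = if (key == "ssGBLUP") tau else NA_real_,
         pairs = pairs, r = wc$r, se = wc$se, n = nrow(pairs),
         weights = pairs$size, n_eff = wc$n_eff)
  })
  names(out) <- names(kernels)
  structure(out, class = "cv_result", scheme = "nongenotyped", trait = trait)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Leave-one-family-out CV (%s scheme), trait '%s'\n",
              attr(x, "scheme"), attr(x, "trait")))
  for (m in x)
    cat(sprintf("  %-18s r = %.3f (SE %.3f), n = %d\n",
                m$model, m$r, m$se, m$n))
  invisible(x)
}

#' Pick the tau with the best genotyped-CV accuracy
#'
#' @param cv a `cv_result` from [cv_genotyped].
#' @return the tau value of the ssGBLUP entry with the highest pooled r.
#' @export
best_tau <- function(cv) {
  ss <- grep("^ssGBLUP_tau", names(cv), value = TRUE)
  if (!length(ss)) stop("no ssGBLUP entries in this cv_result")
  rs <- vapply(cv[ss], `[[`, numeric(1), "r")
  as.numeric(sub("^ssGBLUP_tau", "", names(which.max(rs))))
}
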