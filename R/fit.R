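#' Fit a BLUP genetic evaluation model
#'
#' Central fitting function. Fits the linear mixed model
#' y = Xb + Zu + e for one trait, with u ~ N(0, K sigma_u2) for an
#' arbitrary relationship kernel K: the pedigree matrix A (ABLUP), a
#' blended genomic matrix (GBLUP), or the single-step combined matrix H
#' (ssGBLUP). Variance components are estimated by REML unless supplied,
#' and the breeding values are obtained from Henderson's mixed-model
#' equations.
#'
#' Records of individuals absent from the kernel are dropped (this is
#' how GBLUP restricts the data to the genotyped set).
#'
#' @param pheno phenotype table (`individual`, `year`, `trait`, `value`).
#' @param trait trait label to analyse.
#' @param kernel relationship kernel ([relmat] or named symmetric
#'   matrix) defining the individuals in the model.
#' @param kernel_inv optional inverse of `kernel`; computed densely when
#'   missing.
#' @param vc optional [varcomp]; when supplied REML is skipped.
#' @param method label stored on the fit (e.g. "ABLUP", "GBLUP",
#'   "ssGBLUP"); defaults to a guess from the kernel kind.
#' @param ... passed to [reml_estimate].
#' @return an object of class `blup_fit`.
#' @seealso [coef.blup_fit], [predict.blup_fit], [summary.blup_fit]
#' @export
fit_blup <- function(pheno, trait, kernel, kernel_inv = NULL, vc = NULL,
                     method = NULL, ...) {
  cl <- match.call()
  ids <- if (is_relmat(kernel)) rm_ids(kernel) else rownames(kernel)
  if (is.null(ids)) stop("kernel must carry individual ids")
  if (is.null(method)) {
    kind <- if (is_relmat(kernel)) rm_kind(kernel) else ""
    method <- switch(kind, A = "ABLUP", G_raw = , G_scaled = "GBLUP",
                     H = "ssGBLUP", "BLUP")
  }
  sub <- pheno[pheno$trait == trait & as.character(pheno$individual) %in% ids, ,
               drop = FALSE]
  if (nrow(sub) == 0L) stop("no records for trait '", trait,
                            "' among the kernel's individuals")
  dm <- build_design(sub, ids, trait)
  if (is.null(vc)) vc <- reml_estimate(dm$y, dm, kernel, ...)
  if (is.null(kernel_inv)) {
    Kb <- if (is_relmat(kernel)) as_bare(kernel) else as.matrix(kernel)
    kernel_inv <- tryCatch(solve(Kb), error = function(e)
      stop("kernel is singular; supply kernel_inv or blend the kernel"))
  }
  sol <- solve_blup_mme(dm$y, dm, kernel_inv, vc$lambda)
  fitted <- as.vector(dm$X %*% sol$fixef + dm$Z %*% sol$u)
  structure(list(call = cl, method = method, trait = trait,
                 vc = vc, fixef = sol$fixef, u = sol$u,
                 genotypic = sol$genotypic, fitted = fitted,
                 y = dm$y, records = dm$records,
                 year_levels = dm$year_levels,
                 n_records = length(dm$y), n_individuals = length(ids)),
            class = "blup_fit")
}

#' @export
print.blup_fit <- function(x, ...) {
  cat(sprintf("%s fit for trait '%s'\n", x$method, x$trait))
  cat(sprintf("  %d records, %d individuals in the kernel\n",
              x$n_records, x$n_individuals))
  cat(sprintf("  sigma_u2 = %.4g, sigma_e2 = %.4g, h2 = %.3f\n",
              x$vc$sigma_u2, x$vc$sigma_e2, x$vc$h2))
  invisible(x)
}

#' Summarise a BLUP fit
#' @param object a `blup_fit`.
#' @param ... unused.
#' @export
summary.blup_fit <- function(object, ...) {
  structure(list(fit = object,
                 fixef = object$fixef,
                 vc = object$vc,
                 u_summary = summary(object$u),
                 resid_summary = summary(object$y - object$fitted)),
            class = "summary.blup_fit")
}

#' @export
print.summary.blup_fit <- function(x, ...) {
  print(x$fit)
  cat("\nFixed effects:\n"); print(round(x$fixef, 4))
  cat("\nBreeding values:\n"); print(x$u_summary)
  cat("\nResiduals:\n"); print(x$resid_summary)
  invisible(x)
}

#' @export
coef.blup_fit <- function(object, ...) object$fixef

#' @export
fitted.blup_fit <- function(object, ...) object$fitted

#' @export
residuals.blup_fit <- function(object, ...) object$y - object$fitted

#' @export
logLik.blup_fit <- function(object, ...) {
  structure(object$vc$loglik, df = 2L, class = "logLik")
}

#' Predicted breeding or genotypic values
#'
#' @param object a `blup_fit`.
#' @param ids individuals to predict for (default: all in the kernel).
#' @param type `"genotypic"` (intercept + breeding value, the scale used
#'   for selection decisions) or `"breeding"` (u alone).
#' @param ... unused.
#' @return named numeric vector.
#' @export
predict.blup_fit <- function(object, ids = NULL,
                             type = c("genotypic", "breeding"), ...) {
  type <- match.arg(type)
  v <- if (type == "genotypic") object$genotypic else object$u
  if (is.null(ids)) return(v)
  missing <- setdiff(ids, names(v))
  if (length(missing)) stop("individual(s) not in the model: ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  v[ids]
}

#' Breeding values of a fit
#' @param object a `blup_fit`.
#' @return named numeric vector u-hat.
#' @export
breeding_values <- function(object) {
  stopifnot(inherits(object, "blup_fit"))
  object$u
}

#' Estimated year effects of a fit
#'
#' Returns the year-effect estimates on the reference-level scale: the
#' first (reference) year has effect 0, the others the corresponding
#' fixed-effect contrasts.
#'
#' @param object a `blup_fit`.
#' @return named numeric vector, one entry per year level.
#' @export
year_effects <- function(object) {
  stopifnot(inherits(object, "blup_fit"))
  yl <- object$year_levels
  eff <- stats::setNames(numeric(length(yl)), yl)
  if (length(yl) > 1L) {
    contr <- paste0("year", yl[-1L])
    eff[yl[-1L]] <- object$fixef[contr]
  }
  eff
}

#' @export
plot.blup_fit <- function(x, ...) {
  graphics::plot(x$fitted, x$y,
                 xlab = "Fitted value", ylab = "Observed record",
                 main = sprintf("%s: %s", x$method, x$trait), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
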