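#' Design matrices for the repeated-records mixed model
#'
#' Builds the response and incidence structures of the model
#' y = Xb + Zu + e for one trait: X carries an intercept and year
#' contrasts (first year as reference), Z maps each record to its
#' individual. Individuals without records keep an all-zero Z column and
#' enter the model only through the relationship kernel.
#'
#' @param ph phenotype table: data frame with columns `individual`,
#'   `year`, `trait`, `value` (long format, repeated records allowed).
#' @param individual_order character vector fixing the column order of Z
#'   (usually the ids of the relationship kernel).
#' @param trait trait label to extract.
#' @return list with `y` (numeric response), `X`, `Z` (dense incidence
#'   matrices), `year_levels`, `individual_order` and `records` (the
#'   subset of `ph` used, in row order of `y`).
#' @export
build_design <- function(ph, individual_order, trait) {
  stopifnot(all(c("individual", "year", "trait", "value") %in% names(ph)))
  rec <- ph[ph$trait == trait & !is.na(ph$value), , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records for trait '", trait, "'")
  rec$individual <- as.character(rec$individual)
  bad <- setdiff(rec$individual, individual_order)
  if (length(bad))
    stop("record individual(s) not in individual_order: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  year <- factor(as.character(rec$year))
  X <- if (nlevels(year) > 1L) {
    stats::model.matrix(~year, data = data.frame(year = year))
  } else {
    matrix(1, nrow(rec), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL
  n <- nrow(rec); q <- length(individual_order)
  Z <- matrix(0, n, q, dimnames = list(NULL, individual_order))
  Z[cbind(seq_len(n), match(rec$individual, individual_order))] <- 1
  list(y = as.numeric(rec$value), X = X, Z = Z,
       year_levels = levels(year), individual_order = individual_order,
       records = rec)
}

#' Projection matrix onto the orthogonal complement of X
#'
#' M = I - X (X'X)^-1 X', the operator that sweeps fixed effects out of
#' the response in the closed-form breeding-value predictors.
#'
#' @param dm design list from [build_design] (or any list with an `X`).
#' @return dense n x n projection matrix.
#' @export
design_projection <- function(dm) {
  X <- dm$X
  diag(nrow(X)) - X %*% solve(crossprod(X), t(X))
}

#' Variance components container
#' @param sigma_u2 additive genetic variance (>= 0).
#' @param sigma_e2 residual variance (> 0).
#' @param ... further fields (loglik, convergence info) stored as is.
#' @return a `varcomp` list with `sigma_u2`, `sigma_e2`,
#'   `lambda` = sigma_e2/sigma_u2 and `h2` = sigma_u2/(sigma_u2+sigma_e2).
#' @export
varcomp <- function(sigma_u2, sigma_e2, ...) {
  if (sigma_u2 < 0) stop("sigma_u2 must be >= 0")
  if (sigma_e2 <= 0) stop("sigma_e2 must be > 0")
  structure(list(sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                 lambda = if (sigma_u2 > 0) sigma_e2 / sigma_u2 else Inf,
                 h2 = sigma_u2 / (sigma_u2 + sigma_e2), ...),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("Variance components: sigma_u2 = %.6g, sigma_e2 = %.6g\n",
              x$sigma_u2, x$sigma_e2))
  cat(sprintf("  lambda = %.6g, h2 = %.4f\n", x$lambda, x$h2))
  if (isTRUE(x$pinned))
    cat("  note: sigma_u2 pinned at its lower bound\n")
  invisible(x)
}

#' Narrow-sense heritability from variance components
#'
#' @param vc a `varcomp` object, or a numeric `sigma_u2` (then `sigma_e2`
#'   must be given).
#' @param sigma_e2 residual variance when `vc` is numeric.
#' @return h2 = sigma_u2 / (sigma_u2 + sigma_e2).
#' @export
heritability <- function(vc, sigma_e2 = NULL) {
  if (inherits(vc, "varcomp")) return(vc$sigma_u2 / (vc$sigma_u2 + vc$sigma_e2))
  sigma_u2 <- vc
  if (is.null(sigma_e2)) stop("sigma_e2 required when vc is numeric")
  if (sigma_u2 < 0 || sigma_e2 < 0) stop("variances must be non-negative")
  if (sigma_u2 + sigma_e2 == 0) stop("both variances are zero")
  sigma_u2 / (sigma_u2 + sigma_e2)
}

# Restricted log-likelihood pieces on the fixed-effects complement.
# Returns theta (eigenvalues of the projected kernel), eta (rotated
# response) and the log-determinant of X'X, from which the profiled
# restricted likelihood of the variance ratio delta = sigma_e2/sigma_u2
# is a cheap 1-D function.
reml_spectral <- function(y, X, S) {
  n <- length(y); p <- qr(X)$rank
  if (p != ncol(X)) stop("X is rank deficient; use reference-level contrasts")
  qrX <- qr(X)
  Q <- qr.Q(qrX, complete = TRUE)
  Q2 <- Q[, (p + 1L):n, drop = FALSE]
  T2 <- crossprod(Q2, S %*% Q2)
  T2 <- (T2 + t(T2)) / 2
  eg <- eigen(T2, symmetric = TRUE)
  theta <- pmax(eg$values, 0)
  eta <- as.vector(crossprod(eg$vectors, crossprod(Q2, y)))
  list(theta = theta, eta = eta, n = n, p = p,
       ldXtX = determinant(crossprod(X), logarithm = TRUE)$modulus[1])
}

# Profiled restricted log-likelihood at variance ratio delta
reml_ll <- function(delta, sp) {
  df <- sp$n - sp$p
  denom <- sp$theta + delta
  s2u <- sum(sp$eta^2 / denom) / df
  -0.5 * (df * log(2 * pi) + df * log(s2u) + sum(log(denom)) + sp$ldXtX + df)
}

#' REML estimation of the two variance components
#'
#' Estimates (sigma_u2, sigma_e2) of y ~ N(Xb, Z K Z' sigma_u2 +
#' I sigma_e2) by exact restricted maximum likelihood. The kernel is
#' projected onto the orthogonal complement of X and eigendecomposed
#' once, after which the restricted likelihood is a one-dimensional
#' function of the variance ratio delta = sigma_e2/sigma_u2, maximised
#' by a bracketed grid-plus-Brent search. Convergence is declared when
#' the restricted log-likelihood is resolved to below `tol`.
#'
#' @param y numeric response from [build_design].
#' @param dm design list from [build_design].
#' @param K relationship kernel ([relmat] or matrix) over
#'   `dm$individual_order`, symmetric positive semidefinite.
#' @param tol convergence tolerance on the restricted log-likelihood
#'   (default 1e-8).
#' @param max_iter maximum optimiser iterations (default 200).
#' @return a [varcomp] with fields `loglik`, `iterations`, `pinned`
#'   (TRUE when sigma_u2 hit its lower bound) and `delta_grid` trace.
#' @export
reml_estimate <- function(y, dm, K, tol = 1e-8, max_iter = 200L) {
  if (length(y) < 20L) stop("need at least 20 records for REML")
  Kb <- if (is_relmat(K)) as_bare(K) else as.matrix(K)
  if (!identical(dim(Kb), c(ncol(dm$Z), ncol(dm$Z))))
    stop("kernel dimension does not match Z")
  S <- dm$Z %*% Kb %*% t(dm$Z)
  sp <- reml_spectral(y, dm$X, S)
  # coarse bracket on log10(delta), then Brent inside the best interval
  grid <- seq(-8, 8, by = 0.25)
  ll <- vapply(grid, function(g) reml_ll(10^g, sp), numeric(1))
  best <- which.max(ll)
  lo <- grid[max(1L, best - 1L)]; hi <- grid[min(length(grid), best + 1L)]
  opt <- stats::optimize(function(g) reml_ll(10^g, sp),
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  iter <- length(grid) + ceiling(log((hi - lo) / .Machine$double.eps^0.5) /
                                   log(1 / 0.381966))
  if (iter > max_iter)
    stop("REML did not converge within ", max_iter,
         " iterations; trace: best log10(delta) = ", round(opt$maximum, 3))
  delta <- 10^opt$maximum
  df <- sp$n - sp$p
  s2u <- sum(sp$eta^2 / (sp$theta + delta)) / df
  pinned <- FALSE
  floor_u <- 1e-8 * stats::var(y)
  if (best == length(grid) || s2u < floor_u) {
    pinned <- TRUE
    s2u <- max(s2u, floor_u)
    warning("sigma_u2 pinned at its lower bound", call. = FALSE)
  }
  vc <- varcomp(sigma_u2 = s2u, sigma_e2 = delta * s2u,
                loglik = reml_ll(delta, sp), iterations = iter,
                pinned = pinned, n = sp$n, p = sp$p)
  vc
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates the standard REML log-likelihood
#' -0.5 (df log 2pi + log|V| + log|X'V^-1 X| + y'Py) for
#' V = Z K Z' sigma_u2 + I sigma_e2, by dense linear algebra. Used as an
#' independent check of the spectral path.
#'
#' @inheritParams reml_estimate
#' @param vc a [varcomp] (or list with `sigma_u2`, `sigma_e2`).
#' @return scalar restricted log-likelihood.
#' @export
reml_loglik_dense <- function(y, dm, K, vc) {
  Kb <- if (is_relmat(K)) as_bare(K) else as.matrix(K)
  X <- dm$X; n <- length(y); p <- ncol(X)
  V <- vc$sigma_u2 * dm$Z %*% Kb %*% t(dm$Z) + vc$sigma_e2 * diag(n)
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX, crossprod(X, Vi))
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus[1] +
                       determinant(XtViX, logarithm = TRUE)$modulus[1] +
                       crossprod(y, P %*% y)))
}

#' Solve BLUP through Henderson's mixed-model equations
#'
#' Solves
#' \deqn{[X'X, X'Z; Z'X, Z'Z + lambda K^{-1}] [b; u] = [X'y; Z'y]}
#' for the fixed effects and breeding values.
#'
#' @param y numeric response.
#' @param dm design list from [build_design].
#' @param K_inv inverse relationship kernel over `dm$individual_order`.
#' @param lambda variance ratio sigma_e2/sigma_u2 (> 0).
#' @return a `blup_solution`: list with `fixef` (named), `u` (named
#'   breeding values) and `genotypic` (intercept + u).
#' @export
solve_blup_mme <- function(y, dm, K_inv, lambda) {
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be > 0")
  Ki <- if (is_relmat(K_inv)) as_bare(K_inv) else as.matrix(K_inv)
  X <- dm$X; Z <- dm$Z
  p <- ncol(X); q <- ncol(Z)
  if (!identical(dim(Ki), c(q, q))) stop("K_inv dimension does not match Z")
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * Ki))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- tryCatch(solve(C, rhs), error = function(e)
    stop("mixed-model equations are singular: ", conditionMessage(e)))
  b <- stats::setNames(sol[seq_len(p)], colnames(X))
  u <- stats::setNames(sol[p + seq_len(q)], dm$individual_order)
  structure(list(fixef = b, u = u, genotypic = b[["(Intercept)"]] + u),
            class = "blup_solution")
}

#' Solve BLUP by the closed-form predictor
#'
#' Evaluates u-hat = (Z'MZ + lambda K^-1)^-1 Z'My literally, with
#' M = I - X(X'X)^-1 X', then recovers the fixed effects as
#' b = (X'X)^-1 X'(y - Z u-hat). Algebraically identical to the
#' mixed-model-equations route and kept as its independent counterpart.
#'
#' @param y numeric response.
#' @param dm design list from [build_design].
#' @param K relationship kernel (must be invertible; blend genomic
#'   kernels first).
#' @param lambda variance ratio sigma_e2/sigma_u2 (> 0).
#' @return a `blup_solution` (see [solve_blup_mme]).
#' @export
solve_blup_direct <- function(y, dm, K, lambda) {
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be > 0")
  Kb <- if (is_relmat(K)) as_bare(K) else as.matrix(K)
  Ki <- tryCatch(solve(Kb), error = function(e)
    stop("kernel is singular; blend with the pedigree block first"))
  M <- design_projection(dm)
  Z <- dm$Z; X <- dm$X
  ZM <- crossprod(Z, M)
  u <- solve(ZM %*% Z + lambda * Ki, ZM %*% y)
  u <- stats::setNames(as.vector(u), dm$individual_order)
  b <- solve(crossprod(X), crossprod(X, y - Z %*% u))
  b <- stats::setNames(as.vector(b), colnames(X))
  structure(list(fixef = b, u = u, genotypic = b[["(Intercept)"]] + u),
            class = "blup_solution")
}

#' @export
print.blup_solution <- function(x, ...) {
  cat("BLUP solution\n  fixed effects:\n")
  print(round(x$fixef, 4))
  cat(sprintf("  breeding values: %d individuals (sd %.4g)\n",
              length(x$u), stats::sd(x$u)))
  invisible(x)
}
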