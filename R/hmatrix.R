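#' Tuning parameters for the single-step H matrix
#'
#' `alpha`/`beta` blend the genomic matrix with the pedigree block to
#' guarantee invertibility (alpha + beta = 1). `tau` scales the genomic
#' information and `omega` the pedigree information in the inverse; with
#' tau = omega the genomic:pedigree mixing proportion is tau:(1 - tau),
#' and tau = omega = 0 collapses the single-step model to the pure
#' pedigree model.
#'
#' @param alpha weight of G in the blended genomic block (default 0.95).
#' @param beta weight of A22 in the blended genomic block (default 0.05).
#' @param tau scaling of the genomic block inverse (default 1).
#' @param omega scaling of the pedigree block inverse (default `tau`).
#' @return an `h_params` list.
#' @export
h_params <- function(alpha = 0.95, beta = 0.05, tau = 1, omega = tau) {
  if (abs(alpha + beta - 1) > 1e-8) stop("alpha + beta must equal 1")
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1)
    stop("alpha and beta must lie in [0, 1]")
  if (tau < 0 || omega < 0) stop("tau and omega must be >= 0")
  structure(list(alpha = alpha, beta = beta, tau = tau, omega = omega),
            class = "h_params")
}

#' @export
print.h_params <- function(x, ...) {
  cat(sprintf("H parameters: alpha=%.3g beta=%.3g tau=%.3g omega=%.3g\n",
              x$alpha, x$beta, x$tau, x$omega))
  invisible(x)
}

#' Combined single-step relationship matrix H
#'
#' Assembles H from A and the (rescaled, optionally blended) genomic
#' matrix of the genotyped block:
#' upper-left  A11 + A12 A22^-1 (G - A22) A22^-1 A21,
#' upper-right A12 A22^-1 G, lower-right G; ordered with the
#' non-genotyped individuals first, then the genotyped ones.
#'
#' @param A a [relmat] of kind `"A"` over all individuals.
#' @param G_star genomic [relmat] whose ids are the genotyped
#'   individuals.
#' @param genotyped_ids optional explicit genotyped set; defaults to the
#'   ids of `G_star`.
#' @return a [relmat] of kind `"H"` ordered (non-genotyped, genotyped).
#' @export
build_H <- function(A, G_star, genotyped_ids = rm_ids(G_star)) {
  if (!setequal(rm_ids(G_star), genotyped_ids))
    stop("G_star ids must equal the genotyped id set")
  part <- partition_A(A, genotyped_ids)
  gids <- rm_ids(part$A22)
  G <- as_bare(G_star)[gids, gids, drop = FALSE]
  A22 <- as_bare(part$A22)
  n1 <- nrow(part$A11); n2 <- length(gids)
  if (n1 == 0L) return(relmat(G, gids, kind = "H"))
  A22i <- tryCatch(solve(A22), error = function(e)
    stop("A22 is singular; cannot assemble H"))
  A12 <- as_bare(part$A12)
  B <- A12 %*% A22i                 # A12 A22^-1
  H11 <- as_bare(part$A11) + B %*% (G - A22) %*% t(B)
  H12 <- B %*% G
  H <- rbind(cbind(H11, H12), cbind(t(H12), G))
  H <- (H + t(H)) / 2
  relmat(H, part$order, kind = "H")
}

#' Inverse of the single-step H matrix
#'
#' H^-1 = A^-1 + [0 0; 0 tau (alpha G + beta A22)^-1 - omega A22^-1],
#' where the non-zero block is embedded on the genotyped individuals.
#' The non-genotyped part of A^-1 is never modified.
#'
#' @param A_inv a [relmat] of kind `"A_inv"` over all individuals.
#' @param G_star genomic [relmat] of the genotyped block (rescaled,
#'   unblended: blending is applied here via `params`).
#' @param A22 pedigree block of the genotyped individuals, same ids and
#'   order as `G_star`.
#' @param params an [h_params] list.
#' @return a [relmat] of kind `"H_inv"` in the order of `A_inv`.
#' @export
build_H_inverse <- function(A_inv, G_star, A22, params = h_params()) {
  if (!inherits(params, "h_params")) stop("params must come from h_params()")
  G_star <- align_ids(G_star, A22, "G_star")
  gids <- rm_ids(G_star)
  ids <- rm_ids(A_inv)
  if (!all(gids %in% ids)) stop("genotyped ids missing from A_inv")
  Hinv <- as_bare(A_inv)
  rownames(Hinv) <- colnames(Hinv) <- ids
  if (params$tau != 0 || params$omega != 0) {
    Gw <- params$alpha * as_bare(G_star) + params$beta * as_bare(A22)
    Gwi <- tryCatch(solve(Gw), error = function(e)
      stop("alpha G + beta A22 is singular; increase beta"))
    block <- params$tau * Gwi
    if (params$omega != 0) {
      A22i <- tryCatch(solve(as_bare(A22)), error = function(e)
        stop("A22 is singular; cannot assemble H inverse"))
      block <- block - params$omega * A22i
    }
    Hinv[gids, gids] <- Hinv[gids, gids] + block
  }
  Hinv <- (Hinv + t(Hinv)) / 2
  relmat(Hinv, ids, kind = "H_inv")
}
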