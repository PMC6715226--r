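#' Read a genotype matrix
#'
#' Reads an individuals-by-loci table of additive genotype codes. Two
#' dialects are accepted: a plain delimited matrix with individual ids in
#' the first column and locus ids in the header, and PLINK `.raw`
#' additive coding (recognised by its `FID IID PAT MAT SEX PHENOTYPE`
#' leading columns, which are dropped except `IID`).
#'
#' @param path delimited text file; separator (comma, tab, whitespace)
#'   is autodetected.
#' @return integer matrix of 0/1/2 reference-allele counts with `NA` for
#'   missing calls; rownames are individual ids, colnames locus ids.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          na.strings = c("NA", "-9", ""))
  plink <- all(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE") %in% names(df))
  if (plink) {
    ids <- as.character(df$IID)
    df <- df[, setdiff(names(df), c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")),
             drop = FALSE]
  } else {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  bad <- !is.na(m) & !(m %in% 0:2)
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or missing")
  genotype_matrix(m)
}

#' Validate a genotype matrix
#'
#' @param m numeric/integer matrix, individuals x loci, entries 0/1/2/NA,
#'   with rownames (individual ids) and colnames (locus ids).
#' @return the validated integer matrix.
#' @export
genotype_matrix <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("genotype matrix needs individual rownames and locus colnames")
  if (anyDuplicated(rownames(m))) stop("duplicate individual ids in genotypes")
  if (anyDuplicated(colnames(m))) stop("duplicate locus ids in genotypes")
  if (any(!is.na(m) & !(m %in% 0:2)))
    stop("genotype entries must be in {0, 1, 2} or NA")
  storage.mode(m) <- "integer"
  m
}

# P(offspring = 0,1,2 | parental transmission probabilities ps, pd of the
# reference allele). A genotyped parent with call g transmits with ps = g/2;
# an ungenotyped parent is represented by the locus allele frequency.
mendel_probs <- function(ps, pd) {
  c(`0` = (1 - ps) * (1 - pd),
    `1` = ps * (1 - pd) + (1 - ps) * pd,
    `2` = ps * pd)
}

#' SNP quality control
#'
#' Filters and completes a genotype matrix in five ordered stages:
#' \enumerate{
#'   \item remove loci with call rate below `call_rate_min`;
#'   \item remove loci with minor allele frequency below `maf_min`
#'     (strict inequality: a locus at exactly the threshold is kept);
#'   \item Mendelian-consistency check: where both parents are genotyped
#'     and an offspring call is impossible under Mendelian transmission
#'     (zero probability given the parental calls), that offspring call
#'     is set to missing;
#'   \item imputation of missing calls: when both parents have calls at
#'     the locus, the most probable genotype under Mendelian transmission
#'     (ties broken toward the heterozygote); otherwise the locus mean
#'     rounded to the nearest valid count;
#'   \item greedy pruning of highly correlated loci: scanning in locus
#'     order, a locus is dropped when its squared correlation with an
#'     already-retained locus exceeds `r2_max`.
#' }
#' The imputation and pruning rules are internal substitutes for external
#' phasing-based imputation and published pruning recipes, not
#' reproductions of them.
#'
#' @param g genotype matrix (individuals x loci, 0/1/2/NA).
#' @param ped a sorted `pedigree` covering every genotyped individual.
#' @param call_rate_min minimum per-locus call rate (default 0.80).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param r2_max maximum squared correlation between retained loci
#'   (default 0.99).
#' @return list with `genotypes` (complete, filtered integer matrix) and
#'   `report` (a `qc_report`: per-stage removal counts, per-locus call
#'   rate and MAF of the input, and the count of Mendelian-inconsistent
#'   calls blanked).
#' @export
qc_genotypes <- function(g, ped, call_rate_min = 0.80, maf_min = 0.01,
                         r2_max = 0.99) {
  g <- genotype_matrix(g)
  check_sorted(ped)
  absent <- setdiff(rownames(g), ped$id)
  if (length(absent))
    stop("genotyped individual(s) missing from pedigree: ",
         paste(absent, collapse = ", "))
  n_in <- ncol(g)
  call_rate <- colMeans(!is.na(g))
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)

  keep <- call_rate >= call_rate_min
  n_callrate <- sum(!keep)
  g <- g[, keep, drop = FALSE]

  maf_k <- maf[keep]
  keep2 <- maf_k >= maf_min
  n_maf <- sum(!keep2)
  g <- g[, keep2, drop = FALSE]
  if (ncol(g) == 0L) stop("all loci removed during quality control")

  # Mendelian consistency + imputation, iterated to a fixed point: blanking
  # an inconsistent call can expose a new inconsistency one generation down
  # (when the re-imputed parental call conflicts with an observed offspring
  # call), so the blank-then-impute pair repeats until no impossible trio
  # call remains. Imputation runs in pedigree order so parental calls are
  # final before any offspring call is filled; a call imputed as the
  # Mendelian most-probable genotype is consistent with its trio.
  pos <- stats::setNames(seq_len(nrow(ped)), ped$id)
  ord <- ped$id[ped$id %in% rownames(g)]
  locus_mean <- colMeans(g, na.rm = TRUE)
  freq <- locus_mean / 2
  n_mendel <- 0L; n_imputed <- 0L
  for (pass in seq_len(nrow(ped))) {
    blanked <- 0L
    for (i in ord) {
      s <- ped$sire[pos[i]]; d <- ped$dam[pos[i]]
      if (is.na(s) || is.na(d)) next
      if (!(s %in% rownames(g)) || !(d %in% rownames(g))) next
      gs <- g[s, ]; gd <- g[d, ]; go <- g[i, ]
      ok <- !is.na(gs) & !is.na(gd) & !is.na(go)
      if (!any(ok)) next
      pr <- rbind((1 - gs / 2) * (1 - gd / 2),
                  (gs / 2) * (1 - gd / 2) + (1 - gs / 2) * (gd / 2),
                  (gs / 2) * (gd / 2))
      impossible <- ok & pr[cbind(go + 1L, seq_along(go))] == 0
      if (any(impossible)) {
        g[i, impossible] <- NA_integer_
        blanked <- blanked + sum(impossible)
      }
    }
    if (pass == 1L) n_mendel <- blanked
    if (pass > 1L && blanked == 0L) break
    miss_now <- sum(is.na(g))
    if (pass == 1L) n_imputed <- miss_now
    if (miss_now == 0L) { if (pass == 1L) break else next }
    for (i in ord) {
      miss <- which(is.na(g[i, ]))
      if (!length(miss)) next
      s <- ped$sire[pos[i]]; d <- ped$dam[pos[i]]
      s_ok <- !is.na(s) && s %in% rownames(g)
      d_ok <- !is.na(d) && d %in% rownames(g)
      for (j in miss) {
        if (s_ok || d_ok) {
          ps <- if (s_ok) g[s, j] / 2 else freq[j]
          pd <- if (d_ok) g[d, j] / 2 else freq[j]
          pr <- mendel_probs(ps, pd)
          best <- which(pr == max(pr)) - 1L
          g[i, j] <- if (1L %in% best) 1L else best[1L]
        } else {
          g[i, j] <- as.integer(min(2L, max(0L, round(locus_mean[j]))))
        }
      }
    }
  }

  # Correlation pruning (greedy, locus order)
  n_prune <- 0L
  if (ncol(g) > 1L) {
    sds <- apply(g, 2L, stats::sd)
    cg <- g[, sds > 0, drop = FALSE]
    n_mono <- ncol(g) - ncol(cg)   # post-imputation monomorphic: prune too
    r2 <- if (ncol(cg) > 1L) stats::cor(cg)^2 else matrix(1, 1, 1)
    retained <- logical(ncol(cg))
    for (j in seq_len(ncol(cg))) {
      retained[j] <- !any(retained & r2[j, seq_len(ncol(cg))] > r2_max &
                            seq_len(ncol(cg)) != j)
    }
    keep_ids <- colnames(cg)[retained]
    n_prune <- ncol(g) - length(keep_ids)
    g <- g[, keep_ids, drop = FALSE]
  }
  if (ncol(g) == 0L) stop("all loci removed during quality control")

  report <- structure(list(
    n_loci_in = n_in, n_loci_out = ncol(g),
    removed = c(call_rate = n_callrate, maf = n_maf, correlated = n_prune),
    n_mendelian_blanked = n_mendel, n_imputed = n_imputed,
    call_rate = call_rate, maf = maf,
    thresholds = c(call_rate_min = call_rate_min, maf_min = maf_min,
                   r2_max = r2_max)
  ), class = "qc_report")
  stopifnot(report$n_loci_in - sum(report$removed) == report$n_loci_out)
  list(genotypes = g, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP quality control\n")
  cat(sprintf("  loci in: %d, out: %d\n", x$n_loci_in, x$n_loci_out))
  cat(sprintf("  removed: call rate %d, MAF %d, correlated %d\n",
              x$removed[["call_rate"]], x$removed[["maf"]],
              x$removed[["correlated"]]))
  cat(sprintf("  Mendelian-inconsistent calls blanked: %d; calls imputed: %d\n",
              x$n_mendelian_blanked, x$n_imputed))
  invisible(x)
}

#' VanRaden method-1 genomic relationship matrix
#'
#' G = ZZ' / (2 * sum_j p_j (1 - p_j)) where Z is the genotype matrix
#' column-centred at twice the reference-allele frequency p_j observed in
#' the genotyped set.
#'
#' @param g complete genotype matrix (no missing values), >= 2
#'   individuals and at least one polymorphic locus.
#' @param p optional vector of reference-allele frequencies to use
#'   instead of the observed ones (e.g. founder frequencies in
#'   simulation checks).
#' @return a [relmat] of kind `"G_raw"`.
#' @export
build_G <- function(g, p = NULL) {
  g <- genotype_matrix(g)
  if (anyNA(g)) stop("genotypes must be complete (run qc_genotypes first)")
  if (nrow(g) < 2L) stop("need at least 2 genotyped individuals")
  if (is.null(p)) p <- colMeans(g) / 2
  if (length(p) != ncol(g)) stop("p must have one frequency per locus")
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all loci monomorphic: VanRaden denominator is zero")
  Z <- sweep(g, 2L, 2 * p)
  G <- tcrossprod(Z) / denom
  relmat(G, rownames(g), kind = "G_raw")
}

#' Rescale G to match the pedigree relationships of the genotyped set
#'
#' Applies the affine rescaling G* = a + b G with (a, b) chosen so that
#' the mean diagonal and the mean off-diagonal of G* equal those of A22.
#' This compatibility adjustment places G on the same base-population
#' scale as A and avoids bias in the single-step evaluation.
#'
#' @param G a [relmat] of kind `"G_raw"` (or any symmetric G).
#' @param A22 the genotyped block of A, same ids in the same order.
#' @return a [relmat] of kind `"G_scaled"` with attributes `a` and `b`.
#' @export
scale_G_to_A22 <- function(G, A22) {
  G <- align_ids(G, A22, "G")
  n <- nrow(G)
  if (n < 2L) stop("need at least 2 genotyped individuals to rescale")
  dG <- mean(diag(G)); oG <- mean(as_bare(G)[upper.tri(G)])
  dA <- mean(diag(A22)); oA <- mean(as_bare(A22)[upper.tri(A22)])
  if (abs(dG - oG) < 1e-12)
    stop("mean diagonal equals mean off-diagonal of G; rescaling system is singular")
  b <- (dA - oA) / (dG - oG)
  a <- dA - b * dG
  out <- relmat(a + b * as_bare(G), rm_ids(G), kind = "G_scaled")
  attr(out, "a") <- a
  attr(out, "b") <- b
  out
}

#' Blend a genomic matrix with its pedigree counterpart
#'
#' Returns alpha * G + beta * A22. The small pedigree admixture
#' (defaults alpha = 0.95, beta = 0.05) guarantees invertibility of the
#' genomic block.
#'
#' @param G a [relmat] (usually kind `"G_scaled"`).
#' @param A22 genotyped block of A, same ids and order.
#' @param alpha,beta blending weights; must sum to 1.
#' @return blended [relmat] of kind `"G_scaled"`.
#' @export
blend_G <- function(G, A22, alpha = 0.95, beta = 0.05) {
  if (abs(alpha + beta - 1) > 1e-8) stop("alpha + beta must equal 1")
  G <- align_ids(G, A22, "G")
  relmat(alpha * as_bare(G) + beta * as_bare(A22), rm_ids(G), kind = "G_scaled")
}

# Reorder x's rows/columns to match the reference's ids; errors when the
# two id sets differ.
align_ids <- function(x, ref, what = "matrix") {
  if (identical(rm_ids(x), rm_ids(ref))) return(x)
  if (!setequal(rm_ids(x), rm_ids(ref)))
    stop(what, " and ", rm_kind(ref), " must cover the same individuals")
  ids <- rm_ids(ref)
  relmat(as_bare(x)[ids, ids, drop = FALSE], ids, kind = rm_kind(x))
}
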