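#' Read and validate a pedigree file
#'
#' Reads a delimited pedigree table (columns `individual`, `sire`, `dam`;
#' comma- or tab-separated, autodetected), validates it, and returns a
#' topologically sorted pedigree in which every known parent precedes its
#' offspring. Individuals that appear only as parents are auto-registered
#' as founders: in cross-breeding populations the parental cultivars are
#' part of the evaluated set even when they have no pedigree row of their
#' own.
#'
#' @param path path to the pedigree file. A header row is required.
#' @param unknown_code string marking an unknown parent (default `"0"`).
#' @return a `pedigree`: data frame with character columns `id`, `sire`,
#'   `dam` (`NA` for unknown parents), topologically sorted.
#' @export
read_pedigree <- function(path, unknown_code = "0") {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("pedigree file is empty: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", strip.white = TRUE)
  if (nrow(df) == 0L) stop("pedigree file has no records: ", path)
  if (ncol(df) < 3L) stop("pedigree file needs columns individual, sire, dam")
  pedigree(df[[1L]], df[[2L]], df[[3L]], unknown_code = unknown_code)
}

#' Construct a validated pedigree
#'
#' @param id,sire,dam character vectors of equal length; `sire`/`dam`
#'   entries equal to `unknown_code` (or `NA`) denote unknown parents.
#' @param unknown_code string marking an unknown parent.
#' @return a topologically sorted `pedigree` data frame. Unknown parents
#'   are `NA`; parents never listed as individuals are prepended as
#'   founder rows.
#' @export
pedigree <- function(id, sire, dam, unknown_code = "0") {
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  if (length(id) == 0L) stop("empty pedigree")
  if (any(!nzchar(id)) || anyNA(id)) stop("individual ids must be non-empty")
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate individual id(s): ", paste(unique(dup), collapse = ", "))
  if (!is.na(unknown_code)) {
    sire[!is.na(sire) & sire == unknown_code] <- NA_character_
    dam[!is.na(dam) & dam == unknown_code] <- NA_character_
  }
  self <- which(id == sire | id == dam)
  if (length(self)) stop("individual(s) listed as own parent: ",
                         paste(id[self], collapse = ", "))
  parents <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(parents)) {
    id <- c(parents, id)
    sire <- c(rep(NA_character_, length(parents)), sire)
    dam <- c(rep(NA_character_, length(parents)), dam)
  }
  ord <- ped_toposort(id, sire, dam)
  ped <- data.frame(id = id[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Stable topological sort of the parent -> offspring DAG: repeated passes
# place every individual whose parents are already placed, preserving the
# input order among individuals of the same pedigree depth. Detects cycles.
ped_toposort <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n); names(idx) <- id
  si <- idx[sire]; di <- idx[dam]       # NA for unknown
  ord <- integer(n); k <- 0L
  placed <- logical(n)
  repeat {
    progress <- FALSE
    for (i in seq_len(n)) {
      if (placed[i]) next
      if ((is.na(si[i]) || placed[si[i]]) && (is.na(di[i]) || placed[di[i]])) {
        k <- k + 1L; ord[k] <- i; placed[i] <- TRUE; progress <- TRUE
      }
    }
    if (k == n) break
    if (!progress)
      stop("pedigree contains a cycle (an individual is its own ancestor): ",
           paste(id[!placed], collapse = ", "))
  }
  ord
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d individuals (%d founders)\n",
              nrow(x), sum(is.na(x$sire) & is.na(x$dam))))
  NextMethod()
}

is_sorted_pedigree <- function(ped) {
  if (!inherits(ped, "pedigree")) return(FALSE)
  pos <- seq_len(nrow(ped)); names(pos) <- ped$id
  ps <- pos[ped$sire]; pd <- pos[ped$dam]
  all(is.na(ps) | ps < pos) && all(is.na(pd) | pd < pos)
}

check_sorted <- function(ped) {
  if (!is_sorted_pedigree(ped))
    stop("pedigree must be a sorted 'pedigree' object (see pedigree())")
  invisible(ped)
}

#' Numerator relationship matrix A
#'
#' Builds the pedigree-based additive (numerator) relationship matrix by
#' the recursive tabular method, accounting for inbreeding: the diagonal
#' is 1 + F_i with F_i = 0.5 * a(sire_i, dam_i), and unknown parents are
#' treated as unrelated, non-inbred founders of a single base population.
#'
#' @param ped a sorted `pedigree`.
#' @return a [relmat] of kind `"A"` in pedigree order.
#' @export
build_A <- function(ped) {
  check_sorted(ped)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- idx[ped$sire]; di <- idx[ped$dam]
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + A[s, j]
      if (!is.na(d)) row <- row + A[d, j]
      row <- 0.5 * row
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  relmat(A, ped$id, kind = "A")
}

#' Inbreeding coefficients from a pedigree
#'
#' @param ped a sorted `pedigree`.
#' @return named numeric vector F_i = a(i,i) - 1.
#' @export
inbreeding <- function(ped) {
  A <- build_A(ped)
  stats::setNames(diag(A) - 1, ped$id)
}

#' Inverse of the numerator relationship matrix
#'
#' Builds A^-1 directly by Henderson's rules extended by Quaas for
#' inbreeding: each individual contributes 1/d_i to the inverse on the
#' (individual, parent) pattern, where d_i is the Mendelian sampling
#' variance 0.5 - 0.25 (F_s + F_d) (with the corresponding reduction when
#' parents are unknown). Inbreeding coefficients are taken from the
#' tabular A so the result is the exact inverse of [build_A].
#'
#' @param ped a sorted `pedigree`.
#' @return a [relmat] of kind `"A_inv"` in pedigree order.
#' @export
build_A_inverse <- function(ped) {
  check_sorted(ped)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- idx[ped$sire]; di <- idx[ped$dam]
  Fi <- inbreeding(ped)
  Ainv <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    Fs <- if (is.na(s)) -1 else Fi[s]   # unknown parent: contributes as F = -1
    Fd <- if (is.na(d)) -1 else Fi[d]   # so that d_i = 0.75 or 1 as appropriate
    dii <- 0.5 - 0.25 * (Fs + Fd)
    b <- 1 / dii
    Ainv[i, i] <- Ainv[i, i] + b
    for (p in c(s, d)) {
      if (is.na(p)) next
      Ainv[i, p] <- Ainv[i, p] - b / 2
      Ainv[p, i] <- Ainv[p, i] - b / 2
    }
    if (!is.na(s)) Ainv[s, s] <- Ainv[s, s] + b / 4
    if (!is.na(d)) Ainv[d, d] <- Ainv[d, d] + b / 4
    if (!is.na(s) && !is.na(d)) {
      Ainv[s, d] <- Ainv[s, d] + b / 4
      Ainv[d, s] <- Ainv[d, s] + b / 4
    }
  }
  relmat(Ainv, ped$id, kind = "A_inv")
}

#' Partition A into genotyped and non-genotyped blocks
#'
#' Reorders A with the non-genotyped individuals first (block 1) and the
#' genotyped individuals second (block 2) and extracts the three distinct
#' blocks; the lower-left block is the transpose of `A12` and is not
#' stored.
#'
#' @param A a [relmat] of kind `"A"`.
#' @param genotyped_ids character vector of genotyped individual labels.
#' @return list with [relmat] entries `A11` (non-genotyped), `A12`
#'   (non-genotyped x genotyped), `A22` (genotyped), plus `order`, the id
#'   vector c(non-genotyped, genotyped).
#' @export
partition_A <- function(A, genotyped_ids) {
  ids <- rm_ids(A)
  genotyped_ids <- as.character(genotyped_ids)
  missing <- setdiff(genotyped_ids, ids)
  if (length(missing))
    stop("genotyped id(s) absent from pedigree: ", paste(missing, collapse = ", "))
  g <- ids[ids %in% genotyped_ids]       # keep A's ordering within each block
  ng <- setdiff(ids, g)
  Ab <- as_bare(A)
  rownames(Ab) <- colnames(Ab) <- ids
  list(
    A11 = relmat(Ab[ng, ng, drop = FALSE], ng, kind = "A11"),
    A12 = structure(Ab[ng, g, drop = FALSE], kind = "A12",
                    class = c("relmat", "matrix")),
    A22 = relmat(Ab[g, g, drop = FALSE], g, kind = "A22"),
    order = c(ng, g)
  )
}
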