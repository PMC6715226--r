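#' Labeled relationship matrix
#'
#' Light wrapper around a dense symmetric matrix carrying the individual
#' labels on both dimensions and a `kind` tag recording what the matrix is
#' (pedigree A, its inverse, a partition block, genomic G before or after
#' rescaling, combined H, or an H inverse).
#'
#' @param values square numeric matrix.
#' @param ids character vector of individual labels, one per row/column.
#'   Defaults to the rownames of `values`.
#' @param kind one of `"A"`, `"A_inv"`, `"A11"`, `"A12"`, `"A22"`,
#'   `"G_raw"`, `"G_scaled"`, `"H"`, `"H_inv"`.
#' @return a `relmat`: the matrix with `dimnames` set to `ids` and a
#'   `kind` attribute.
#' @export
relmat <- function(values, ids = rownames(values), kind) {
  kinds <- c("A", "A_inv", "A11", "A12", "A22", "G_raw", "G_scaled", "H", "H_inv")
  kind <- match.arg(kind, kinds)
  values <- as.matrix(values)
  if (is.null(ids)) stop("relationship matrix needs individual ids")
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("relationship matrix ids must be unique")
  # A12 blocks are rectangular; everything else must be square symmetric
  if (kind != "A12") {
    if (nrow(values) != ncol(values))
      stop("relationship matrix of kind '", kind, "' must be square")
    if (length(ids) != nrow(values))
      stop("ids length does not match matrix dimension")
    if (nrow(values) > 0 && max(abs(values - t(values))) > 1e-10)
      stop("relationship matrix of kind '", kind, "' is not symmetric")
    dimnames(values) <- list(ids, ids)
  }
  attr(values, "kind") <- kind
  class(values) <- c("relmat", class(values))
  values
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("<relmat kind=%s, %d x %d>\n", attr(x, "kind"), nrow(x), ncol(x)))
  y <- x
  attr(y, "kind") <- NULL
  class(y) <- "matrix"
  if (nrow(y) <= 10L) print(round(y, 4)) else {
    print(round(y[1:6, 1:min(6, ncol(y)), drop = FALSE], 4))
    cat("...\n")
  }
  invisible(x)
}

#' @rdname relmat
#' @param x object to test or strip.
#' @export
is_relmat <- function(x) inherits(x, "relmat")

rm_kind <- function(x) attr(x, "kind")

rm_ids <- function(x) rownames(x)

#' Drop relmat attributes, returning the bare matrix
#' @keywords internal
#' @noRd
as_bare <- function(x) {
  attr(x, "kind") <- NULL
  class(x) <- "matrix"
  unclass(x)
}
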