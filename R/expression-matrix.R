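#' Construct an expression matrix
#'
#' Thin S3 wrapper around a numeric gene-by-sample matrix carrying its
#' transform state, so that the log2(TPM+1) preprocessing cannot be applied
#' twice by accident.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (colnames).
#' @param transform Either `"raw_tpm"` (non-negative TPM) or `"log2p1"`
#'   (already log2(TPM+1)-transformed).
#' @return An `expr_matrix` object.
#' @export
#' @examples
#' m <- matrix(c(0, 1, 3, 1023), 2, 2,
#'             dimnames = list(c("gA", "gB"), c("s1", "s2")))
#' em <- expression_matrix(m)
#' preprocess_tpm(em)
expression_matrix <- function(values, transform = c("raw_tpm", "log2p1")) {
  transform <- match.arg(transform)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers")
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (transform == "raw_tpm" && any(values < 0))
    stop("raw TPM values must be non-negative")
  structure(list(values = values, transform = transform),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples [", x$transform, "]\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' log2(TPM + 1) preprocessing
#'
#' Replaces every value v by log2(v + 1), the standard variance-stabilizing
#' transform applied before ssGSEA scoring. Refuses matrices that are
#' already transformed.
#'
#' @param matrix An [expression_matrix()] in `raw_tpm` state.
#' @return The transformed `expr_matrix` (state `log2p1`).
#' @export
preprocess_tpm <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$transform != "raw_tpm")
    stop("matrix is already log2(TPM+1)-transformed")
  expression_matrix(log2(matrix$values + 1), transform = "log2p1")
}
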