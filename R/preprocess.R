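#' Construct a normalized-matrix container
#'
#' Wraps a gene-by-sample matrix of log2 expression values together with
#' the bookkeeping the state-space and mutual-information stages need
#' (centering flag, size factors, pseudocount).  Used internally by
#' [normalize_log()]; exposed so externally normalized values can enter
#' the pipeline.
#'
#' @param values Numeric gene-by-sample matrix with dimnames.
#' @param centered Logical: have gene rows been mean-centered?
#' @param size_factors Per-sample positive reals (or NULL if unknown).
#' @param pseudocount Pseudocount used on the CPM scale.
#' @param size_factor_method Free-text provenance tag.
#' @return An object of class `normalized_matrix`.
#' @export
normalized_matrix <- function(values, centered = FALSE, size_factors = NULL,
                              pseudocount = 1,
                              size_factor_method = "external") {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("values must be a numeric matrix")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("gene_%0*d", nchar(nrow(values)), seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("sample_%d", seq_len(ncol(values)))
  if (!is.null(size_factors)) {
    if (length(size_factors) != ncol(values) || any(size_factors <= 0))
      stopf("size_factors must be one strictly positive value per sample")
  }
  structure(list(values = values, centered = isTRUE(centered),
                 size_factors = size_factors, pseudocount = pseudocount,
                 size_factor_method = size_factor_method),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d samples (log2 CPM + %g)%s\n",
              nrow(x$values), ncol(x$values), x$pseudocount,
              if (x$centered) ", mean-centered" else ""))
  invisible(x)
}

#' Log-normalize a count matrix to log2 CPM
#'
#' Computes `log2(count / size_factor * 1e6 + pseudocount)` per cell.  By
#' default the size factor of a sample is its library size (column sum),
#' i.e. the values are log2(CPM + pseudocount); externally computed
#' effective library sizes (e.g. TMM-scaled) can be supplied instead.
#'
#' @param counts Nonnegative gene-by-sample count matrix, or a
#'   `sim_dataset` (its counts are used).
#' @param pseudocount Positive pseudocount added on the CPM scale
#'   (default 1, so zero counts map to 0).
#' @param size_factors Optional per-sample positive values overriding the
#'   column sums.
#' @return A [normalized_matrix()] (not yet centered).
#' @examples
#' m <- matrix(c(1, 3, 0, 4), 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' normalize_log(m)$values
#' @export
normalize_log <- function(counts, pseudocount = 1, size_factors = NULL) {
  if (inherits(counts, "sim_dataset")) counts <- counts$counts
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("counts must be a numeric matrix")
  if (any(!is.finite(counts)) || any(counts < 0))
    stopf("counts must be finite and nonnegative")
  if (!is_number(pseudocount) || pseudocount <= 0)
    stopf("pseudocount must be strictly positive")
  method <- "library_size"
  if (is.null(size_factors)) {
    size_factors <- colSums(counts)
  } else {
    if (length(size_factors) != ncol(counts))
      stopf("size_factors must have one value per sample")
    method <- "user_supplied"
  }
  bad <- which(size_factors <= 0)
  if (length(bad))
    stopf("sample(s) with non-positive size factor / zero total count: %s",
          paste(colnames(counts)[bad], collapse = ", "))
  cpm <- sweep(counts, 2, size_factors / 1e6, `/`)
  nm <- normalized_matrix(log2(cpm + pseudocount), centered = FALSE,
                          size_factors = size_factors,
                          pseudocount = pseudocount,
                          size_factor_method = method)
  nm
}

#' Mean-center gene rows
#'
#' Subtracts each gene's across-sample mean, producing the mean-centered
#' log-normalized values the state-space and mutual-information stages
#' operate on.  Centering an already-centered matrix is a numerical no-op
#' (idempotent).
#'
#' @param x A [normalized_matrix()] or a plain numeric matrix.
#' @return Same type as the input, with zero row means and (for
#'   `normalized_matrix`) the `centered` flag set.
#' @export
mean_center <- function(x) {
  if (inherits(x, "normalized_matrix")) {
    x$values <- x$values - rowMeans(x$values)
    x$centered <- TRUE
    return(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) stopf("x must be a numeric matrix")
  x - rowMeans(x)
}
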