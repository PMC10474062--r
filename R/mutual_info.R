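#' Fit a max-entropy (equal-frequency) binning scheme
#'
#' For continuous data the discretization that maximizes the entropy of
#' the binned variable is equal-frequency binning, so the bin boundaries
#' are placed at the empirical 1/3 and 2/3 quantiles (order statistics,
#' `type = 1`) of the pooled values of all genes.  Assignment convention:
#' `x <= b1` is bin 1, `b1 < x <= b2` bin 2, `x > b2` bin 3.
#'
#' @param values Numeric vector of pooled expression values (all genes x
#'   selected samples).
#' @param k Number of bins (default 3).
#' @return An object of class `binning_scheme`: `k`, `boundaries`
#'   (k-1 increasing values), `source` description, `n_pooled`.
#' @examples
#' fit_max_entropy_bins(1:9)$boundaries  # c(3, 6)
#' @export
fit_max_entropy_bins <- function(values, k = 3L) {
  if (!is.numeric(values) || any(!is.finite(values)))
    stopf("values must be finite numbers")
  if (!is_count_scalar(k) || k < 2) stopf("k must be an integer >= 2")
  if (length(unique(values)) < k)
    stopf("need at least %d distinct values to fit %d bins", k, k)
  b <- unname(stats::quantile(values, probs = seq_len(k - 1) / k, type = 1))
  if (anyDuplicated(b))
    stopf("bin boundaries collapse at tied value %g; data too discrete for %d bins",
          b[which(duplicated(b))[1]], k)
  structure(list(k = as.integer(k), boundaries = b,
                 source = sprintf("equal-frequency quantiles of %d pooled values",
                                  length(values)),
                 n_pooled = length(values)),
            class = "binning_scheme")
}

#' Discretize values under a binning scheme
#'
#' @param x Numeric vector or matrix.
#' @param scheme A [fit_max_entropy_bins()] scheme.
#' @return Integer bins in `1..k`, same shape as `x`.
#' @export
assign_bins <- function(x, scheme) {
  if (!inherits(scheme, "binning_scheme")) stopf("scheme must be a binning_scheme")
  b <- findInterval(x, scheme$boundaries, left.open = TRUE) + 1L
  if (is.matrix(x)) dim(b) <- dim(x)
  b
}

#' Plug-in mutual information of a contingency table, in bits
#'
#' Computes `I(X:Y) = H(X) + H(Y) - H(X,Y)` from the empirical cell
#' frequencies of a contingency table, with the `0 log 0 = 0` convention
#' and no small-sample bias correction.  Tiny negative values arising from
#' floating-point cancellation are clamped to 0.
#'
#' @param tab Nonnegative matrix of counts (bins x classes).
#' @return Mutual information in bits.
#' @examples
#' mi_from_table(rbind(c(5, 0), c(0, 5)))  # 1 bit
#' @export
mi_from_table <- function(tab) {
  if (!is.matrix(tab) || any(tab < 0) || !all(is.finite(tab)))
    stopf("tab must be a finite nonnegative matrix")
  if (sum(tab) == 0) stopf("empty contingency table")
  mi <- shannon_entropy(rowSums(tab)) + shannon_entropy(colSums(tab)) -
    shannon_entropy(as.vector(tab))
  if (mi < 0) {
    if (mi < -1e-9) stopf("mutual information numerically negative (%g)", mi)
    mi <- 0
  }
  mi
}

#' Which samples and labels does a contrast use?
#'
#' `condition4` uses all samples with the four-level condition label;
#' `CP_vs_BC` the leukemic samples labelled CP/BC; `wt_vs_KO` the
#' non-leukemic samples labelled wt/KO.
#'
#' @param annotation Sample annotation data.frame.
#' @param contrast One of `"condition4"`, `"CP_vs_BC"`, `"wt_vs_KO"`.
#' @return List with `sample_id` and droplevelled factor `labels`.
#' @export
contrast_samples <- function(annotation,
                             contrast = c("condition4", "CP_vs_BC", "wt_vs_KO")) {
  contrast <- match.arg(contrast)
  keep <- switch(contrast,
    condition4 = rep(TRUE, nrow(annotation)),
    CP_vs_BC = annotation$condition %in% c("CP", "BC"),
    wt_vs_KO = annotation$condition %in% c("wt", "KO"))
  labels <- droplevels(factor(annotation$condition[keep]))
  required <- switch(contrast, condition4 = condition_levels,
                     CP_vs_BC = c("CP", "BC"), wt_vs_KO = c("wt", "KO"))
  absent <- setdiff(required, levels(labels))
  if (length(absent))
    stopf("contrast %s: condition level(s) absent from annotation: %s",
          contrast, paste(absent, collapse = ", "))
  list(sample_id = annotation$sample_id[keep], labels = labels)
}

#' Per-gene mutual information against condition labels
#'
#' For every gene, expression over the contrast's samples is discretized
#' with a global three-bin max-entropy scheme (fitted on the pooled
#' mean-centered log-normalized values of all genes over those samples,
#' unless a scheme is supplied) and the plug-in mutual information with
#' the condition label is computed in bits.
#'
#' @param matrix A centered [normalized_matrix()].
#' @param annotation Sample annotation data.frame.
#' @param contrast See [contrast_samples()].
#' @param binning Optional [fit_max_entropy_bins()] scheme to reuse
#'   (e.g. the four-condition scheme); refitted on this contrast's pooled
#'   values when NULL.
#' @return An object of class `mi_profile`: `contrast`, `samples_used`,
#'   `labels`, per-gene `mi` (named, bits), `binning`, `log_base = 2`.
#' @export
compute_mi_profile <- function(matrix, annotation,
                               contrast = c("condition4", "CP_vs_BC", "wt_vs_KO"),
                               binning = NULL) {
  if (!inherits(matrix, "normalized_matrix"))
    stopf("matrix must be a normalized_matrix")
  if (!matrix$centered)
    stopf("mutual information uses mean-centered values; call mean_center() first")
  contrast <- match.arg(contrast)
  sel <- contrast_samples(annotation, contrast)
  missing <- setdiff(sel$sample_id, colnames(matrix$values))
  if (length(missing))
    stopf("matrix lacks sample(s): %s", paste(utils::head(missing, 3), collapse = ", "))
  vals <- matrix$values[, sel$sample_id, drop = FALSE]
  if (is.null(binning)) {
    binning <- fit_max_entropy_bins(as.vector(vals), k = 3L)
    binning$source <- sprintf("%s; contrast %s (%d genes x %d samples)",
                              binning$source, contrast, nrow(vals), ncol(vals))
  } else if (!inherits(binning, "binning_scheme")) {
    stopf("binning must be a binning_scheme")
  }
  if (any(!is.finite(binning$boundaries))) stopf("non-finite bin boundaries")

  bins <- assign_bins(vals, binning)
  y <- as.integer(sel$labels)
  L <- nlevels(sel$labels)
  k <- binning$k
  cell <- bins + k * rep(y - 1L, each = nrow(bins))  # gene x sample cell index
  mi <- apply(cell, 1, function(z)
    mi_from_table(matrix(tabulate(z, nbins = k * L), nrow = k)))
  names(mi) <- rownames(vals)

  structure(list(contrast = contrast, samples_used = sel$sample_id,
                 labels = sel$labels, mi = mi, binning = binning,
                 log_base = 2),
            class = "mi_profile")
}

#' @export
print.mi_profile <- function(x, ...) {
  cat(sprintf("mi_profile (%s): %d genes, %d samples, %d-level label; median MI %.3f bits\n",
              x$contrast, length(x$mi), length(x$samples_used),
              nlevels(x$labels), stats::median(x$mi)))
  invisible(x)
}

# Exact one-sided P(rank sum of x >= observed) under the permutation null,
# via a subset-sum dynamic program over doubled mid-ranks (exact under ties,
# where the classical Wilcoxon distribution does not apply).
exact_rank_sum_p <- function(r2, n1) {
  n <- length(r2)
  w_obs <- sum(r2[seq_len(n1)])
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  f <- matrix(0, n1 + 1L, smax + 1L)
  f[1L, 1L] <- 1
  seen <- 0L
  for (v in r2) {
    jmax <- min(seen, n1 - 1L)
    for (j in jmax:0L) {
      row <- f[j + 1L, seq_len(smax + 1L - v)]
      f[j + 2L, (v + 1L):(smax + 1L)] <- f[j + 2L, (v + 1L):(smax + 1L)] + row
    }
    seen <- seen + 1L
  }
  sum(f[n1 + 1L, (w_obs + 1L):(smax + 1L)]) / choose(n, n1)
}

#' One-sided rank-sum test that `x` is stochastically greater than `y`
#'
#' Mid-ranks are used for ties.  For small problems
#' (`length(x) * length(y) <= exact_threshold`) the p-value is computed by
#' exact enumeration of the permutation distribution of the rank sum
#' (valid under ties); larger problems use the normal approximation with
#' tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric vectors.
#' @param exact_threshold Switchover on `length(x) * length(y)`
#'   (default 200).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   NULL applies the threshold rule.
#' @return List: `statistic` (rank sum of `x`), `p`, `method`.
#' @export
rank_sum_greater <- function(x, y, exact_threshold = 200L, exact = NULL) {
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  n1 <- length(x)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (is.null(exact)) exact <- n1 * length(y) <= exact_threshold
  if (exact) {
    r2 <- as.integer(round(2 * r))
    p <- exact_rank_sum_p(r2, n1)
    method <- "exact_enumeration"
  } else {
    p <- stats::wilcox.test(x, y, alternative = "greater",
                            exact = FALSE, correct = TRUE)$p.value
    method <- "normal_approximation"
  }
  list(statistic = w, p = p, method = method)
}

#' Compare the mutual-information density of a gene set to the rest
#'
#' Tests whether the per-gene MI values of a gene set are stochastically
#' greater than those of the remaining transcriptome (universe minus set)
#' with a one-sided rank-sum test — the "information density" comparison.
#'
#' @param profile An [compute_mi_profile()] result.
#' @param gene_set Character vector of gene ids; ids outside the profile's
#'   universe are dropped (an error is raised if none remain).
#' @param exact_threshold Passed to [rank_sum_greater()].
#' @return An object of class `density_comparison`: `n_set`, `n_rest`,
#'   `rank_sum_statistic`, `p_one_sided`, `median_set`, `median_rest`,
#'   `alternative = "set_greater"`, `method`.
#' @export
compare_mi_density <- function(profile, gene_set, exact_threshold = 200L) {
  if (!inherits(profile, "mi_profile")) stopf("profile must be an mi_profile")
  if (!length(gene_set)) stopf("gene_set is empty")
  universe <- names(profile$mi)
  inset <- intersect(gene_set, universe)
  if (!length(inset))
    stopf("no gene-set id is in the profile universe; missing ids e.g. %s",
          paste(utils::head(setdiff(gene_set, universe), 5), collapse = ", "))
  rest <- setdiff(universe, inset)
  if (!length(rest)) stopf("gene set covers the whole universe; no 'rest' to compare")
  rs <- rank_sum_greater(profile$mi[inset], profile$mi[rest],
                         exact_threshold = exact_threshold)
  structure(list(n_set = length(inset), n_rest = length(rest),
                 rank_sum_statistic = rs$statistic,
                 p_one_sided = rs$p,
                 median_set = stats::median(profile$mi[inset]),
                 median_rest = stats::median(profile$mi[rest]),
                 alternative = "set_greater", method = rs$method),
            class = "density_comparison")
}

#' @export
print.density_comparison <- function(x, ...) {
  cat(sprintf(
    "density_comparison: %d set vs %d rest; median MI %.3f vs %.3f; one-sided p = %.4g (%s)\n",
    x$n_set, x$n_rest, x$median_set, x$median_rest, x$p_one_sided, x$method))
  invisible(x)
}
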