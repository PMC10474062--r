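#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]), capped at 1 and
#' monotone in p-rank.
#'
#' @param p_values Numeric vector in \[0, 1\] (NA not allowed).
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1))
    stopf("p-values must be numbers in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Stand-in differential-expression caller (per-gene Welch t-test)
#'
#' A deliberately simple DEG caller for synthetic data: per gene, a Welch
#' two-sample t-test on the log2-CPM values of the contrast's two groups,
#' followed by Benjamini-Hochberg adjustment; `is_deg` flags genes with
#' `q < alpha`.  Genes with zero variance in both groups get `p = 1`
#' (documented policy; such genes carry no evidence under this test).
#' Count-model callers are intentionally not reproduced here — externally
#' computed DEG tables can be supplied to the pipeline instead.
#'
#' @param matrix A [normalized_matrix()] (centering is irrelevant to the
#'   t statistic and tolerated).
#' @param annotation Sample annotation data.frame.
#' @param contrast A two-level contrast, `"CP_vs_BC"` or `"wt_vs_KO"`.
#' @param alpha FDR threshold (default 0.05).
#' @return A `deg_result` data.frame: `gene_id`, `p_value`, `q_value`,
#'   `log2_fold_change` (second factor level minus first, e.g. BC - CP),
#'   `is_deg`; attributes `method = "standin_welch"` and `alpha`.
#' @export
call_degs_standin <- function(matrix, annotation,
                              contrast = c("CP_vs_BC", "wt_vs_KO"),
                              alpha = 0.05) {
  if (!inherits(matrix, "normalized_matrix"))
    stopf("matrix must be a normalized_matrix")
  contrast <- match.arg(contrast)
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1)
    stopf("alpha must be in (0, 1)")
  sel <- contrast_samples(annotation, contrast)
  if (any(table(sel$labels) < 2))
    stopf("each contrast level needs at least 2 samples")
  v <- matrix$values[, sel$sample_id, drop = FALSE]
  g1 <- v[, sel$labels == levels(sel$labels)[1], drop = FALSE]
  g2 <- v[, sel$labels == levels(sel$labels)[2], drop = FALSE]
  n1 <- ncol(g1); n2 <- ncol(g2)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- rowSums((g1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((g2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  p[se2 == 0] <- 1  # zero variance in both groups: no evidence
  q <- bh_adjust(p)
  res <- data.frame(gene_id = rownames(v), p_value = unname(p),
                    q_value = unname(q),
                    log2_fold_change = unname(m2 - m1),
                    is_deg = unname(q < alpha),
                    stringsAsFactors = FALSE)
  attr(res, "method") <- "standin_welch"
  attr(res, "alpha") <- alpha
  attr(res, "contrast") <- contrast
  class(res) <- c("deg_result", "data.frame")
  res
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= k)` that a size-`n` draw from a universe
#' of `N` genes containing `K` successes (e.g. DEGs) contains at least the
#' observed `k` successes, computed stably via [stats::phyper()].  The
#' two-sided option doubles the smaller tail and caps at 1.
#'
#' @param N Universe size.
#' @param K Successes in the universe.
#' @param n Draw (gene-set) size.
#' @param k Observed successes in the draw.
#' @param tail `"upper"` (over-representation, default) or `"two_sided"`.
#' @return An `enrichment_result`: `N_universe`, `K_deg`, `n_set`,
#'   `k_deg_in_set`, `p_hypergeometric`, `tail`.
#' @examples
#' hypergeom_test(10, 4, 5, 4)$p_hypergeometric  # 6/252
#' @export
hypergeom_test <- function(N, K, n, k, tail = c("upper", "two_sided")) {
  tail <- match.arg(tail)
  for (v in list(N = N, K = K, n = n, k = k))
    if (!is_count_scalar(v, positive = FALSE)) stopf("counts must be nonnegative integers")
  if (K > N || n > N || k > min(K, n) || k < max(0, n - (N - K)))
    stopf("inconsistent counts: need k <= min(K, n) <= N and k >= n - (N - K)")
  upper <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p <- if (tail == "upper") upper else {
    lower <- stats::phyper(k, K, N - K, n)
    min(1, 2 * min(upper, lower))
  }
  structure(list(N_universe = as.integer(N), K_deg = as.integer(K),
                 n_set = as.integer(n), k_deg_in_set = as.integer(k),
                 p_hypergeometric = p, tail = tail),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: %d/%d in set vs %d/%d in universe; %s-tail hypergeometric p = %.4g\n",
    x$k_deg_in_set, x$n_set, x$K_deg, x$N_universe, x$tail, x$p_hypergeometric))
  invisible(x)
}

#' DEG-balance check for a gene set
#'
#' Asks whether a gene set's information advantage is explained simply by
#' containing more differentially expressed genes than expected: a
#' hypergeometric test of the DEG count inside the set against the DEG
#' count in the whole analysis universe.
#'
#' @param deg A `deg_result` (or any data.frame with `gene_id` and
#'   `is_deg`).
#' @param gene_set Character vector of gene ids.
#' @param tail Passed to [hypergeom_test()].
#' @return An `enrichment_result`.
#' @export
deg_balance_check <- function(deg, gene_set, tail = "upper") {
  if (!all(c("gene_id", "is_deg") %in% names(deg)))
    stopf("deg must have gene_id and is_deg columns")
  inset <- intersect(gene_set, deg$gene_id)
  if (!length(inset)) stopf("gene set shares no ids with the DEG table")
  hypergeom_test(N = nrow(deg), K = sum(deg$is_deg), n = length(inset),
                 k = sum(deg$is_deg[deg$gene_id %in% inset]), tail = tail)
}
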