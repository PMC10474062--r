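# Independent oracles and small fixture builders used across the suite.

# Plug-in MI by the double sum over cells, p(x,y) log2[p(x,y)/(p(x)p(y))]
# (a different route than the three-entropies formula in the package).
mi_oracle <- function(tab) {
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    pxy <- tab[i, j] / n
    if (pxy > 0) mi <- mi + pxy * log2(pxy / (px[i] * py[j]))
  }
  mi
}

# Exhaustive one-sided rank-sum p by enumerating every assignment of the
# pooled values to the "set" positions (mid-ranks for ties).
enum_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(r), n1)
  ws <- colSums(matrix(r[combs], nrow = n1))
  mean(ws >= w_obs - 1e-9)
}

# Exhaustive hypergeometric upper tail: enumerate every size-n subset of
# 1..N and count those containing >= k of the first K elements.
enum_hypergeom_p <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  combs <- utils::combn(N, n)
  overlap <- colSums(combs <= K)
  mean(overlap >= k)
}

# 2x2 factorial annotation matching the simulator's layout.
fake_annotation <- function(n = 5) {
  cond <- c("wt", "KO", "CP", "BC")
  data.frame(
    sample_id = paste0(rep(cond, each = n), "_", rep(seq_len(n), 4)),
    leukemic = factor(rep(c("nonCML", "nonCML", "CML", "CML"), each = n),
                      levels = c("nonCML", "CML")),
    genotype = factor(rep(c("wt", "KO", "wt", "KO"), each = n),
                      levels = c("wt", "KO")),
    condition = factor(rep(cond, each = n), levels = cond),
    stringsAsFactors = FALSE
  )
}

# Minimal state_space carrying given sample coordinates (axes 1 and 2
# selected), for rotation and comparison tests.
make_space <- function(coords) {
  if (is.null(rownames(coords)))
    rownames(coords) <- paste0("s", seq_len(nrow(coords)))
  structure(list(singular_values = rep(1, ncol(coords)),
                 sample_coords = coords, gene_loadings = NULL,
                 elbow_index = 2L,
                 selected_axes = c(disease = 1L, genotype = 2L),
                 rotation_angle_deg = 0, separation_scores = NULL,
                 universe = character(0),
                 sample_ids = rownames(coords)),
            class = "state_space")
}

# Centered normalized_matrix wrapping a raw value matrix.
centered_nm <- function(values) {
  normalized_matrix(values - rowMeans(values), centered = TRUE)
}

# sim_config scaled down to a small gene universe (the full-size defaults
# keep their 655-gene planted set, which needs n_genes >= 655).
small_config <- function(n_genes, seed, ...) {
  args <- list(n_genes = n_genes, seed = seed,
               planted_set_size = max(10, round(n_genes * 0.2)),
               n_leukemic_responsive = round(n_genes * 0.2),
               n_genotype_responsive = round(n_genes * 0.075))
  do.call(sim_config, utils::modifyList(args, list(...)))
}

random_contingency <- function(nrow, ncol) {
  repeat {
    tab <- matrix(rpois(nrow * ncol, lambda = sample(1:8, 1)), nrow, ncol)
    if (sum(tab) > 0) return(tab)
  }
}
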