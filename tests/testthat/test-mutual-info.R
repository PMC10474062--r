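test_that("max-entropy binning places boundaries at the tertile order statistics", {
  b <- fit_max_entropy_bins(1:9)
  expect_equal(b$boundaries, c(3, 6))
  bins <- assign_bins(1:9, b)
  expect_equal(bins, rep(1:3, each = 3))
  expect_equal(shannon_entropy(tabulate(bins)), log2(3), tolerance = 1e-12)

  # large normal sample: boundaries near the normal tertiles +-0.4307
  set.seed(19)
  bn <- fit_max_entropy_bins(rnorm(30000))
  expect_lt(max(abs(bn$boundaries - qnorm(c(1 / 3, 2 / 3)))), 0.02)

  expect_error(fit_max_entropy_bins(rep(1, 10)), "distinct")
  expect_error(fit_max_entropy_bins(c(0, 0, 0, 0, 0, 0, 1, 2)), "collapse")
})

test_that("plug-in MI agrees with the double-sum oracle and its bounds", {
  expect_equal(mi_from_table(rbind(c(5, 0), c(0, 5))), 1)
  expect_equal(mi_from_table(rbind(c(5, 5), c(0, 0))), 0)
  # identical conditional bin counts in each class: independence, MI = 0
  tab <- cbind(c(2, 2, 1), c(2, 2, 1))
  expect_equal(mi_from_table(tab), mi_oracle(tab), tolerance = 1e-12)
  expect_equal(mi_from_table(tab), 0, tolerance = 1e-12)

  set.seed(4)
  for (i in 1:200) {
    tab <- random_contingency(3, sample(c(2, 4), 1))
    mi <- mi_from_table(tab)
    expect_equal(mi, mi_oracle(tab), tolerance = 1e-12)
    # symmetry in X and Y
    expect_equal(mi, mi_from_table(t(tab)), tolerance = 1e-12)
    expect_gte(mi, 0)
    expect_lte(mi, min(shannon_entropy(rowSums(tab)),
                       shannon_entropy(colSums(tab))) + 1e-12)
  }
})

test_that("MI profiles hit the analytic values for extreme genes", {
  ann <- fake_annotation(5)
  # 10 non-leukemic samples for the wt_vs_KO contrast
  vals <- rbind(
    sep = c(rep(-1, 5), rep(1, 5), rnorm(10)),       # wt in bin 1, KO in bin 3
    const = rep(0, 20),                               # single occupied bin
    noise = rnorm(20)
  )
  colnames(vals) <- ann$sample_id
  vals["sep", ann$condition %in% c("CP", "BC")] <- rnorm(10)
  nm <- normalized_matrix(vals, centered = TRUE)  # synthetic values, by construction
  scheme <- fit_max_entropy_bins(rep(c(-1, 0, 1), 3))  # boundaries (-1, 0)
  prof <- compute_mi_profile(nm, ann, "wt_vs_KO", binning = scheme)
  expect_identical(prof$contrast, "wt_vs_KO")
  expect_length(prof$mi, 3)
  expect_equal(unname(prof$mi["sep"]), 1)    # H(Y) = 1 bit, H(Y|X) = 0
  expect_equal(unname(prof$mi["const"]), 0)
  expect_identical(prof$samples_used, ann$sample_id[1:10])
})

test_that("MI profile contracts: refitted binning, level checks, bounds", {
  ds <- simulate_counts(small_config(200, seed = 6))
  nm <- mean_center(normalize_log(ds))
  prof <- compute_mi_profile(nm, ds$annotation, "CP_vs_BC")
  expect_equal(prof$binning$n_pooled, 200 * 10)
  expect_true(all(prof$mi >= 0))
  hy <- shannon_entropy(table(prof$labels))
  expect_true(all(prof$mi <= hy + 1e-12))

  expect_error(compute_mi_profile(normalize_log(ds), ds$annotation, "CP_vs_BC"),
               "centered")
  ann_no_bc <- ds$annotation[ds$annotation$condition != "BC", ]
  expect_error(compute_mi_profile(nm, ann_no_bc, "CP_vs_BC"), "BC")

  # four-condition contrast uses all samples and can exceed 1 bit
  prof4 <- compute_mi_profile(nm, ds$annotation, "condition4")
  expect_length(prof4$samples_used, 20)
  expect_true(all(prof4$mi <= 2 + 1e-12))
})

test_that("permuting sample labels destroys planted mutual information", {
  ds <- simulate_counts(sim_config(seed = 13))
  nm <- mean_center(normalize_log(ds))
  prof <- compute_mi_profile(nm, ds$annotation, "CP_vs_BC")
  decoys <- generate_gene_sets(ds, n_decoys = 20, seed = 7)[-1]
  elevation <- function(p) mean(p$mi[ds$gene_sets$planted]) -
    mean(vapply(decoys, function(s) mean(p$mi[s]), numeric(1)))
  resp <- ds$truth$gene_id[ds$truth$in_planted_set & ds$truth$genotype_responsive]

  perm_elev <- vapply(1:6, function(ps) {
    ann_perm <- ds$annotation
    set.seed(100 + ps)
    ann_perm$condition <- sample(ann_perm$condition)
    ann_perm$leukemic <- factor(
      ifelse(ann_perm$condition %in% c("CP", "BC"), "CML", "nonCML"),
      levels = c("nonCML", "CML"))
    prof_perm <- compute_mi_profile(nm, ann_perm, "CP_vs_BC")
    # responsive-gene MI collapses toward the plug-in noise floor
    expect_lt(mean(prof_perm$mi[resp]), mean(prof$mi[resp]) - 0.1)
    elevation(prof_perm)
  }, numeric(1))
  # averaged over permutations, the planted set sits where decoy sets sit
  expect_lt(abs(mean(perm_elev)), 0.25 * elevation(prof))
})

test_that("one-sided rank-sum p-values match exhaustive enumeration", {
  # fully separated 3-vs-5: only one assignment reaches the observed sum
  rs <- rank_sum_greater(c(0.9, 0.8, 0.7), c(0.4, 0.3, 0.2, 0.1, 0.05))
  expect_identical(rs$method, "exact_enumeration")
  expect_equal(rs$p, 1 / choose(8, 3), tolerance = 1e-12)

  # random configurations with and without ties
  set.seed(12)
  for (i in 1:40) {
    n1 <- sample(2:7, 1)
    n2 <- sample(2:7, 1)
    x <- sample(seq(0, 1, by = 0.1), n1, replace = TRUE)  # forces ties
    y <- sample(seq(0, 1, by = 0.1), n2, replace = TRUE)
    expect_equal(rank_sum_greater(x, y)$p, enum_rank_sum_p(x, y),
                 tolerance = 1e-12)
    xf <- rnorm(n1)
    yf <- rnorm(n2)
    expect_equal(rank_sum_greater(xf, yf)$p, enum_rank_sum_p(xf, yf),
                 tolerance = 1e-12)
    # tie-free case: agrees with the classical exact Wilcoxon distribution
    expect_equal(rank_sum_greater(xf, yf)$p,
                 stats::wilcox.test(xf, yf, alternative = "greater",
                                    exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }

  # complete tie: no evidence of an upward shift
  expect_gte(rank_sum_greater(rep(1, 4), rep(1, 6))$p, 0.5)
})

test_that("MI-density comparison books set and rest correctly and validates input", {
  ds <- simulate_counts(sim_config(seed = 14))
  nm <- mean_center(normalize_log(ds))
  prof <- compute_mi_profile(nm, ds$annotation, "CP_vs_BC")
  d <- compare_mi_density(prof, ds$gene_sets$planted)
  expect_equal(d$n_set + d$n_rest, length(prof$mi))
  expect_identical(d$method, "normal_approximation")
  expect_lt(d$p_one_sided, 0.01)
  expect_gt(d$median_set, d$median_rest)

  expect_error(compare_mi_density(prof, character(0)), "empty")
  expect_error(compare_mi_density(prof, c("bogus_a", "bogus_b")), "bogus_a")
})
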