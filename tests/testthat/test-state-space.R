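test_that("state-space SVD satisfies rank, energy and orthonormality properties", {
  set.seed(42)
  # rank-1 input: exactly one singular value above 1e-10
  u <- rnorm(30)
  v <- rnorm(6)
  m1 <- outer(u, v)
  ss1 <- fit_state_space(normalized_matrix(m1 - rowMeans(m1), centered = TRUE))
  sv <- ss1$singular_values
  expect_equal(sum(sv > 1e-10), 1)

  m <- matrix(rnorm(50 * 10), 50, 10)
  m <- m - rowMeans(m)
  ss <- fit_state_space(normalized_matrix(m, centered = TRUE))
  expect_equal(sum(ss$singular_values^2), sum(m^2), tolerance = 1e-6)
  expect_lt(max(abs(crossprod(ss$gene_loadings) - diag(ncol(ss$gene_loadings)))), 1e-8)
  # sign convention: largest-|loading| gene positive in every component
  picks <- apply(ss$gene_loadings, 2, function(x) x[which.max(abs(x))])
  expect_true(all(picks > 0))
})

test_that("sample coordinates agree with the covariance eigendecomposition oracle", {
  set.seed(7)
  for (i in 1:5) {
    m <- matrix(rnorm(40 * 12), 40, 12)
    m <- m - rowMeans(m)
    ss <- fit_state_space(normalized_matrix(m, centered = TRUE))
    e <- eigen(crossprod(m), symmetric = TRUE)
    for (k in 1:8) {
      oracle <- e$vectors[, k] * sqrt(e$values[k])
      got <- ss$sample_coords[, k]
      if (sum(oracle * got) < 0) oracle <- -oracle
      expect_lt(max(abs(got - oracle)), 1e-8)
    }
  }
})

test_that("fit_state_space validates input and reports universe problems", {
  m <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  nm_raw <- normalized_matrix(m, centered = FALSE)
  expect_error(fit_state_space(nm_raw), "centered")
  nm <- centered_nm(m)
  expect_error(fit_state_space(nm, universe = c("nope1", "nope2")), "no gene ids")
  expect_warning(ssu <- fit_state_space(nm, universe = c("g1", "g2", "g3", "nope")),
                 "absent")
  expect_identical(ssu$universe, c("g1", "g2", "g3"))
  expect_error(fit_state_space(centered_nm(m[, 1:2, drop = FALSE])), "3 samples")
})

test_that("scree elbow maximizes the distance to the first-last chord", {
  s <- c(10, 6, 3.5, 2.0, 1.9, 1.8, 1.7, 1.6)
  # independent computation: vertical residual from the chord is
  # proportional to the perpendicular distance
  chord <- s[1] + (s[length(s)] - s[1]) * (seq_along(s) - 1) / (length(s) - 1)
  oracle <- which.max(abs(s - chord)[-c(1, length(s))]) + 1L
  expect_identical(find_scree_elbow(s), 4L)
  expect_identical(oracle, 4L)

  expect_identical(find_scree_elbow(c(10, 1, 1, 1, 1)), 2L)
  # perfectly linear decay: all interior distances tie at 0 -> smallest
  expect_identical(find_scree_elbow(c(5, 4, 3, 2, 1)), 2L)

  expect_error(find_scree_elbow(c(1, 2, 3)), "nonincreasing")
  expect_error(find_scree_elbow(c(2, 1)), "at least 3")
})

test_that("axis-separation scores match the ANOVA R-squared oracle", {
  coords <- cbind(c(-1, -1, 1, 1), c(1, -1, 1, -1))
  rownames(coords) <- paste0("s", 1:4)
  sp <- make_space(coords)
  ann <- data.frame(sample_id = paste0("s", 1:4),
                    leukemic = factor(c("A", "A", "B", "B")),
                    genotype = factor(c("A", "A", "B", "B")),
                    condition = factor(c("A", "A", "B", "B")))
  sc <- score_axis_separation(sp, ann, "leukemic")
  expect_equal(unname(sc), c(1, 0))

  # random coordinates: equality with an aov-based oracle, and the null
  # mean score for balanced 2-level labels at n = 20 is about 1/19
  set.seed(31)
  ann20 <- fake_annotation(5)
  means <- replicate(300, {
    m <- matrix(rnorm(30 * 20), 30, 20, dimnames = list(NULL, ann20$sample_id))
    ssp <- fit_state_space(centered_nm(m))
    sc <- score_axis_separation(ssp, ann20, "leukemic")
    # row-centering makes the last component degenerate; skip it
    keep <- ssp$singular_values > 1e-8
    oracle <- apply(ssp$sample_coords[, keep], 2, function(x) {
      a <- stats::anova(stats::lm(x ~ ann20$leukemic))
      a$`Sum Sq`[1] / sum(a$`Sum Sq`)
    })
    expect_lt(max(abs(sc[keep] - oracle)), 1e-10)
    mean(sc[keep])
  })
  expect_lt(abs(mean(means) - 1 / 19), 0.02)
})

test_that("axis selection picks the disease component first, then genotype", {
  ds <- simulate_counts(sim_config(seed = 21))
  nm <- mean_center(normalize_log(ds))
  ss <- select_axes(fit_state_space(nm), ds$annotation)
  expect_identical(unname(ss$selected_axes["disease"]), 1L)
  expect_false(ss$selected_axes["disease"] == ss$selected_axes["genotype"])
  expect_identical(rownames(ss$separation_scores),
                   c("leukemic", "genotype", "condition4"))
  expect_true(all(ss$separation_scores >= 0 & ss$separation_scores <= 1))
  # single-level factor errors
  ann1 <- ds$annotation
  ann1$leukemic <- factor("CML", levels = c("nonCML", "CML"))
  expect_error(score_axis_separation(ss, ann1, "leukemic"), "single level")
})

test_that("plane rotation is an exact isometry with the documented geometry", {
  sp <- make_space(rbind(c(1, 0), c(0, 0)))
  r90 <- rotate_plane(sp, 90)
  expect_equal(unname(r90$sample_coords[1, ]), c(0, 1), tolerance = 1e-12)
  expect_equal(r90$rotation_angle_deg, 90)

  # auto mode: centroids (0,0) and (1,1) -> -45 degrees, centroid axis on +x
  coords <- rbind(c(-0.1, 0.1), c(0.1, -0.1), c(0.9, 1.1), c(1.1, 0.9))
  ann <- data.frame(sample_id = paste0("s", 1:4),
                    leukemic = factor(c("nonCML", "nonCML", "CML", "CML"),
                                      levels = c("nonCML", "CML")),
                    genotype = factor(rep("wt", 4)),
                    condition = factor(c("wt", "wt", "CP", "CP")))
  auto <- rotate_plane(make_space(coords), annotation = ann)
  expect_equal(auto$rotation_angle_deg, -45, tolerance = 1e-9)
  cent <- colMeans(auto$sample_coords[3:4, ]) - colMeans(auto$sample_coords[1:2, ])
  expect_lt(abs(cent[2]), 1e-9)
  expect_gt(cent[1], 0)

  # rotating by theta then -theta restores coordinates; distances preserved
  set.seed(8)
  sp2 <- make_space(matrix(rnorm(24), 12, 2))
  fwd <- rotate_plane(sp2, 33.3)
  expect_lt(max(abs(as.matrix(dist(fwd$sample_coords)) -
                    as.matrix(dist(sp2$sample_coords)))), 1e-10)
  back <- rotate_plane(fwd, -33.3)
  expect_lt(max(abs(back$sample_coords - sp2$sample_coords)), 1e-10)

  # degenerate coincident centroids
  same <- make_space(rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1)))
  expect_error(rotate_plane(same, annotation = ann), "coincide")
})

test_that("state-space comparison is a sign/scale-invariant R-squared", {
  set.seed(5)
  a <- matrix(rnorm(24), 12, 2, dimnames = list(paste0("s", 1:12), NULL))
  cmp <- compare_state_spaces(a, a)
  expect_equal(unname(cmp$r_squared), c(1, 1))
  cmp2 <- compare_state_spaces(a, -3 * a)
  expect_equal(unname(cmp2$r_squared), c(1, 1))

  # independent vectors, n = 20: E[R^2] = 1/(n-1)
  r2 <- replicate(2000, {
    x <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("s", 1:20), NULL))
    y <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("s", 1:20), NULL))
    compare_state_spaces(x, y)$r_squared
  })
  expect_lt(abs(mean(r2) - 1 / 19), 0.015)

  b <- a
  rownames(b) <- paste0("t", 1:12)
  expect_error(compare_state_spaces(a, b), "same samples")
  z <- a
  z[, 1] <- 0
  cmp3 <- compare_state_spaces(a, z)
  expect_true(is.na(cmp3$r_squared[1]) && cmp3$undefined[1])
  expect_false(cmp3$undefined[2])
})
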