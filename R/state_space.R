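#' Fit an SVD state-space
#'
#' Performs a thin singular value decomposition of the mean-centered
#' log-normalized gene-by-sample matrix (optionally restricted to a gene
#' universe) and returns the sample coordinates in the resulting
#' state-space.  Coordinates are the right singular vectors scaled by the
#' singular values, so distances between samples reflect expression
#' distances in the chosen universe.  Each singular vector's sign is fixed
#' so that its largest-magnitude gene loading is positive, removing the
#' sign ambiguity of the SVD from all downstream output.
#'
#' @param matrix A centered [normalized_matrix()] (see [mean_center()]).
#' @param universe Optional character vector of gene ids; the SVD is
#'   restricted to the intersection with the matrix rows (missing ids are
#'   reported with a warning).
#' @return An object of class `state_space`: singular values, sample
#'   coordinates (`sample_coords`, samples x components), gene loadings,
#'   `elbow_index` from [find_scree_elbow()], and slots for the selected
#'   axis pair, rotation angle and separation scores filled by
#'   [select_axes()] and [rotate_plane()].
#' @export
fit_state_space <- function(matrix, universe = NULL) {
  if (!inherits(matrix, "normalized_matrix"))
    stopf("matrix must be a normalized_matrix")
  if (!matrix$centered)
    stopf("state-space requires mean-centered values; call mean_center() first")
  M <- matrix$values
  if (!is.null(universe)) {
    missing <- setdiff(universe, rownames(M))
    if (length(missing) == length(universe))
      stopf("universe shares no gene ids with the matrix")
    if (length(missing))
      warnf("%d universe gene id(s) absent from the matrix (e.g. %s)",
            length(missing), paste(utils::head(missing, 3), collapse = ", "))
    M <- M[intersect(universe, rownames(M)), , drop = FALSE]
  }
  if (ncol(M) < 3) stopf("need at least 3 samples")
  if (nrow(M) < 2) stopf("need at least 2 genes")

  sv <- svd(M)
  # deterministic sign convention: largest-|loading| gene positive
  for (j in seq_along(sv$d)) {
    i <- which.max(abs(sv$u[, j]))
    if (sv$u[i, j] < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  coords <- sweep(sv$v, 2, sv$d, `*`)
  comp <- paste0("PC", seq_along(sv$d))
  dimnames(coords) <- list(colnames(M), comp)
  dimnames(sv$u) <- list(rownames(M), comp)

  structure(list(
    singular_values = sv$d,
    sample_coords = coords,
    gene_loadings = sv$u,
    elbow_index = find_scree_elbow(sv$d),
    selected_axes = NULL,
    rotation_angle_deg = 0,
    separation_scores = NULL,
    universe = rownames(M),
    sample_ids = colnames(M)
  ), class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("state_space: %d genes, %d samples, %d components (elbow at %d)\n",
              length(x$universe), length(x$sample_ids),
              length(x$singular_values), x$elbow_index))
  if (!is.null(x$selected_axes))
    cat(sprintf("  axes: disease = PC%d, genotype = PC%d; rotation %.2f deg\n",
                x$selected_axes[["disease"]], x$selected_axes[["genotype"]],
                x$rotation_angle_deg))
  invisible(x)
}

#' Locate the elbow of a scree plot
#'
#' Returns the 1-based index of the singular value with maximal
#' perpendicular distance from the chord joining the first and last scree
#' points.  Only interior indices are candidates (the chord endpoints have
#' distance zero by construction); among tied maxima the smallest index
#' wins.
#'
#' @param singular_values Nonincreasing nonnegative values, length >= 3.
#' @return Integer elbow index.
#' @examples
#' find_scree_elbow(c(10, 6, 3.5, 2, 1.9, 1.8, 1.7, 1.6))  # 4
#' @export
find_scree_elbow <- function(singular_values) {
  s <- singular_values
  n <- length(s)
  if (n < 3) stopf("need at least 3 singular values")
  if (any(diff(s) > 1e-8 * max(abs(s), 1)))
    stopf("singular values must be nonincreasing")
  i <- seq_len(n)
  # distance from (i, s_i) to the chord (1, s_1) -- (n, s_n)
  dy <- s[n] - s[1]
  dx <- n - 1
  d <- abs(dy * (i - 1) - dx * (s - s[1])) / sqrt(dy^2 + dx^2)
  interior <- 2:(n - 1)
  dmax <- max(d[interior])
  interior[which(d[interior] >= dmax - 1e-12)[1]]
}

factor_labels <- function(annotation, sample_ids,
                          factor = c("leukemic", "genotype", "condition4")) {
  factor <- match.arg(factor)
  idx <- match(sample_ids, annotation$sample_id)
  if (anyNA(idx))
    stopf("annotation is missing sample(s): %s",
          paste(utils::head(sample_ids[is.na(idx)], 3), collapse = ", "))
  col <- if (factor == "condition4") "condition" else factor
  droplevels(base::factor(annotation[[col]][idx]))
}

#' Score how well each component separates an experimental factor
#'
#' For every component, the score is the between-group sum of squares of
#' the sample coordinates divided by the total sum of squares (the one-way
#' ANOVA R-squared), in \[0, 1\]: 1 means the factor's groups are perfectly
#' separated along that component, 0 means their means coincide.
#'
#' @param model A `state_space`.
#' @param annotation Sample annotation data.frame (`sample_id`, `leukemic`,
#'   `genotype`, `condition`).
#' @param factor Which factor to score: `"leukemic"`, `"genotype"`, or the
#'   four-level `"condition4"` cross.
#' @return Numeric vector of per-component scores.
#' @export
score_axis_separation <- function(model, annotation,
                                  factor = c("leukemic", "genotype", "condition4")) {
  if (!inherits(model, "state_space")) stopf("model must be a state_space")
  y <- factor_labels(annotation, model$sample_ids, factor)
  if (nlevels(y) < 2) stopf("factor has a single level; cannot score separation")
  small <- names(which(table(y) < 2))
  if (length(small))
    warnf("factor level(s) with fewer than 2 samples: %s",
          paste(small, collapse = ", "))
  apply(model$sample_coords, 2, function(x) {
    tot <- sum((x - mean(x))^2)
    if (tot <= 0) return(0)
    gm <- tapply(x, y, mean)
    sum(table(y) * (gm - mean(x))^2) / tot
  })
}

#' Select the disease and genotype axes of a state-space
#'
#' Sets `selected_axes` to the component best separating leukemic status
#' and, among the remaining components, the one best separating genotype;
#' stores the full separation-score table for all three factors.
#'
#' @inheritParams score_axis_separation
#' @return The model with `selected_axes` and `separation_scores` filled.
#' @export
select_axes <- function(model, annotation) {
  s_leu <- score_axis_separation(model, annotation, "leukemic")
  s_gen <- score_axis_separation(model, annotation, "genotype")
  s_con <- score_axis_separation(model, annotation, "condition4")
  axis_d <- unname(which.max(s_leu))
  s_gen_masked <- s_gen
  s_gen_masked[axis_d] <- -Inf
  axis_g <- unname(which.max(s_gen_masked))
  model$selected_axes <- c(disease = axis_d, genotype = axis_g)
  model$separation_scores <- rbind(leukemic = s_leu, genotype = s_gen,
                                   condition4 = s_con)
  model
}

#' Rotate the selected state-space plane
#'
#' Applies a 2-D rotation to the (disease axis, genotype axis) coordinates,
#' leaving all other components untouched.  In automatic mode the angle is
#' chosen so that the vector from the first-level centroid to the
#' second-level centroid of the chosen factor (non-leukemic to leukemic by
#' default) lies along the positive x-axis, which makes disease
#' progression read left-to-right.  The rotation is an isometry of the
#' plane: all inter-sample distances are preserved.
#'
#' @param model A `state_space` with `selected_axes` set (see
#'   [select_axes()]).
#' @param angle_deg Rotation angle in degrees (counterclockwise), or NULL
#'   for automatic centroid alignment.
#' @param annotation Required in automatic mode.
#' @param factor Two-level factor used for centroid alignment.
#' @return The model with rotated plane coordinates;
#'   `rotation_angle_deg` accumulates the applied angle.
#' @export
rotate_plane <- function(model, angle_deg = NULL, annotation = NULL,
                         factor = "leukemic") {
  if (!inherits(model, "state_space")) stopf("model must be a state_space")
  if (is.null(model$selected_axes))
    stopf("selected_axes not set; call select_axes() first")
  axes <- model$selected_axes
  plane <- model$sample_coords[, axes, drop = FALSE]
  if (is.null(angle_deg)) {
    if (is.null(annotation)) stopf("automatic rotation needs the annotation")
    y <- factor_labels(annotation, model$sample_ids, factor)
    if (nlevels(y) != 2) stopf("automatic rotation needs a 2-level factor")
    c1 <- colMeans(plane[y == levels(y)[1], , drop = FALSE])
    c2 <- colMeans(plane[y == levels(y)[2], , drop = FALSE])
    v <- c2 - c1
    if (sqrt(sum(v^2)) < 1e-12)
      stopf("group centroids coincide; rotation angle undefined")
    angle_deg <- -atan2(v[2], v[1]) * 180 / pi
  }
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  model$sample_coords[, axes] <- plane %*% R
  model$rotation_angle_deg <- model$rotation_angle_deg + angle_deg
  model
}

#' Extract the selected-plane coordinates of a state-space
#'
#' @param model A `state_space` with `selected_axes` set.
#' @return Samples x 2 matrix (disease axis = column 1).
#' @export
plane_coords <- function(model) {
  if (!inherits(model, "state_space")) stopf("model must be a state_space")
  if (is.null(model$selected_axes))
    stopf("selected_axes not set; call select_axes() first")
  p <- model$sample_coords[, model$selected_axes, drop = FALSE]
  colnames(p) <- c("disease_axis", "genotype_axis")
  p
}

#' Compare two state-spaces by squared correlation of coordinates
#'
#' Per axis of the selected plane, computes the squared Pearson correlation
#' between the sample coordinates of two state-spaces (e.g. the full
#' transcriptome and a gene-set sub-space).  R-squared is invariant to sign
#' flips and common rescaling of either coordinate vector.
#'
#' @param full,subset `state_space` objects with axes selected (rotated or
#'   not), or samples x 2 coordinate matrices with matching rownames.
#' @param axis_labels Length-2 character labels for the compared axes.
#' @return An object of class `space_comparison`: `r_squared` (named
#'   length-2 vector, NA where an axis has zero variance), `n_samples`,
#'   `axes_compared`, `undefined` flags.
#' @export
compare_state_spaces <- function(full, subset,
                                 axis_labels = c("disease_axis", "genotype_axis")) {
  a <- if (inherits(full, "state_space")) plane_coords(full) else as.matrix(full)
  b <- if (inherits(subset, "state_space")) plane_coords(subset) else as.matrix(subset)
  if (ncol(a) != 2 || ncol(b) != 2) stopf("coordinate sets must have 2 columns")
  if (nrow(a) != nrow(b) || !identical(rownames(a), rownames(b)))
    stopf("the two coordinate sets must cover the same samples in the same order")
  r2 <- numeric(2)
  undefined <- logical(2)
  for (j in 1:2) {
    if (stats::sd(a[, j]) == 0 || stats::sd(b[, j]) == 0) {
      r2[j] <- NA_real_
      undefined[j] <- TRUE
    } else {
      r2[j] <- stats::cor(a[, j], b[, j])^2
    }
  }
  names(r2) <- names(undefined) <- axis_labels
  structure(list(r_squared = r2, n_samples = nrow(a),
                 axes_compared = axis_labels, undefined = undefined),
            class = "space_comparison")
}

#' @export
print.space_comparison <- function(x, ...) {
  cat(sprintf("space_comparison over %d samples: R2(%s) = %.3f, R2(%s) = %.3f\n",
              x$n_samples, x$axes_compared[1], x$r_squared[1],
              x$axes_compared[2], x$r_squared[2]))
  invisible(x)
}
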