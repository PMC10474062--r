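#' Configure an end-to-end analysis run
#'
#' Inputs may be in-memory objects (count matrix or `sim_dataset`,
#' annotation data.frame, named gene-set list) or file paths (counts TSV,
#' annotation TSV, GMT) as written by [write_dataset()].
#'
#' @param counts Count matrix, `sim_dataset`, or counts TSV path.
#' @param annotation Annotation data.frame or TSV path; defaults to the
#'   `sim_dataset` annotation when `counts` is one.
#' @param gene_sets Named list of gene-id vectors or GMT path; defaults to
#'   the `sim_dataset` gene sets.
#' @param out_dir Optional directory for TSV/JSON artifacts (nothing is
#'   written when NULL).
#' @param contrasts Subset of `c("condition4", "CP_vs_BC", "wt_vs_KO")`.
#' @param binning_mode `"refit"` fits bin boundaries per contrast;
#'   `"reuse_condition4"` fits them once on all four conditions.
#' @param rotation `"auto"` (centroid alignment, per space) or a fixed
#'   angle in degrees applied to every space.
#' @param alpha FDR threshold for the stand-in DEG caller.
#' @param deg `"standin"`, or a data.frame / TSV path with externally
#'   computed `gene_id` + `is_deg` columns.
#' @param deg_contrast Two-level contrast used for the DEG-balance check.
#' @param seed Integer seed echoed in the report (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts, annotation = NULL, gene_sets = NULL,
                            out_dir = NULL,
                            contrasts = c("condition4", "CP_vs_BC", "wt_vs_KO"),
                            binning_mode = c("refit", "reuse_condition4"),
                            rotation = "auto", alpha = 0.05,
                            deg = "standin", deg_contrast = "CP_vs_BC",
                            seed = 1L) {
  binning_mode <- match.arg(binning_mode)
  contrasts <- match.arg(contrasts, several.ok = TRUE)
  if (!(identical(rotation, "auto") || is_number(rotation)))
    stopf("rotation must be \"auto\" or a numeric angle in degrees")
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (inherits(counts, "sim_dataset")) {
    if (is.null(annotation)) annotation <- counts$annotation
    if (is.null(gene_sets)) gene_sets <- counts$gene_sets
    counts <- counts$counts
  }
  if (is.character(counts)) counts <- read_counts_tsv(counts)
  if (is.character(annotation)) annotation <- read_annotation_tsv(annotation)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  if (is.null(annotation) || is.null(gene_sets))
    stopf("annotation and gene_sets are required")
  if (is.character(deg) && !identical(deg, "standin")) {
    deg <- utils::read.delim(deg, stringsAsFactors = FALSE)
  }
  structure(list(counts = counts, annotation = annotation,
                 gene_sets = gene_sets, out_dir = out_dir,
                 contrasts = contrasts, binning_mode = binning_mode,
                 rotation = rotation, alpha = alpha, deg = deg,
                 deg_contrast = deg_contrast, seed = as.integer(seed)),
            class = "pipeline_config")
}

rotate_per_config <- function(model, config) {
  if (identical(config$rotation, "auto"))
    rotate_plane(model, annotation = config$annotation, factor = "leukemic")
  else
    rotate_plane(model, angle_deg = config$rotation)
}

space_summary <- function(model) {
  list(elbow_index = model$elbow_index,
       axis_disease = unname(model$selected_axes[["disease"]]),
       axis_genotype = unname(model$selected_axes[["genotype"]]),
       rotation_angle_deg = model$rotation_angle_deg,
       separation_scores = apply(model$separation_scores, 1, function(r)
         stats::setNames(as.list(r), colnames(model$separation_scores))),
       n_genes = length(model$universe),
       singular_values = model$singular_values)
}

#' Run the full state-space / mutual-information analysis
#'
#' Executes normalize -> state-space (full transcriptome and every gene
#' set, with axis selection, rotation and sub-space comparison) ->
#' per-contrast mutual-information profiles with set-vs-rest density
#' comparisons -> DEG-balance check, and optionally writes TSV/JSON
#' artifacts.  The run is deterministic given the config.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list: `state_space` (full-space summary),
#'   `gene_sets` (per set: sub-space summary, rotated and pre-rotation
#'   R-squared, per-contrast density comparison, DEG balance),
#'   `mi` (per contrast: binning and summary), `deg` summary, `config`
#'   echo, `seed`, package `version`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stopf("config must be a pipeline_config")
  set.seed(config$seed)
  ann <- config$annotation
  message(sprintf("pipeline: %d genes x %d samples; %d gene set(s); contrasts: %s",
                  nrow(config$counts), ncol(config$counts),
                  length(config$gene_sets), paste(config$contrasts, collapse = ", ")))

  nm <- mean_center(normalize_log(config$counts))

  full <- select_axes(fit_state_space(nm), ann)
  full_pre <- plane_coords(full)
  full <- rotate_per_config(full, config)

  # mutual information per contrast (bin boundaries per binning_mode)
  reuse <- NULL
  if (config$binning_mode == "reuse_condition4") {
    sel <- contrast_samples(ann, "condition4")
    reuse <- fit_max_entropy_bins(as.vector(nm$values[, sel$sample_id]))
  }
  profiles <- lapply(config$contrasts, function(ct)
    compute_mi_profile(nm, ann, ct, binning = reuse))
  names(profiles) <- config$contrasts

  deg <- config$deg
  if (identical(deg, "standin"))
    deg <- call_degs_standin(nm, ann, config$deg_contrast, alpha = config$alpha)

  set_reports <- lapply(names(config$gene_sets), function(set_name) {
    set <- config$gene_sets[[set_name]]
    inter <- intersect(set, rownames(config$counts))
    message(sprintf("  set %s: %d/%d ids in the count matrix",
                    set_name, length(inter), length(set)))
    if (!length(inter)) stopf("gene set %s shares no ids with the counts", set_name)
    sub <- select_axes(fit_state_space(nm, universe = inter), ann)
    cmp_pre <- compare_state_spaces(full_pre, plane_coords(sub))
    sub <- rotate_per_config(sub, config)
    cmp <- compare_state_spaces(full, sub)
    density <- lapply(profiles, function(pr) {
      d <- compare_mi_density(pr, inter)
      d[c("n_set", "n_rest", "rank_sum_statistic", "p_one_sided",
          "median_set", "median_rest", "method")]
    })
    balance <- deg_balance_check(deg, inter)
    list(n_genes_used = length(inter),
         subspace = space_summary(sub),
         r_squared = as.list(cmp$r_squared),
         r_squared_prerotation = as.list(cmp_pre$r_squared),
         mi_density = density,
         deg_balance = unclass(balance))
  })
  names(set_reports) <- names(config$gene_sets)

  report <- list(
    state_space = space_summary(full),
    gene_sets = set_reports,
    mi = lapply(profiles, function(pr)
      list(contrast = pr$contrast, n_samples = length(pr$samples_used),
           binning_boundaries = pr$binning$boundaries,
           binning_source = pr$binning$source,
           median_mi = stats::median(pr$mi), max_mi = max(pr$mi))),
    deg = list(method = attr(deg, "method") %||% "external",
               contrast = attr(deg, "contrast") %||% config$deg_contrast,
               alpha = config$alpha, n_deg = sum(deg$is_deg),
               n_genes = nrow(deg)),
    config = list(contrasts = config$contrasts,
                  binning_mode = config$binning_mode,
                  rotation = config$rotation, alpha = config$alpha),
    seed = config$seed,
    version = as.character(utils::packageVersion("statemi"))
  )
  class(report) <- "run_report"

  if (!is.null(config$out_dir))
    write_report_artifacts(report, full, profiles, deg, ann, config$out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report_artifacts <- function(report, full, profiles, deg, ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pc <- plane_coords(full)
  coords <- data.frame(sample_id = rownames(pc), x = pc[, 1], y = pc[, 2],
                       condition = ann$condition[match(rownames(pc), ann$sample_id)])
  utils::write.table(coords, file.path(dir, "state_space_coords.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  scree <- data.frame(component = seq_along(full$singular_values),
                      singular_value = full$singular_values)
  utils::write.table(scree, file.path(dir, "scree.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (ct in names(profiles)) {
    mi_df <- data.frame(gene_id = names(profiles[[ct]]$mi),
                        mi_bits = unname(profiles[[ct]]$mi))
    utils::write.table(mi_df, file.path(dir, sprintf("mi_%s.tsv", ct)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(deg, file.path(dir, "deg.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  ss <- x$state_space
  cat(sprintf("run_report (statemi %s, seed %d)\n", x$version, x$seed))
  cat(sprintf("  full space: elbow %d, disease axis PC%d, genotype axis PC%d, rotation %.1f deg\n",
              ss$elbow_index, ss$axis_disease, ss$axis_genotype,
              ss$rotation_angle_deg))
  for (nm in names(x$gene_sets)) {
    gs <- x$gene_sets[[nm]]
    cat(sprintf("  set %-10s R2 = %.3f / %.3f;", nm,
                gs$r_squared$disease_axis, gs$r_squared$genotype_axis))
    for (ct in names(gs$mi_density))
      cat(sprintf(" p[%s] = %.3g;", ct, gs$mi_density[[ct]]$p_one_sided))
    cat(sprintf(" DEG-balance p = %.3g\n", gs$deg_balance$p_hypergeometric))
  }
  cat(sprintf("  DEGs (%s, %s): %d of %d genes at FDR < %g\n",
              x$deg$method, x$deg$contrast, x$deg$n_deg, x$deg$n_genes,
              x$deg$alpha))
  invisible(x)
}
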