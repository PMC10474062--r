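#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header row of sample ids and gene ids in the first column,
#' as written by [write_dataset()].
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' Read a sample annotation table from TSV
#'
#' Columns: `sample_id`, `leukemic`, `genotype`, `condition`.
#'
#' @param path File path.
#' @return data.frame with factor columns levelled as in the simulator.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "leukemic", "genotype", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("annotation lacks column(s): %s", paste(miss, collapse = ", "))
  df$leukemic <- factor(df$leukemic, levels = c("nonCML", "CML"))
  df$genotype <- factor(df$genotype, levels = c("wt", "KO"))
  df$condition <- factor(df$condition, levels = condition_levels)
  df
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then member gene ids.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stopf("malformed GMT line(s): %s", paste(bad, collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @param descriptions Optional character vector (recycled "na" otherwise).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("sets must be a named list")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, ds, genes)
    paste(c(nm, ds, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `counts.tsv` (genes x samples), `annotation.tsv`,
#' `gene_sets.gmt`, `truth.tsv` and, optionally, a MatrixMarket triplet
#' (`counts.mtx` + `genes.txt` + `samples.txt`; requires the Matrix
#' package).
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @param mtx Also write MatrixMarket output?
#' @return Invisibly, the directory path.
#' @export
write_dataset <- function(dataset, dir, mtx = FALSE) {
  if (!inherits(dataset, "sim_dataset")) stopf("dataset must be a sim_dataset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts_df <- data.frame(gene_id = rownames(dataset$counts),
                          dataset$counts, check.names = FALSE)
  utils::write.table(counts_df, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(dataset$gene_sets, file.path(dir, "gene_sets.gmt"))
  utils::write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (mtx) {
    if (!requireNamespace("Matrix", quietly = TRUE))
      stopf("MatrixMarket output needs the Matrix package")
    Matrix::writeMM(Matrix::Matrix(dataset$counts, sparse = TRUE),
                    file.path(dir, "counts.mtx"))
    writeLines(rownames(dataset$counts), file.path(dir, "genes.txt"))
    writeLines(colnames(dataset$counts), file.path(dir, "samples.txt"))
  }
  invisible(dir)
}
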