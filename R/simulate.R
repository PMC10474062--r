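#' Configuration for the synthetic two-factor leukemia RNA-seq design
#'
#' Defines the parameters of a negative-binomial count simulation that
#' emulates a 2x2 factorial bulk RNA-seq study of leukemic stem cells:
#' four conditions (wild-type, knockout, chronic-phase leukemic,
#' blast-crisis leukemic) obtained by crossing leukemic status
#' (non-CML/CML) with genotype (wt/KO), five biological replicates per
#' condition by default.
#'
#' Counts follow NB(mu, phi) with `var = mu + phi * mu^2`.  A dominant
#' leukemic axis of variation is planted by giving `n_leukemic_responsive`
#' background genes a log2 fold-change of `leukemic_lfc` (random sign) in
#' leukemic samples; a secondary genotype axis likewise via
#' `n_genotype_responsive` genes responding in KO samples.  A planted
#' "metabolism-like" gene set of `planted_set_size` genes carries signal on
#' *both* axes for a fraction `planted_set_responsive_frac` of its members,
#' again with random signs, so the set is informative without being
#' uniformly up- or down-regulated.  Background responsive genes are drawn
#' outside the planted set so the set's information content is controlled
#' solely by its own responsive fraction.
#'
#' @param n_genes Number of genes in the simulated universe.
#' @param n_per_group Biological replicates per condition (default 5).
#' @param baseline_log_mean_mu,baseline_log_mean_sd Mean and sd (natural
#'   log scale) of the lognormal baseline expected count per gene.
#' @param dispersion NB dispersion phi (> 0); `var = mu + phi mu^2`.
#' @param library_size_mean,library_size_cv Mean and coefficient of
#'   variation of lognormal per-sample library sizes; samples receive the
#'   size factor `library_size / library_size_mean`.
#' @param leukemic_lfc,genotype_lfc Absolute log2 fold-changes applied to
#'   responsive genes on each axis (sign drawn per gene).
#' @param n_leukemic_responsive,n_genotype_responsive Numbers of background
#'   (non-planted-set) genes responding to each factor.
#' @param planted_set_size Size of the planted informative gene set
#'   (default 655).
#' @param planted_set_responsive_frac Fraction of planted-set genes that
#'   respond on both axes.
#' @param seed Integer seed; identical configs give bit-identical datasets.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_counts()], [generate_gene_sets()]
#' @export
sim_config <- function(n_genes = 2000L,
                       n_per_group = 5L,
                       baseline_log_mean_mu = log(100),
                       baseline_log_mean_sd = 1.2,
                       dispersion = 0.1,
                       library_size_mean = 1e6,
                       library_size_cv = 0.1,
                       leukemic_lfc = 1.5,
                       genotype_lfc = 1.5,
                       n_leukemic_responsive = 400L,
                       n_genotype_responsive = 150L,
                       planted_set_size = 655L,
                       planted_set_responsive_frac = 0.3,
                       seed = 1L) {
  if (!is_count_scalar(n_genes)) stopf("n_genes must be a positive integer")
  if (!is_count_scalar(n_per_group)) stopf("n_per_group must be a positive integer")
  if (!is_number(baseline_log_mean_mu)) stopf("baseline_log_mean_mu must be a number")
  if (!is_number(baseline_log_mean_sd) || baseline_log_mean_sd < 0)
    stopf("baseline_log_mean_sd must be nonnegative")
  if (!is_number(dispersion) || dispersion <= 0)
    stopf("dispersion must be strictly positive")
  if (!is_number(library_size_mean) || library_size_mean <= 0)
    stopf("library_size_mean must be strictly positive")
  if (!is_number(library_size_cv) || library_size_cv < 0)
    stopf("library_size_cv must be nonnegative")
  if (!is_number(leukemic_lfc) || !is_number(genotype_lfc))
    stopf("fold-changes must be numbers")
  if (!is_count_scalar(n_leukemic_responsive, positive = FALSE) ||
      !is_count_scalar(n_genotype_responsive, positive = FALSE))
    stopf("responsive gene counts must be nonnegative integers")
  if (!is_count_scalar(planted_set_size)) stopf("planted_set_size must be a positive integer")
  if (planted_set_size > n_genes)
    stopf("planted_set_size (%d) exceeds n_genes (%d)", planted_set_size, n_genes)
  if (n_leukemic_responsive > n_genes - planted_set_size ||
      n_genotype_responsive > n_genes - planted_set_size)
    stopf("background responsive gene counts must fit outside the planted set")
  if (!is_number(planted_set_responsive_frac) ||
      planted_set_responsive_frac < 0 || planted_set_responsive_frac > 1)
    stopf("planted_set_responsive_frac must be in [0, 1]")
  if (!is_count_scalar(seed, positive = FALSE)) stopf("seed must be an integer")

  structure(list(
    n_genes = as.integer(n_genes), n_per_group = as.integer(n_per_group),
    baseline_log_mean_mu = baseline_log_mean_mu,
    baseline_log_mean_sd = baseline_log_mean_sd,
    dispersion = dispersion,
    library_size_mean = library_size_mean, library_size_cv = library_size_cv,
    leukemic_lfc = leukemic_lfc, genotype_lfc = genotype_lfc,
    n_leukemic_responsive = as.integer(n_leukemic_responsive),
    n_genotype_responsive = as.integer(n_genotype_responsive),
    planted_set_size = as.integer(planted_set_size),
    planted_set_responsive_frac = planted_set_responsive_frac,
    seed = as.integer(seed)
  ), class = "sim_config")
}

condition_levels <- c("wt", "KO", "CP", "BC")

#' Simulate a factorial RNA-seq dataset
#'
#' Draws negative-binomial counts for the 2x2 factorial design described in
#' [sim_config()].  Condition labels: `wt` (non-leukemic, wt genotype),
#' `KO` (non-leukemic, knockout), `CP` (chronic-phase leukemic, wt
#' genotype), `BC` (blast-crisis leukemic, knockout).  The leukemic effect
#' is applied to CML samples (CP and BC), the genotype effect to knockout
#' samples (KO and BC); effects act multiplicatively on the NB mean as
#' `2^lfc`.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_dataset`: a list with `counts` (integer
#'   gene-by-sample matrix), `annotation` (data.frame: `sample_id`,
#'   `leukemic`, `genotype`, `condition`), `gene_sets` (list holding the
#'   planted set), `truth` (per-gene data.frame of planted signed
#'   log2 fold-changes and membership flags) and the `config` used.
#' @examples
#' ds <- simulate_counts(sim_config(n_genes = 200, seed = 7))
#' dim(ds$counts)
#' table(ds$annotation$condition)
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) stopf("config must come from sim_config()")
  withr::with_seed(config$seed, simulate_counts_impl(config))
}

simulate_counts_impl <- function(config) {
  G <- config$n_genes
  n <- config$n_per_group
  S <- 4L * n

  annotation <- data.frame(
    sample_id = paste0(rep(condition_levels, each = n), "_", rep(seq_len(n), 4L)),
    leukemic  = factor(rep(c("nonCML", "nonCML", "CML", "CML"), each = n),
                       levels = c("nonCML", "CML")),
    genotype  = factor(rep(c("wt", "KO", "wt", "KO"), each = n),
                       levels = c("wt", "KO")),
    condition = factor(rep(condition_levels, each = n), levels = condition_levels),
    stringsAsFactors = FALSE
  )

  gene_ids <- sprintf("gene_%0*d", nchar(G), seq_len(G))

  baseline <- exp(stats::rnorm(G, config$baseline_log_mean_mu,
                               config$baseline_log_mean_sd))

  # planted set and its responsive members (effects on both axes, +-1 signs)
  planted <- sort(sample.int(G, config$planted_set_size))
  n_resp_planted <- round(config$planted_set_responsive_frac * config$planted_set_size)
  resp_planted <- sort(sample(planted, n_resp_planted))

  lfc_leu <- numeric(G)
  lfc_gen <- numeric(G)
  background <- setdiff(seq_len(G), planted)
  bg_leu <- sort(sample(background, config$n_leukemic_responsive))
  bg_gen <- sort(sample(background, config$n_genotype_responsive))
  sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
  lfc_leu[bg_leu] <- sgn(length(bg_leu)) * config$leukemic_lfc
  lfc_gen[bg_gen] <- sgn(length(bg_gen)) * config$genotype_lfc
  lfc_leu[resp_planted] <- sgn(length(resp_planted)) * config$leukemic_lfc
  lfc_gen[resp_planted] <- sgn(length(resp_planted)) * config$genotype_lfc

  # lognormal library sizes with the requested mean and CV
  sdlog <- sqrt(log(1 + config$library_size_cv^2))
  meanlog <- log(config$library_size_mean) - sdlog^2 / 2
  lib <- stats::rlnorm(S, meanlog, sdlog)
  size_factor <- lib / config$library_size_mean

  is_cml <- as.numeric(annotation$leukemic == "CML")
  is_ko <- as.numeric(annotation$genotype == "KO")
  log2_effect <- outer(lfc_leu, is_cml) + outer(lfc_gen, is_ko)
  mu <- baseline * 2^log2_effect
  mu <- sweep(mu, 2, size_factor, `*`)

  counts <- matrix(
    stats::rnbinom(G * S, mu = mu, size = 1 / config$dispersion),
    nrow = G, ncol = S, dimnames = list(gene_ids, annotation$sample_id)
  )

  truth <- data.frame(
    gene_id = gene_ids,
    in_planted_set = seq_len(G) %in% planted,
    leukemic_responsive = lfc_leu != 0,
    genotype_responsive = lfc_gen != 0,
    leukemic_lfc = lfc_leu,
    genotype_lfc = lfc_gen,
    baseline_mean = baseline,
    stringsAsFactors = FALSE
  )

  structure(list(
    counts = counts,
    annotation = annotation,
    gene_sets = list(planted = gene_ids[planted]),
    truth = truth,
    config = config
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d genes x %d samples (%d conditions x %d)\n",
              nrow(x$counts), ncol(x$counts), 4L, x$config$n_per_group))
  cat(sprintf("  planted set: %d genes (%d responsive); seed %d\n",
              length(x$gene_sets$planted),
              sum(x$truth$in_planted_set & x$truth$genotype_responsive),
              x$config$seed))
  invisible(x)
}

#' Build a gene-set collection of the planted set plus random decoys
#'
#' Decoy sets are sampled uniformly without replacement from the full gene
#' universe; they calibrate the null behaviour of the mutual-information
#' density comparison.
#'
#' @param dataset A `sim_dataset` from [simulate_counts()].
#' @param n_decoys Number of decoy sets (0 gives just the planted set).
#' @param decoy_size Genes per decoy; defaults to the planted-set size.
#' @param seed Integer seed for the decoy draws.
#' @return Named list of character vectors of gene ids
#'   (`planted`, `decoy_01`, ...).
#' @export
generate_gene_sets <- function(dataset, n_decoys = 10L, decoy_size = NULL,
                               seed = 1L) {
  if (!inherits(dataset, "sim_dataset")) stopf("dataset must be a sim_dataset")
  if (!is_count_scalar(n_decoys, positive = FALSE))
    stopf("n_decoys must be a nonnegative integer")
  universe <- rownames(dataset$counts)
  if (is.null(decoy_size)) decoy_size <- length(dataset$gene_sets$planted)
  if (!is_count_scalar(decoy_size)) stopf("decoy_size must be a positive integer")
  if (decoy_size > length(universe))
    stopf("decoy_size (%d) exceeds the gene universe (%d)",
          decoy_size, length(universe))
  sets <- dataset$gene_sets["planted"]
  if (n_decoys > 0) {
    decoys <- withr::with_seed(seed, lapply(seq_len(n_decoys), function(i)
      sort(sample(universe, decoy_size))))
    names(decoys) <- sprintf("decoy_%02d", seq_len(n_decoys))
    sets <- c(sets, decoys)
  }
  sets
}
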