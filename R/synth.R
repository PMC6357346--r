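#' Configuration for the paired expression/methylation simulator
#'
#' Defines the study conditions for a synthetic two-group (tumor/normal)
#' cohort with paired gene expression and promoter CpG methylation, planted
#' differentially expressed genes (DEGs), differentially methylated genes
#' (DMGs), a joint DEG-and-DMG subset, and a biomarker panel drawn from the
#' joint subset.
#'
#' Defaults describe a moderately sized two-arm design: 30 tumor and 30
#' normal samples, 300 genes with on average 3 promoter CpGs each, 10%
#' planted DEGs and DMGs with half of each overlapping (5% joint), a 3 log2
#' unit expression shift over noise with SD 0.5, and a 0.4 beta shift --
#' strong, clearly detectable signal of the kind a tumor-versus-normal
#' contrast on bulk data exhibits for its top markers.
#'
#' @param n_tumor,n_normal samples per class.
#' @param n_genes number of genes.
#' @param cpgs_per_promoter mean promoter CpGs per gene (>= 1); per-gene
#'   counts are `1 + Poisson(cpgs_per_promoter - 1)`.
#' @param frac_deg,frac_dmg fractions of genes planted as DEG / DMG.
#' @param frac_joint fraction planted as both (must not exceed either).
#' @param expr_effect mean log2 expression shift for planted DEGs; sign is
#'   random per gene.
#' @param meth_effect beta-value shift for planted DMG promoters, in
#'   (0.1, 0.5]; values above 0.1 keep planted loci beyond the delta-beta
#'   call threshold in expectation.
#' @param expr_noise_sd SD of log2 expression noise.
#' @param meth_concentration precision of the Beta noise around group means
#'   (shape1 + shape2); larger is less noisy.
#' @param n_biomarkers biomarker genes planted (drawn from the joint set).
#' @param frac_decoy fraction of extra CpG loci placed outside any promoter,
#'   to exercise the interval-mapping filter.
#' @param seed master seed; per-data-type streams (annotation, expression,
#'   methylation) are derived from it so runs are bit-reproducible.
#' @return A `synth_config` list, validated.
#' @seealso [simulate_dataset()]
#' @export
synth_config <- function(n_tumor = 30L, n_normal = 30L, n_genes = 300L,
                         cpgs_per_promoter = 3, frac_deg = 0.1,
                         frac_dmg = 0.1, frac_joint = 0.05,
                         expr_effect = 3, meth_effect = 0.4,
                         expr_noise_sd = 0.5, meth_concentration = 50,
                         n_biomarkers = 6L, frac_decoy = 0.2, seed = 1L) {
  cfg <- list(n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
              n_genes = as.integer(n_genes),
              cpgs_per_promoter = cpgs_per_promoter, frac_deg = frac_deg,
              frac_dmg = frac_dmg, frac_joint = frac_joint,
              expr_effect = expr_effect, meth_effect = meth_effect,
              expr_noise_sd = expr_noise_sd,
              meth_concentration = meth_concentration,
              n_biomarkers = as.integer(n_biomarkers),
              frac_decoy = frac_decoy, seed = as.integer(seed))
  for (f in c("frac_deg", "frac_dmg", "frac_joint", "frac_decoy"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("invalid configuration: '", f, "' must lie in [0,1], got ", cfg[[f]])
  if (cfg$frac_joint > min(cfg$frac_deg, cfg$frac_dmg))
    stop("invalid configuration: 'frac_joint' exceeds frac_deg or frac_dmg")
  if (cfg$frac_deg + cfg$frac_dmg - cfg$frac_joint > 1)
    stop("invalid configuration: frac_deg + frac_dmg - frac_joint > 1")
  if (cfg$cpgs_per_promoter < 1)
    stop("invalid configuration: 'cpgs_per_promoter' must be >= 1")
  if (cfg$meth_effect <= 0 || cfg$meth_effect > 0.5)
    stop("invalid configuration: 'meth_effect' must lie in (0, 0.5], got ",
         cfg$meth_effect)
  if (cfg$n_tumor < 2L || cfg$n_normal < 2L)
    stop("invalid configuration: need >= 2 samples per class")
  n_joint <- round(cfg$frac_joint * cfg$n_genes)
  if (cfg$n_biomarkers > n_joint)
    stop("invalid configuration: 'n_biomarkers' (", cfg$n_biomarkers,
         ") exceeds the number of joint DEG/DMG genes (", n_joint, ")")
  class(cfg) <- "synth_config"
  cfg
}

# independent sub-seed per data-type stream, kept within 32-bit range
stream_seed <- function(seed, k) as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)

#' Simulate a paired expression/methylation cohort with known truth
#'
#' Generates log2-scale expression (normals at per-gene baselines plus
#' Gaussian noise, tumors additionally shifted by `expr_effect` with random
#' sign for planted DEGs), Beta-distributed promoter CpG methylation
#' (group-specific means; planted DMGs shift a random non-empty subset of
#' their promoter CpGs by `meth_effect` with random direction per gene), a
#' TSS annotation with strand, and decoy CpGs outside all promoters.
#' Biomarker genes are planted as true joint signal (always a subset of the
#' joint DEG-and-DMG genes).
#'
#' @param config a [synth_config()].
#' @return A list of class `fuzzsig_sim` with elements
#'   \describe{
#'     \item{expression}{[omics_matrix()] of log2 expression, genes x samples}
#'     \item{methylation}{[omics_matrix()] of beta values, CpG loci x samples}
#'     \item{annotation}{gene TSS data.frame (see [read_annotation()])}
#'     \item{loci}{CpG coordinate data.frame: `locus`, `chrom`, `pos`}
#'     \item{truth}{list: `deg_genes`, `dmg_genes`, `biomarker_genes`,
#'       `locus_gene_map` (named character: promoter CpG id -> gene)}
#'   }
#' @examples
#' sim <- simulate_dataset(synth_config(n_genes = 50, n_biomarkers = 2, seed = 3))
#' sim$expression
#' length(sim$truth$deg_genes)
#' @export
simulate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  n <- cfg$n_tumor + cfg$n_normal
  samples <- c(sprintf("T%03d", seq_len(cfg$n_tumor)),
               sprintf("N%03d", seq_len(cfg$n_normal)))
  labels <- stats::setNames(rep(c("tumor", "normal"),
                                c(cfg$n_tumor, cfg$n_normal)), samples)
  tum <- seq_len(cfg$n_tumor)

  n_deg <- round(cfg$frac_deg * cfg$n_genes)
  n_dmg <- round(cfg$frac_dmg * cfg$n_genes)
  n_joint <- round(cfg$frac_joint * cfg$n_genes)

  ## -- annotation stream: planted sets, gene coordinates, CpG placement ----
  set.seed(stream_seed(cfg$seed, 1L))
  planted <- sample(genes, n_deg + n_dmg - n_joint)
  deg_genes <- planted[seq_len(n_deg)]
  # joint genes are the first n_joint of the DEG draw; DMG-only fill the rest
  dmg_genes <- c(planted[seq_len(n_joint)],
                 planted[seq_len(n_dmg - n_joint) + n_deg])
  joint <- planted[seq_len(n_joint)]
  biomarkers <- if (cfg$n_biomarkers > 0L) sample(joint, cfg$n_biomarkers) else character()

  gene_space <- 100000L
  ann <- data.frame(gene = genes, chrom = "chr1",
                    tss = 10000L + gene_space * (seq_len(cfg$n_genes) - 1L),
                    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
                    stringsAsFactors = FALSE)

  k_cpg <- 1L + stats::rpois(cfg$n_genes, cfg$cpgs_per_promoter - 1)
  lo <- ifelse(ann$strand == "+", ann$tss - 1500L, ann$tss - 500L)
  hi <- ifelse(ann$strand == "+", ann$tss + 500L, ann$tss + 1500L)
  cpg_gene <- rep(genes, k_cpg)
  cpg_pos <- unlist(lapply(seq_len(cfg$n_genes), function(i)
    sort(sample(seq(lo[i], hi[i]), k_cpg[i]))))
  n_decoy <- round(cfg$frac_decoy * sum(k_cpg))
  # decoys sit mid-intergenic, far outside every +/-1500 bp promoter window
  decoy_pos <- if (n_decoy > 0L)
    sample(ann$tss, n_decoy, replace = TRUE) + 50000L else integer()
  loci <- data.frame(
    locus = sprintf("cg%06d", seq_len(sum(k_cpg) + n_decoy)),
    chrom = "chr1", pos = c(cpg_pos, decoy_pos), stringsAsFactors = FALSE)
  locus_gene_map <- stats::setNames(cpg_gene, loci$locus[seq_along(cpg_gene)])

  ## -- expression stream ---------------------------------------------------
  set.seed(stream_seed(cfg$seed, 2L))
  baseline <- stats::runif(cfg$n_genes, 4, 10)
  sign_g <- stats::setNames(sample(c(-1, 1), cfg$n_genes, replace = TRUE), genes)
  expr <- baseline + matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$expr_noise_sd),
                            cfg$n_genes, n)
  dimnames(expr) <- list(genes, samples)
  is_deg <- genes %in% deg_genes
  # effect added after all draws so changing its size leaves the noise intact
  expr[is_deg, tum] <- expr[is_deg, tum] + cfg$expr_effect * sign_g[is_deg]
  expr[expr < 0] <- 0  # log2(x + 1) of counts is non-negative

  ## -- methylation stream --------------------------------------------------
  set.seed(stream_seed(cfg$seed, 3L))
  n_loci <- nrow(loci)
  base_mu <- stats::runif(n_loci, 0.15, 0.85)
  tumor_mu <- base_mu
  dir_g <- stats::setNames(sample(c(-1, 1), cfg$n_genes, replace = TRUE), genes)
  shifted <- logical(n_loci)
  for (g in dmg_genes) {
    idx <- which(cpg_gene == g)
    pick <- idx[stats::runif(length(idx)) < 0.75]
    if (!length(pick)) pick <- idx[sample.int(length(idx), 1L)]
    shifted[pick] <- TRUE
    d <- dir_g[g]
    # re-anchor the base mean so mean +/- effect stays inside (0.05, 0.95)
    room <- 0.95 - cfg$meth_effect - 0.05
    base_mu[pick] <- 0.05 + stats::runif(length(pick)) * room +
      (if (d < 0) cfg$meth_effect else 0)
    tumor_mu[pick] <- base_mu[pick] + d * cfg$meth_effect
  }
  phi <- cfg$meth_concentration
  rbeta_mu <- function(mu) {
    mu <- pmin(pmax(mu, 0.01), 0.99)
    stats::rbeta(length(mu), mu * phi, (1 - mu) * phi)
  }
  meth <- matrix(0, n_loci, n, dimnames = list(loci$locus, samples))
  for (j in seq_len(n))
    meth[, j] <- rbeta_mu(if (j <= cfg$n_tumor) tumor_mu else base_mu)

  structure(list(
    expression = omics_matrix(expr, labels, "expression"),
    methylation = omics_matrix(meth, labels, "methylation"),
    annotation = ann, loci = loci,
    truth = list(deg_genes = deg_genes, dmg_genes = dmg_genes,
                 biomarker_genes = biomarkers,
                 locus_gene_map = locus_gene_map),
    config = cfg), class = "fuzzsig_sim")
}

#' @export
print.fuzzsig_sim <- function(x, ...) {
  cat(sprintf(paste0("fuzzsig_sim: %d genes x %d samples; %d CpG loci ",
                     "(%d promoter, %d decoy)\n  planted: %d DEG, %d DMG ",
                     "(%d joint), %d biomarkers; seed %d\n"),
              nrow(x$expression$values), ncol(x$expression$values),
              nrow(x$methylation$values), length(x$truth$locus_gene_map),
              nrow(x$loci) - length(x$truth$locus_gene_map),
              length(x$truth$deg_genes), length(x$truth$dmg_genes),
              length(intersect(x$truth$deg_genes, x$truth$dmg_genes)),
              length(x$truth$biomarker_genes), x$config$seed))
  invisible(x)
}

#' Simulate an external validation cohort
#'
#' Generates an expression-only cohort over the same gene universe as an
#' internal simulation, in which only a designated subset of genes (by
#' default the internally planted joint DEG-and-DMG genes, which include the
#' biomarkers) keeps its differential signal; all other internally planted
#' DEGs are null here. A global location/scale batch distortion is applied so
#' that [quantile_normalize()] has real work to do. This emulates the
#' common situation where many expression-only markers fail to transfer
#' across cohorts while jointly methylation-supported markers persist.
#'
#' @param sim an internal [simulate_dataset()] result.
#' @param stable_genes genes whose differential signal persists externally;
#'   default: the internal joint DEG-and-DMG genes.
#' @param n_tumor,n_normal external cohort size per class.
#' @param batch_shift,batch_scale location/scale distortion applied to the
#'   whole external matrix.
#' @param seed RNG seed for the external cohort.
#' @return A list of class `fuzzsig_sim` with `expression` and `truth`
#'   components (no methylation).
#' @export
simulate_external <- function(sim,
                              stable_genes = intersect(sim$truth$deg_genes,
                                                       sim$truth$dmg_genes),
                              n_tumor = 30L, n_normal = 30L,
                              batch_shift = 2, batch_scale = 1.3,
                              seed = sim$config$seed + 1L) {
  stopifnot(inherits(sim, "fuzzsig_sim"))
  cfg <- sim$config
  genes <- rownames(sim$expression$values)
  n <- n_tumor + n_normal
  samples <- c(sprintf("ET%03d", seq_len(n_tumor)),
               sprintf("EN%03d", seq_len(n_normal)))
  labels <- stats::setNames(rep(c("tumor", "normal"), c(n_tumor, n_normal)),
                            samples)
  set.seed(stream_seed(cfg$seed, 2L))          # replay per-gene params
  baseline <- stats::runif(cfg$n_genes, 4, 10)
  sign_g <- stats::setNames(sample(c(-1, 1), cfg$n_genes, replace = TRUE), genes)
  set.seed(stream_seed(seed, 4L))
  expr <- baseline + matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$expr_noise_sd),
                            cfg$n_genes, n)
  dimnames(expr) <- list(genes, samples)
  keep <- genes %in% stable_genes
  expr[keep, seq_len(n_tumor)] <- expr[keep, seq_len(n_tumor)] +
    cfg$expr_effect * sign_g[keep]
  expr <- expr * batch_scale + batch_shift
  expr[expr < 0] <- 0
  structure(list(expression = omics_matrix(expr, labels, "expression"),
                 truth = list(deg_genes = intersect(genes[keep],
                                                    sim$truth$deg_genes)),
                 config = cfg),
            class = "fuzzsig_sim")
}

#' Derive "original array" and "expanded" views of a methylation matrix
#'
#' The expanded methylation profile covers many more CpG loci than the
#' original array but with imputation noise; the original array is a sparse
#' subsample with clean values. This helper derives both views from one
#' simulated matrix: `original` keeps a random fraction of loci unchanged,
#' `expanded` keeps all loci and perturbs each with Gaussian noise (clamped
#' to \[0, 1\]), emulating imperfect imputation.
#'
#' @param methylation an [omics_matrix()] of beta values.
#' @param frac_original fraction of loci on the "original" array (default
#'   1/18, the coverage ratio of a 450K array relative to an expanded
#'   profile).
#' @param expanded_noise_sd SD of the imputation noise on the expanded view.
#' @param seed RNG seed.
#' @return list with `original` and `expanded` omics matrices.
#' @export
methylation_views <- function(methylation, frac_original = 1 / 18,
                              expanded_noise_sd = 0.05, seed = 1L) {
  stopifnot(inherits(methylation, "omics_matrix"),
            methylation$type == "methylation")
  v <- methylation$values
  set.seed(stream_seed(seed, 5L))
  keep <- sort(sample.int(nrow(v), max(2L, round(frac_original * nrow(v)))))
  original <- omics_matrix(v[keep, , drop = FALSE], methylation$labels,
                           "methylation")
  noisy <- v + matrix(stats::rnorm(length(v), 0, expanded_noise_sd),
                      nrow(v), ncol(v))
  noisy <- pmin(pmax(noisy, 0), 1)
  expanded <- omics_matrix(noisy, methylation$labels, "methylation")
  list(original = original, expanded = expanded)
}

#' Write a simulated dataset to disk in the package's file formats
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly. Files: `expression.tsv`, `methylation.tsv`,
#'   `annotation.tsv`, `loci.tsv`, `labels.tsv`, `truth.json`.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "fuzzsig_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(sim$expression, file.path(dir, "expression.tsv"))
  if (!is.null(sim$methylation))
    write_matrix(sim$methylation, file.path(dir, "methylation.tsv"))
  write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  if (!is.null(sim$loci))
    utils::write.table(sim$loci, file.path(dir, "loci.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_labels(sim$expression$labels, file.path(dir, "labels.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
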