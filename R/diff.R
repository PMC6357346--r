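#' Log2-transform an expression matrix
#'
#' @param expression an [omics_matrix()] with non-negative values (e.g. raw
#'   counts or normalized abundances).
#' @param pseudocount added before taking log2 (default 1).
#' @return An `omics_matrix` with values `log2(v + pseudocount)`.
#' @examples
#' m <- matrix(c(0, 7, 1023, 3), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' om <- omics_matrix(m, c(s1 = "tumor", s2 = "normal"))
#' log2_transform(om)$values
#' @export
log2_transform <- function(expression, pseudocount = 1) {
  stopifnot(inherits(expression, "omics_matrix"))
  v <- expression$values
  if (any(v < 0)) {
    idx <- which(v < 0, arr.ind = TRUE)[1L, ]
    stop("negative expression value at feature '", rownames(v)[idx[1L]],
         "', sample '", colnames(v)[idx[2L]], "'")
  }
  omics_matrix(log2(v + pseudocount), expression$labels, expression$type)
}

# Vectorised per-row Welch t-test. Rows with zero variance in both groups
# get p = 1 by convention (no evidence either way); tested against t.test.
row_welch <- function(values, tumor_idx, normal_idx) {
  n1 <- length(tumor_idx); n2 <- length(normal_idx)
  x1 <- values[, tumor_idx, drop = FALSE]
  x2 <- values[, normal_idx, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  p[degenerate] <- 1
  tstat[degenerate] <- 0
  data.frame(mean_tumor = m1, mean_normal = m2, diff = m1 - m2,
             t = tstat, df = df, p = p, row.names = rownames(values))
}

#' Call differentially expressed genes
#'
#' Per-gene Welch two-sample t-test of tumor versus normal on log2-scale
#' expression, with multiple-testing adjustment across all genes. A gene is
#' flagged as DEG when its absolute mean log2 difference exceeds
#' `lfc_threshold` (default 1, i.e. two-fold) and its adjusted p-value is
#' below `p_threshold` (default 0.01). Genes with zero variance in both
#' groups receive p = 1 by convention.
#'
#' @param log_expression an [omics_matrix()] on the log2 scale with >= 2
#'   samples in each class.
#' @param lfc_threshold minimum |mean log2 difference|.
#' @param p_threshold adjusted-p cutoff.
#' @param p_adjust_method `"BH"` (default) or any [stats::p.adjust()] method.
#' @return A data.frame with one row per gene: `gene`, `mean_tumor`,
#'   `mean_normal`, `log2fc`, `p`, `p_adj`, `is_deg`.
#' @export
call_deg <- function(log_expression, lfc_threshold = 1, p_threshold = 0.01,
                     p_adjust_method = "BH") {
  stopifnot(inherits(log_expression, "omics_matrix"))
  cls <- split_classes(log_expression, min_per_class = 2L)
  w <- row_welch(log_expression$values, cls$tumor, cls$normal)
  p_adj <- stats::p.adjust(w$p, method = p_adjust_method)
  data.frame(gene = rownames(w), mean_tumor = w$mean_tumor,
             mean_normal = w$mean_normal, log2fc = w$diff, p = w$p,
             p_adj = p_adj,
             is_deg = abs(w$diff) > lfc_threshold & p_adj < p_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differentially methylated loci
#'
#' Per-locus Welch t-test of tumor versus normal beta values. A locus is a
#' DML when its adjusted p-value is below `p_threshold` and its absolute
#' tumor-minus-normal mean beta difference exceeds `delta_beta` (default
#' 0.1).
#'
#' @param methylation an [omics_matrix()] of beta values with >= 2 samples
#'   per class.
#' @param delta_beta minimum |mean beta difference|.
#' @inheritParams call_deg
#' @return A data.frame with one row per locus: `locus`, `mean_tumor`,
#'   `mean_normal`, `delta_beta`, `p`, `p_adj`, `is_dml`.
#' @export
call_dml <- function(methylation, delta_beta = 0.1, p_threshold = 0.01,
                     p_adjust_method = "BH") {
  stopifnot(inherits(methylation, "omics_matrix"))
  cls <- split_classes(methylation, min_per_class = 2L)
  w <- row_welch(methylation$values, cls$tumor, cls$normal)
  p_adj <- stats::p.adjust(w$p, method = p_adjust_method)
  data.frame(locus = rownames(w), mean_tumor = w$mean_tumor,
             mean_normal = w$mean_normal, delta_beta = w$diff, p = w$p,
             p_adj = p_adj,
             is_dml = p_adj < p_threshold & abs(w$diff) > delta_beta,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Map CpG loci to gene promoter windows
#'
#' The promoter of a gene is the interval from `upstream` bases 5' of the TSS
#' to `downstream` bases 3' of it, inclusive at both ends: on the + strand
#' `[tss - upstream, tss + downstream]`, reflected about the TSS on the -
#' strand (`[tss - downstream, tss + upstream]`). A locus may fall in several
#' overlapping promoters and then contributes to each gene independently.
#'
#' @param annotation gene TSS data.frame (see [read_annotation()]).
#' @param loci data.frame with columns `locus`, `chrom`, `pos` (1-based).
#' @param upstream,downstream window half-widths in bases (defaults 1500/500).
#' @param strand_aware if `FALSE`, every gene uses the + strand window
#'   regardless of annotated strand.
#' @return Named list: gene symbol -> character vector of locus ids (genes
#'   with no promoter locus are omitted).
#' @export
map_promoter_loci <- function(annotation, loci, upstream = 1500,
                              downstream = 500, strand_aware = TRUE) {
  validate_annotation(annotation)
  if (nrow(annotation) == 0L || nrow(loci) == 0L) return(stats::setNames(list(), character()))
  strand <- if (strand_aware) annotation$strand else rep("+", nrow(annotation))
  tss <- GenomicRanges::GRanges(annotation$chrom,
                                IRanges::IRanges(annotation$tss, width = 1L),
                                strand = strand)
  # width upstream + downstream + 1 so both window ends are inclusive
  prom <- GenomicRanges::promoters(tss, upstream = upstream,
                                   downstream = downstream + 1L)
  cpg <- GenomicRanges::GRanges(loci$chrom,
                                IRanges::IRanges(loci$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(cpg, prom, ignore.strand = TRUE)
  if (!length(hits)) return(stats::setNames(list(), character()))
  g <- annotation$gene[S4Vectors::subjectHits(hits)]
  l <- loci$locus[S4Vectors::queryHits(hits)]
  split(l, factor(g, levels = unique(g)))
}

#' Fisher's combined probability test
#'
#' Combines k independent p-values into one: the statistic `-2 * sum(log p)`
#' is compared to the upper tail of a chi-squared distribution with 2k
#' degrees of freedom. Zero p-values are clamped to 1e-300 (with a warning)
#' to keep the statistic finite.
#'
#' @param pvalues numeric vector of p-values in (0, 1]; must be non-empty.
#' @return list with `stat` (chi-squared statistic), `df` (2k) and `p`
#'   (combined p-value).
#' @examples
#' fisher_combine(c(0.01, 0.04))
#' fisher_combine(0.05)$p  # single p is returned unchanged
#' @export
fisher_combine <- function(pvalues) {
  if (!length(pvalues)) stop("fisher_combine: empty p-value list")
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1))
    stop("fisher_combine: p-values must lie in [0, 1]")
  if (any(pvalues == 0)) {
    warning("p-value of 0 clamped to 1e-300")
    pvalues[pvalues == 0] <- 1e-300
  }
  stat <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Call differentially methylated genes
#'
#' A gene is considered when its promoter window contains at least one tested
#' CpG locus. The raw per-locus p-values of all its promoter loci (or, with
#' `combine = "dml_only"`, only its DML loci) are aggregated with
#' [fisher_combine()]; q-values are computed by multiple-testing adjustment
#' over the genes that carry at least one DML, and a gene is a DMG when it
#' has >= 1 promoter DML and q below `q_threshold`. Basing the combination
#' on all promoter loci makes the gene-level call robust to error at any
#' single locus, while the DML gate keeps genes without a clearly shifted
#' locus out.
#'
#' @param dml a [call_dml()] result.
#' @param promoter_map gene -> locus-id list from [map_promoter_loci()].
#' @param q_threshold q-value cutoff (default 0.01).
#' @param combine `"all_loci"` (default) or `"dml_only"`.
#' @param p_adjust_method adjustment across genes, default `"BH"`.
#' @return A data.frame with one row per gene with >= 1 mapped locus:
#'   `gene`, `n_promoter_loci`, `n_dml`, `fisher_stat`, `fisher_p`, `q`,
#'   `is_dmg`. `q` is `NA` for genes with no DML (they are never DMGs).
#' @export
call_dmg <- function(dml, promoter_map, q_threshold = 0.01,
                     combine = c("all_loci", "dml_only"),
                     p_adjust_method = "BH") {
  combine <- match.arg(combine)
  if (!length(promoter_map)) stop("empty promoter map")
  p_by_locus <- stats::setNames(dml$p, dml$locus)
  dml_by_locus <- stats::setNames(dml$is_dml, dml$locus)
  genes <- names(promoter_map)
  rows <- lapply(genes, function(g) {
    ids <- intersect(promoter_map[[g]], dml$locus)
    if (!length(ids)) return(NULL)
    n_dml <- sum(dml_by_locus[ids])
    use <- if (combine == "dml_only" && n_dml > 0L)
      ids[dml_by_locus[ids]] else ids
    fc <- fisher_combine(p_by_locus[use])
    data.frame(gene = g, n_promoter_loci = length(ids), n_dml = n_dml,
               fisher_stat = fc$stat, fisher_p = fc$p,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stop("no promoter locus appears in the DML table")
  gated <- rows$n_dml >= 1L
  rows$q <- NA_real_
  rows$q[gated] <- stats::p.adjust(rows$fisher_p[gated],
                                   method = p_adjust_method)
  rows$is_dmg <- gated & !is.na(rows$q) & rows$q < q_threshold
  rownames(rows) <- NULL
  rows
}
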