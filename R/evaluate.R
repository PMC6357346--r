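#' Seeded stratified fold assignment
#'
#' Assigns every sample to one of `k` folds so that class proportions are
#' preserved as closely as possible. With `k` equal to the sample count this
#' degenerates to leave-one-out.
#'
#' @param labels named character vector of `"tumor"`/`"normal"` labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`, named by sample, in the
#'   order of `labels`. Test folds partition the samples.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  n <- length(labels)
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
  fold <- integer(n)
  set.seed(seed)
  # cycle fold ids across classes so folds stay balanced overall and
  # k = n degenerates to leave-one-out
  nxt <- sample.int(k, 1L) - 1L
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- (nxt + seq_along(idx) - 1L) %% k + 1L
    nxt <- nxt + length(idx)
  }
  stats::setNames(fold, names(labels))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen tumor sample scores above a
#' randomly chosen normal sample, with ties counted one half.
#'
#' @param scores numeric scores (larger = more tumor-like).
#' @param labels `"tumor"`/`"normal"` per score.
#' @return AUC in \[0, 1\].
#' @examples
#' compute_auc(c(1, 2, 3, 4), c("normal", "tumor", "normal", "tumor"))  # 0.75
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.character(labels)
  nt <- sum(labels == "tumor"); nn <- sum(labels == "normal")
  if (nt == 0L || nn == 0L)
    stop("AUC needs both classes; got ", nt, " tumor / ", nn, " normal")
  r <- rank(scores)  # midranks handle ties as half-wins
  (sum(r[labels == "tumor"]) - nt * (nt + 1) / 2) / (nt * nn)
}

#' Quantile-normalize an external matrix against a reference
#'
#' Forces every external sample's value distribution onto the reference
#' pool: genes present in both matrices are retained, a reference quantile
#' vector of that length is taken from the pooled reference values, and each
#' external sample's k-th smallest value is replaced by the k-th reference
#' quantile (ties receive the mean of the quantiles they span). Used to
#' put an external cohort on the scale of the training data before
#' prediction. Idempotent against a fixed reference.
#'
#' @param external an [omics_matrix()] to normalize.
#' @param reference an [omics_matrix()] supplying the target distribution.
#' @return An `omics_matrix` over the shared genes.
#' @export
quantile_normalize <- function(external, reference) {
  stopifnot(inherits(external, "omics_matrix"),
            inherits(reference, "omics_matrix"))
  shared <- intersect(rownames(external$values), rownames(reference$values))
  if (length(shared) < 2L)
    stop("need at least 2 shared genes, got ", length(shared))
  x <- external$values[shared, , drop = FALSE]
  pool <- sort(as.vector(reference$values[shared, , drop = FALSE]))
  n <- length(shared)
  # n evenly spaced quantiles of the pooled reference distribution;
  # type 5 makes the (k - 0.5)/n quantiles of an n-vector the vector itself
  ref_q <- stats::quantile(pool, probs = (seq_len(n) - 0.5) / n,
                           names = FALSE, type = 5)
  out <- apply(x, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    (ref_q[floor(r)] + ref_q[ceiling(r)]) / 2
  })
  rownames(out) <- shared
  omics_matrix(out, external$labels, external$type)
}

#' Cross-validate the full signature-selection + fuzzy-classification pipeline
#'
#' Stratified k-fold cross-validation in which, by default, every stage of
#' the pipeline -- DEG calling, DML/DMG calling, candidate intersection,
#' biomarker-weighted elastic-net selection and fuzzy-rule induction -- runs
#' on the training folds only; the held-out fold is only ever touched by
#' [predict.fuzzy_rulebase()]. `selection = "global"` instead selects the
#' signature once on all samples before splitting (the optimistic variant,
#' kept for comparison).
#'
#' @param expression log2-scale [omics_matrix()].
#' @param methylation beta-value [omics_matrix()] (the view the variant
#'   needs: original or expanded); `NULL` for the `bio`/`exp` variants.
#' @param annotation gene TSS data.frame.
#' @param loci CpG coordinate data.frame (`locus`, `chrom`, `pos`).
#' @param panel [biomarker_panel()] or `NULL`.
#' @param variant model variant, see [variant_features()].
#' @param k number of folds (default 10); shrunk with a warning when a class
#'   has fewer than `k` samples.
#' @param seed integer seed for fold assignment and the internal elastic-net
#'   CV.
#' @param selection `"in_fold"` (default) or `"global"`.
#' @param ... tuning parameters passed to [fuzzsig()] /
#'   [select_signature()] (e.g. `alpha`, `biomarker_penalty`).
#' @return Object of class `fuzzsig_eval`: list with `variant`, `per_fold`
#'   (data.frame: fold, n_test, accuracy, auc, n_signature),
#'   `mean_accuracy`, `mean_auc`, `seed`, `folds`.
#' @export
cross_validate <- function(expression, methylation = NULL, annotation = NULL,
                           loci = NULL, panel = NULL,
                           variant = "bio_exp_emeth", k = 10L, seed = 1L,
                           selection = c("in_fold", "global"), ...) {
  selection <- match.arg(selection)
  labels <- expression$labels
  min_class <- min(table(labels))
  if (min_class < k) {
    warning("class with ", min_class, " samples < k = ", k,
            "; shrinking k to ", min_class)
    k <- min_class
  }
  folds <- stratified_folds(labels, k = k, seed = seed)
  global_model <- if (selection == "global")
    fuzzsig(expression, methylation, annotation, loci, panel,
            variant = variant, seed = seed, ...) else NULL
  per_fold <- lapply(seq_len(k), function(f) {
    test_ids <- names(folds)[folds == f]
    train_ids <- names(folds)[folds != f]
    model <- if (selection == "global") {
      refit_fuzzsig(global_model, subset_omics(expression, samples = train_ids))
    } else {
      fuzzsig(subset_omics(expression, samples = train_ids),
              if (!is.null(methylation)) subset_omics(methylation, samples = train_ids),
              annotation, loci, panel, variant = variant, seed = seed, ...)
    }
    test <- subset_omics(expression, samples = test_ids)
    pred <- predict(model, test, type = "full")
    truth <- labels[test_ids]
    data.frame(fold = f, n_test = length(test_ids),
               accuracy = mean(pred$class == truth),
               auc = compute_auc(pred$score, truth),
               n_signature = length(model$signature$genes))
  })
  per_fold <- do.call(rbind, per_fold)
  structure(list(variant = variant, per_fold = per_fold,
                 mean_accuracy = mean(per_fold$accuracy),
                 mean_auc = mean(per_fold$auc), seed = seed, k = k,
                 folds = folds),
            class = "fuzzsig_eval")
}

#' @export
print.fuzzsig_eval <- function(x, ...) {
  cat(sprintf("fuzzsig_eval [%s]: %d-fold CV (seed %d)\n", x$variant, x$k,
              x$seed))
  cat(sprintf("  mean accuracy %.3f, mean AUC %.3f\n", x$mean_accuracy,
              x$mean_auc))
  invisible(x)
}

#' @export
summary.fuzzsig_eval <- function(object, ...) {
  print(object)
  print(object$per_fold, row.names = FALSE)
  invisible(object)
}

#' Plot per-fold accuracy and AUC
#'
#' @param x a [cross_validate()] result.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.fuzzsig_eval <- function(x, ...) {
  graphics::matplot(x$per_fold$fold,
                    cbind(x$per_fold$accuracy, x$per_fold$auc),
                    type = "b", pch = c(1, 2), lty = 1, ylim = c(0, 1),
                    xlab = "fold", ylab = "performance", ...)
  graphics::legend("bottomright", c("accuracy", "AUC"), pch = c(1, 2),
                   col = 1:2, bty = "n")
  invisible(x)
}

#' Compare model variants internally and on an external cohort
#'
#' Runs [cross_validate()] for each requested variant on the same seeded
#' folds, then trains each variant on the full internal cohort and evaluates
#' it on an external expression cohort that is first passed through
#' [quantile_normalize()] against the internal data -- the
#' internal-CV-versus-external-validation design used to probe signature
#' robustness.
#'
#' @param sim internal dataset: a [simulate_dataset()] result (or any list
#'   with `expression`, `annotation`, `loci` components).
#' @param external external cohort with an `expression` omics matrix (e.g.
#'   [simulate_external()]).
#' @param panel [biomarker_panel()].
#' @param meth_views list with `original` and `expanded` methylation
#'   matrices, e.g. [methylation_views()]; defaults to building one from
#'   `sim$methylation`.
#' @param variants variants to run (default: all five).
#' @param k,seed CV settings shared across variants.
#' @param ... passed through to [cross_validate()].
#' @return A list of class `fuzzsig_comparison`: `reports` (per-variant
#'   `fuzzsig_eval`), `external` (data.frame: variant, accuracy, auc,
#'   n_signature), `ranking` (data.frame sorted by external accuracy).
#' @export
compare_variants <- function(sim, external, panel,
                             meth_views = methylation_views(sim$methylation,
                                                            seed = seed),
                             variants = c("bio", "exp", "exp_meth",
                                          "bio_exp_meth", "bio_exp_emeth"),
                             k = 10L, seed = 1L, ...) {
  meth_for <- function(v) switch(v,
    bio = NULL, exp = NULL,
    exp_meth = meth_views$original, bio_exp_meth = meth_views$original,
    bio_exp_emeth = meth_views$expanded)
  reports <- list()
  external_rows <- list()
  for (v in variants) {
    reports[[v]] <- cross_validate(sim$expression, meth_for(v),
                                   sim$annotation, sim$loci, panel,
                                   variant = v, k = k, seed = seed, ...)
    model <- fuzzsig(sim$expression, meth_for(v), sim$annotation, sim$loci,
                     panel, variant = v, seed = seed, ...)
    ext <- quantile_normalize(external$expression, sim$expression)
    pred <- predict(model, ext, type = "full")
    truth <- ext$labels
    external_rows[[v]] <- data.frame(
      variant = v, accuracy = mean(pred$class == truth),
      auc = compute_auc(pred$score, truth),
      n_signature = length(model$signature$genes),
      stringsAsFactors = FALSE)
  }
  ext_df <- do.call(rbind, external_rows)
  rownames(ext_df) <- NULL
  internal <- data.frame(
    variant = variants,
    cv_accuracy = vapply(reports, function(r) r$mean_accuracy, 0),
    cv_auc = vapply(reports, function(r) r$mean_auc, 0),
    stringsAsFactors = FALSE)
  ranking <- merge(internal, ext_df, by = "variant")
  ranking <- ranking[order(-ranking$accuracy), ]
  rownames(ranking) <- NULL
  structure(list(reports = reports, external = ext_df, ranking = ranking,
                 seed = seed),
            class = "fuzzsig_comparison")
}

#' @export
print.fuzzsig_comparison <- function(x, ...) {
  cat("fuzzsig_comparison (internal CV vs external validation)\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}
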