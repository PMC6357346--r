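#' Candidate feature genes: simultaneously DEG and DMG
#'
#' @param deg a [call_deg()] result.
#' @param dmg a [call_dmg()] result.
#' @return Character vector of genes flagged in both tables. An empty
#'   intersection triggers a warning (downstream selection then falls back
#'   to the biomarker panel alone).
#' @export
candidate_features <- function(deg, dmg) {
  out <- intersect(deg$gene[deg$is_deg], dmg$gene[dmg$is_dmg])
  if (!length(out))
    warning("no gene is simultaneously DEG and DMG; ",
            "selection will rely on the biomarker panel alone")
  out
}

#' Select a gene signature with a biomarker-weighted elastic net
#'
#' Fits a binomial elastic-net classifier (via \pkg{glmnet}) over the
#' candidate genes plus any panel genes present in the matrix. Panel genes
#' receive the penalty multiplier `biomarker_penalty` (default 0.1) while
#' all other features keep multiplier 1, so reported biomarkers are shrunk
#' less and preferentially retained; a multiplier of 0 makes them
#' unpenalized (never dropped except by exact collinearity) and 1 treats
#' them as ordinary candidates. Lambda is chosen by seeded, stratified
#' internal cross-validation minimizing binomial deviance (or the one-SE
#' rule). The signature is the set of genes with nonzero coefficients at the
#' chosen lambda.
#'
#' @param log_expression an [omics_matrix()] on the log2 scale.
#' @param candidates character vector of candidate genes (may be empty if a
#'   panel is supplied).
#' @param panel optional [biomarker_panel()]; panel genes absent from the
#'   matrix are ignored.
#' @param alpha elastic-net mixing parameter in \[0, 1\] (default 0.5).
#' @param biomarker_penalty penalty multiplier for panel genes, in \[0, 1\].
#' @param lambda_rule `"1se"` (default: the largest lambda within one
#'   standard error of the minimum CV deviance, which keeps no-signal runs
#'   parsimonious) or `"min"` (the liberal minimum-deviance rule, which
#'   favors larger signatures).
#' @param nfolds internal CV folds (default 10).
#' @param seed integer seed controlling the internal fold assignment.
#' @param provenance label recording which model variant produced the
#'   signature.
#' @return An object of class `fuzzsig_signature`: list with `genes`
#'   (nonzero-coefficient genes), `coefficients` (named, original scale),
#'   `lambda_chosen`, `provenance`, `features` (the full feature set
#'   offered), `panel_genes`.
#' @export
select_signature <- function(log_expression, candidates, panel = NULL,
                             alpha = 0.5, biomarker_penalty = 0.1,
                             lambda_rule = c("1se", "min"), nfolds = 10L,
                             seed = 1L, provenance = "custom") {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(inherits(log_expression, "omics_matrix"),
            alpha >= 0, alpha <= 1,
            biomarker_penalty >= 0, biomarker_penalty <= 1)
  panel_genes <- if (is.null(panel)) character() else
    intersect(panel$genes, rownames(log_expression$values))
  features <- union(intersect(candidates, rownames(log_expression$values)),
                    panel_genes)
  if (length(features) < 2L)
    stop("need at least 2 features for signature selection, got ",
         length(features))
  x <- t(log_expression$values[features, , drop = FALSE])
  y <- factor(log_expression$labels, levels = c("normal", "tumor"))
  pf <- ifelse(features %in% panel_genes, biomarker_penalty, 1)
  foldid <- stratified_folds(log_expression$labels, k = nfolds, seed = seed)
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                          penalty.factor = pf, foldid = foldid,
                          type.measure = "deviance", standardize = TRUE)
  lambda <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  beta <- stats::coef(cv, s = lambda)
  beta <- stats::setNames(as.numeric(beta), rownames(beta))[-1L]  # drop intercept
  nz <- beta[beta != 0]
  structure(list(genes = names(nz), coefficients = nz,
                 lambda_chosen = lambda, provenance = provenance,
                 features = features, panel_genes = panel_genes,
                 alpha = alpha, biomarker_penalty = biomarker_penalty),
            class = "fuzzsig_signature")
}

#' @export
print.fuzzsig_signature <- function(x, ...) {
  cat(sprintf("fuzzsig_signature [%s]: %d of %d offered genes (lambda = %.4g)\n",
              x$provenance, length(x$genes), length(x$features),
              x$lambda_chosen))
  if (length(x$genes)) {
    mark <- ifelse(x$genes %in% x$panel_genes, "*", "")
    cat("  ", paste0(x$genes, mark, collapse = ", "), "\n", sep = "")
    if (any(nzchar(mark))) cat("  (* = biomarker panel gene)\n")
  }
  invisible(x)
}

#' Feature sets for the five model variants
#'
#' Expresses the model variants purely as feature-set constructors over the
#' differential-calling results:
#' \describe{
#'   \item{bio}{the biomarker panel only}
#'   \item{exp}{all DEGs (expression only)}
#'   \item{exp_meth}{DEGs intersected with DMGs from the original-array
#'     methylation}
#'   \item{bio_exp_meth}{as `exp_meth`, plus panel genes with reduced
#'     penalty}
#'   \item{bio_exp_emeth}{DEGs intersected with DMGs from the expanded
#'     methylation, plus panel genes with reduced penalty}
#' }
#'
#' @param variant one of the five names above.
#' @param deg [call_deg()] result.
#' @param dmg_original,dmg_expanded [call_dmg()] results on the two
#'   methylation views (only the one the variant needs is required).
#' @param panel [biomarker_panel()], required for the `bio*` variants.
#' @return list with `candidates` (character vector) and `weight_panel`
#'   (logical: does this variant down-penalize the panel genes?).
#' @export
variant_features <- function(variant = c("bio_exp_emeth", "bio", "exp",
                                         "exp_meth", "bio_exp_meth"),
                             deg = NULL, dmg_original = NULL,
                             dmg_expanded = NULL, panel = NULL) {
  variant <- match.arg(variant)
  need_panel <- variant %in% c("bio", "bio_exp_meth", "bio_exp_emeth")
  if (need_panel && is.null(panel))
    stop("variant '", variant, "' requires a biomarker panel")
  degs <- if (!is.null(deg)) deg$gene[deg$is_deg] else character()
  cand <- switch(variant,
    bio = character(),
    exp = degs,
    exp_meth = intersect(degs, dmg_original$gene[dmg_original$is_dmg]),
    bio_exp_meth = intersect(degs, dmg_original$gene[dmg_original$is_dmg]),
    bio_exp_emeth = intersect(degs, dmg_expanded$gene[dmg_expanded$is_dmg]))
  list(candidates = cand, weight_panel = need_panel, variant = variant)
}
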