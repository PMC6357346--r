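#' Fit the full integrative signature + fuzzy-classifier pipeline
#'
#' One call runs the whole method on a training cohort: (1) DEGs are called
#' on the log2 expression; (2) if the variant uses methylation, DMLs are
#' called on the beta matrix, CpGs are mapped into promoter windows, and
#' DMGs are called by Fisher-combining promoter locus p-values; (3) the
#' candidate set (DEG, intersected with DMG where applicable) plus the
#' biomarker panel enters a biomarker-weighted elastic net
#' ([select_signature()]); (4) a Mamdani fuzzy rulebase ([fit_fuzzy()]) is
#' induced on the signature genes. The returned model predicts new samples
#' from expression alone.
#'
#' If the elastic net retains fewer than one gene (possible on noise-only
#' data), the model falls back to the full offered feature set with a
#' warning, so that prediction is always defined.
#'
#' @param expression log2-scale [omics_matrix()] (use [log2_transform()]
#'   first for raw counts).
#' @param methylation beta-value [omics_matrix()], or `NULL` for
#'   expression-only variants.
#' @param annotation gene TSS data.frame (required when methylation is
#'   supplied).
#' @param loci CpG coordinate data.frame (`locus`, `chrom`, `pos`).
#' @param panel [biomarker_panel()] (required for `bio*` variants).
#' @param variant one of `"bio"`, `"exp"`, `"exp_meth"`, `"bio_exp_meth"`,
#'   `"bio_exp_emeth"`; the `*_meth`/`*_emeth` distinction is carried by
#'   which methylation matrix you pass in.
#' @param lfc_threshold,p_threshold DEG thresholds (see [call_deg()]).
#' @param delta_beta DML effect threshold (see [call_dml()]).
#' @param q_threshold DMG q-value cutoff (see [call_dmg()]).
#' @param upstream,downstream promoter window (see [map_promoter_loci()]).
#' @param alpha,biomarker_penalty,lambda_rule,nfolds elastic-net settings
#'   (see [select_signature()]).
#' @param terms fuzzy [linguistic_terms()].
#' @param seed integer seed for the internal elastic-net CV folds.
#' @return Object of class `fuzzsig_model`: list with `signature`
#'   ([select_signature()] result), `rulebase` ([fit_fuzzy()] result),
#'   `deg`, `dmg` (or `NULL`), `variant`, `genes` (signature genes used by
#'   the classifier), `call`.
#' @examples
#' sim <- simulate_dataset(synth_config(n_genes = 120, n_biomarkers = 3, seed = 2))
#' pan <- biomarker_panel("SYNTH", sim$truth$biomarker_genes)
#' fit <- fuzzsig(sim$expression, sim$methylation, sim$annotation, sim$loci,
#'                panel = pan, variant = "bio_exp_emeth")
#' fit
#' predict(fit, sim$expression)[1:4]
#' @export
fuzzsig <- function(expression, methylation = NULL, annotation = NULL,
                    loci = NULL, panel = NULL, variant = "bio_exp_emeth",
                    lfc_threshold = 1, p_threshold = 0.01, delta_beta = 0.1,
                    q_threshold = 0.01, upstream = 1500, downstream = 500,
                    alpha = 0.5, biomarker_penalty = 0.1,
                    lambda_rule = "1se", nfolds = 10L,
                    terms = linguistic_terms(), seed = 1L) {
  variant <- match.arg(variant, c("bio_exp_emeth", "bio", "exp", "exp_meth",
                                  "bio_exp_meth"))
  needs_meth <- variant %in% c("exp_meth", "bio_exp_meth", "bio_exp_emeth")
  if (needs_meth && (is.null(methylation) || is.null(annotation) ||
                     is.null(loci)))
    stop("variant '", variant,
         "' requires methylation, annotation and loci inputs")
  deg <- if (variant != "bio")
    call_deg(expression, lfc_threshold, p_threshold) else NULL
  dmg <- NULL
  if (needs_meth) {
    dml <- call_dml(methylation, delta_beta, p_threshold)
    pmap <- map_promoter_loci(annotation, loci, upstream, downstream)
    dmg <- call_dmg(dml, pmap, q_threshold)
  }
  vf <- variant_features(variant, deg = deg, dmg_original = dmg,
                         dmg_expanded = dmg, panel = panel)
  sig <- tryCatch(
    select_signature(expression, vf$candidates,
                     panel = if (vf$weight_panel) panel else NULL,
                     alpha = alpha,
                     biomarker_penalty = if (vf$weight_panel) biomarker_penalty else 1,
                     lambda_rule = lambda_rule, nfolds = nfolds, seed = seed,
                     provenance = toupper(gsub("_", "+", sub("emeth", "EMETH", variant)))),
    error = function(e) e)
  if (inherits(sig, "error")) stop("signature selection failed: ",
                                   conditionMessage(sig))
  genes <- sig$genes
  if (length(genes) < 1L) {
    warning("elastic net retained no gene; falling back to the full feature set")
    genes <- sig$features
  }
  rulebase <- fit_fuzzy(subset_omics(expression, features = genes),
                        terms = terms)
  structure(list(signature = sig, rulebase = rulebase, deg = deg, dmg = dmg,
                 variant = variant, genes = genes, seed = seed,
                 call = match.call()),
            class = "fuzzsig_model")
}

# retrain only the fuzzy stage on new training samples, keeping the
# signature fixed (used by the global-selection CV mode)
refit_fuzzsig <- function(model, expression) {
  rb <- fit_fuzzy(subset_omics(expression, features = model$genes),
                  terms = model$rulebase$terms)
  model$rulebase <- rb
  model
}

#' Predict tumor/normal status for new samples
#'
#' Applies the fitted fuzzy rulebase to new expression data restricted to
#' the model's signature genes. Values are normalized with the training
#' bounds (clamped); no stage of the model is refitted.
#'
#' @param object a [fuzzsig()] model.
#' @param newdata an [omics_matrix()] or samples x genes matrix covering the
#'   signature genes.
#' @param type `"class"`, `"score"` or `"full"` (see
#'   [predict.fuzzy_rulebase()]).
#' @param ... unused.
#' @export
predict.fuzzsig_model <- function(object, newdata,
                                  type = c("class", "score", "full"), ...) {
  predict(object$rulebase, newdata, type = match.arg(type))
}

#' @export
print.fuzzsig_model <- function(x, ...) {
  cat(sprintf("fuzzsig_model [%s]: %d-gene signature, %d fuzzy rules\n",
              x$variant, length(x$genes), nrow(x$rulebase$rules)))
  cat("  genes: ", paste(x$genes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.fuzzsig_model <- function(object, ...) {
  print(object)
  if (!is.null(object$deg))
    cat(sprintf("  DEGs called: %d\n", sum(object$deg$is_deg)))
  if (!is.null(object$dmg))
    cat(sprintf("  DMGs called: %d (of %d promoter genes)\n",
                sum(object$dmg$is_dmg), nrow(object$dmg)))
  summary(object$rulebase)
  invisible(object)
}
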