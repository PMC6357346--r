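#' Gaussian linguistic terms
#'
#' The normalized expression range \[0, 1\] of each gene is covered by three
#' linguistic terms -- "small", "medium", "large" -- with Gaussian membership
#' functions centered at 0, 0.5 and 1, all with the same width.
#'
#' @param centers term centers (default `c(0, 0.5, 1)`).
#' @param sigma common Gaussian width (default 0.175).
#' @param names term names, same length as `centers`.
#' @return A data.frame with columns `name`, `center`, `sigma`.
#' @export
linguistic_terms <- function(centers = c(0, 0.5, 1), sigma = 0.175,
                             names = c("small", "medium", "large")) {
  stopifnot(length(centers) == length(names), sigma > 0,
            !anyDuplicated(names))
  data.frame(name = names, center = centers, sigma = sigma,
             stringsAsFactors = FALSE)
}

#' Gaussian membership degree
#'
#' `exp(-(x - center)^2 / (2 sigma^2))`; equals 1 exactly at the term center.
#'
#' @param x numeric value(s), typically normalized to \[0, 1\].
#' @param center term center.
#' @param sigma term width (> 0).
#' @return membership degree(s) in (0, 1].
#' @examples
#' membership(0.5, 0.5)        # peak
#' membership(0.5, 0, 0.175)   # ~ 0.0169
#' @export
membership <- function(x, center, sigma = 0.175) {
  stopifnot(sigma > 0)
  exp(-(x - center)^2 / (2 * sigma^2))
}

#' Per-gene min/max normalization bounds
#'
#' Bounds are fitted on training data only and reused unchanged at
#' prediction time, so cross-validation stays honest.
#'
#' @param values numeric matrix, samples x genes.
#' @return data.frame with columns `gene`, `min`, `max`.
#' @export
fit_bounds <- function(values) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  data.frame(gene = colnames(values),
             min = apply(values, 2L, min),
             max = apply(values, 2L, max),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Normalize values to \[0, 1\] with fitted bounds
#'
#' `(x - min) / (max - min)`, clamped to \[0, 1\] for out-of-range test
#' values; a gene constant on the training data maps to 0.5 by convention.
#'
#' @param values numeric matrix (samples x genes) or named numeric vector.
#' @param bounds a [fit_bounds()] result covering every gene in `values`.
#' @return object of the same shape with values in \[0, 1\].
#' @export
normalize_bounds <- function(values, bounds) {
  vec <- !is.matrix(values)
  if (vec) values <- matrix(values, 1L, dimnames = list(NULL, names(values)))
  genes <- colnames(values)
  if (is.null(genes)) stop("values must carry gene names")
  miss <- setdiff(genes, bounds$gene)
  if (length(miss)) stop("no normalization bounds for gene: ", miss[1L])
  b <- bounds[match(genes, bounds$gene), ]
  rng <- b$max - b$min
  out <- sweep(values, 2L, b$min, "-")
  constant <- rng == 0
  rng[constant] <- 1
  out <- sweep(out, 2L, rng, "/")
  out[, constant] <- 0.5
  out <- pmin(pmax(out, 0), 1)
  if (vec) out[1L, ] else out
}

# winning (maximum-membership) term index for each normalized value;
# ties go to the term with the smaller center (deterministic)
winning_term <- function(x, terms) {
  deg <- vapply(seq_len(nrow(terms)),
                function(i) membership(x, terms$center[i], terms$sigma[i]),
                numeric(length(x)))
  if (length(x) == 1L) deg <- matrix(deg, nrow = 1L)
  max.col(deg, ties.method = "first")
}

#' Fit a Mamdani fuzzy-rule classifier
#'
#' Induces IF-THEN rules from training samples by the Wang-Mendel
#' construction: each gene's range is min/max-normalized to \[0, 1\] and
#' covered by three Gaussian [linguistic_terms()]; each training sample
#' contributes one candidate rule whose antecedent assigns every signature
#' gene its maximum-membership term, whose consequent is the sample's class,
#' and whose degree is the product of the winning memberships. Candidates
#' with identical antecedents are merged; when both classes claim the same
#' antecedent pattern the class with the larger summed degree wins (ties go
#' to `normal`, the conservative call), and the kept rule's weight is the
#' kept class's share of the pattern's total degree.
#'
#' @param x numeric matrix, samples x genes (raw scale; normalization is
#'   fitted internally), or an [omics_matrix()] (genes x samples, labels
#'   taken from it).
#' @param y character/factor of `"tumor"`/`"normal"` labels (ignored when
#'   `x` is an `omics_matrix`).
#' @param genes optional subset of columns to use as the signature.
#' @param terms a [linguistic_terms()] table.
#' @param bounds optional pre-fitted [fit_bounds()] table (e.g. identity
#'   bounds for data already on \[0, 1\]); fitted from `x` when `NULL`.
#' @return An object of class `fuzzy_rulebase`: list with `rules`
#'   (data.frame: `pattern` term indices as comma string, `consequent`,
#'   `weight`, `support`), `bounds`, `terms`, `gene_order`,
#'   `majority_class`.
#' @seealso [predict.fuzzy_rulebase()], [export_rules()]
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(20, 5), 10), matrix(rnorm(20, 9), 10))
#' colnames(x) <- c("gA", "gB")
#' fit <- fit_fuzzy(x, rep(c("normal", "tumor"), each = 10))
#' fit
#' @export
fit_fuzzy <- function(x, y = NULL, genes = NULL, terms = linguistic_terms(),
                      bounds = NULL) {
  if (inherits(x, "omics_matrix")) {
    y <- x$labels
    x <- t(x$values)
  }
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  if (is.null(y) || length(y) != nrow(x))
    stop("need one tumor/normal label per training sample")
  y <- as.character(y)
  if (!all(y %in% c("tumor", "normal")))
    stop("labels must be 'tumor' or 'normal'")
  if (!is.null(genes)) x <- x[, genes, drop = FALSE]
  if (nrow(x) < 1L) stop("empty training set")
  gene_order <- colnames(x)
  if (is.null(bounds)) bounds <- fit_bounds(x)
  z <- normalize_bounds(x, bounds)

  term_idx <- vapply(seq_len(ncol(z)),
                     function(j) winning_term(z[, j], terms),
                     integer(nrow(z)))
  if (nrow(z) == 1L) term_idx <- matrix(term_idx, nrow = 1L)
  deg <- matrix(membership(as.vector(z),
                           terms$center[as.vector(term_idx)],
                           terms$sigma[1L]),
                nrow(z), ncol(z))
  cand_weight <- apply(deg, 1L, prod)
  pattern <- apply(term_idx, 1L, paste, collapse = ",")

  agg <- stats::aggregate(cand_weight,
                          by = list(pattern = pattern, class = y), FUN = sum)
  names(agg)[3L] <- "w"
  support <- stats::aggregate(seq_along(pattern),
                              by = list(pattern = pattern), FUN = length)
  rules <- do.call(rbind, lapply(split(agg, agg$pattern), function(d) {
    total <- sum(d$w)
    if (nrow(d) == 1L) {
      kept <- d$class; w <- 1
    } else {
      wt <- d$w[d$class == "tumor"]; wn <- d$w[d$class == "normal"]
      kept <- if (wt > wn) "tumor" else "normal"   # tie -> normal
      w <- max(wt, wn) / total
    }
    data.frame(pattern = d$pattern[1L], consequent = kept, weight = w,
               stringsAsFactors = FALSE)
  }))
  rules$support <- support$x[match(rules$pattern, support$pattern)]
  rownames(rules) <- NULL
  tab <- table(factor(y, levels = c("normal", "tumor")))
  structure(list(rules = rules, bounds = bounds, terms = terms,
                 gene_order = gene_order,
                 majority_class = names(tab)[which.max(tab)]),
            class = "fuzzy_rulebase")
}

# integer matrix of antecedent term indices, rules x genes
rule_patterns <- function(rb) {
  m <- do.call(rbind, lapply(strsplit(rb$rules$pattern, ","), as.integer))
  matrix(m, nrow = nrow(rb$rules))
}

#' Predict from a fuzzy rulebase
#'
#' Mamdani inference: every rule fires with strength `min` over its
#' antecedent memberships (t-norm) times the rule weight; each class
#' aggregates its rules' strengths with `max` (s-norm); the predicted class
#' is the argmax, and the continuous score is
#' `aggregate(tumor) - aggregate(normal)` in \[-1, 1\]. When no rule fires
#' for either class (both aggregates zero) the majority training class is
#' predicted and flagged.
#'
#' @param object a [fit_fuzzy()] rulebase.
#' @param newdata numeric matrix (samples x genes, raw scale), named numeric
#'   vector for one sample, or an [omics_matrix()].
#' @param type `"class"`, `"score"`, or `"full"` (data.frame with class,
#'   score, per-class aggregates and the no-rule flag).
#' @param ... unused.
#' @return See `type`.
#' @export
predict.fuzzy_rulebase <- function(object, newdata,
                                   type = c("class", "score", "full"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "omics_matrix")) newdata <- t(newdata$values)
  if (!is.matrix(newdata))
    newdata <- matrix(newdata, 1L, dimnames = list(NULL, names(newdata)))
  miss <- setdiff(object$gene_order, colnames(newdata))
  if (length(miss)) stop("sample does not cover gene: ", miss[1L])
  z <- normalize_bounds(newdata[, object$gene_order, drop = FALSE],
                        object$bounds)
  pat <- rule_patterns(object)
  centers <- object$terms$center
  sigma <- object$terms$sigma[1L]
  n <- nrow(z)
  agg_t <- numeric(n); agg_n <- numeric(n)
  tumor_rules <- object$rules$consequent == "tumor"
  for (i in seq_len(n)) {
    # rules x genes membership of this sample in each rule's antecedents
    memb <- matrix(membership(rep(z[i, ], each = nrow(pat)),
                              centers[pat], sigma), nrow(pat))
    fire <- apply(memb, 1L, min) * object$rules$weight
    agg_t[i] <- if (any(tumor_rules)) max(fire[tumor_rules]) else 0
    agg_n[i] <- if (any(!tumor_rules)) max(fire[!tumor_rules]) else 0
  }
  none <- agg_t == 0 & agg_n == 0
  cls <- ifelse(agg_t > agg_n, "tumor", "normal")  # tie -> normal
  cls[none] <- object$majority_class
  score <- agg_t - agg_n
  switch(type,
         class = stats::setNames(cls, rownames(newdata)),
         score = stats::setNames(score, rownames(newdata)),
         full = data.frame(sample = rownames(newdata) %||% seq_len(n),
                           class = cls, score = score, tumor = agg_t,
                           normal = agg_n, no_rule_fired = none,
                           row.names = NULL, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fuzzy_rulebase <- function(x, ...) {
  cat(sprintf("fuzzy_rulebase: %d rules over %d genes (%d tumor, %d normal)\n",
              nrow(x$rules), length(x$gene_order),
              sum(x$rules$consequent == "tumor"),
              sum(x$rules$consequent == "normal")))
  invisible(x)
}

#' @export
summary.fuzzy_rulebase <- function(object, ...) {
  cat(sprintf("Mamdani fuzzy rulebase\n  genes (%d): %s\n",
              length(object$gene_order),
              paste(object$gene_order, collapse = ", ")))
  cat(sprintf("  terms: %s (sigma = %g)\n",
              paste(sprintf("%s@%g", object$terms$name, object$terms$center),
                    collapse = ", "), object$terms$sigma[1L]))
  cat(sprintf("  rules: %d (mean weight %.3f, conflicts resolved: %d)\n",
              nrow(object$rules), mean(object$rules$weight),
              sum(object$rules$weight < 1)))
  cat("  top rules by support:\n")
  top <- utils::head(object$rules[order(-object$rules$support), ], 3L)
  cat(paste0("    ", export_rules(object, rules = top)), sep = "\n")
  invisible(object)
}

#' Plot the membership functions of a rulebase
#'
#' @param x a [fit_fuzzy()] rulebase (or [linguistic_terms()] table).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.fuzzy_rulebase <- function(x, ...) {
  terms <- if (is.data.frame(x)) x else x$terms
  grid <- seq(0, 1, length.out = 201L)
  m <- vapply(seq_len(nrow(terms)),
              function(i) membership(grid, terms$center[i], terms$sigma[i]),
              numeric(length(grid)))
  graphics::matplot(grid, m, type = "l", lty = 1, xlab = "normalized expression",
                    ylab = "membership", ...)
  graphics::legend("right", legend = terms$name, col = seq_len(nrow(terms)),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Export rules as human-readable IF-THEN text
#'
#' One line per rule, antecedents in the rulebase's gene order:
#' `IF (GENE is small) ^ (GENE2 is large) ^ ... THEN the sample is a tumor
#' sample  [weight=0.97]`.
#'
#' @param rulebase a [fit_fuzzy()] result.
#' @param rules optionally a subset of `rulebase$rules` rows.
#' @return character vector, one element per rule.
#' @seealso [parse_rules()] for the inverse.
#' @export
export_rules <- function(rulebase, rules = rulebase$rules) {
  pat <- do.call(rbind, lapply(strsplit(rules$pattern, ","), as.integer))
  vapply(seq_len(nrow(rules)), function(i) {
    ante <- paste(sprintf("(%s is %s)", rulebase$gene_order,
                          rulebase$terms$name[pat[i, ]]), collapse = " ^ ")
    sprintf("IF %s THEN the sample is a %s sample  [weight=%.6g]",
            ante, rules$consequent[i], rules$weight[i])
  }, character(1L))
}

#' Parse IF-THEN rule text back into a rule table
#'
#' Inverse of [export_rules()] given the same terms: recovers the antecedent
#' pattern, consequent and weight of each line.
#'
#' @param lines character vector of exported rule lines.
#' @param terms the [linguistic_terms()] the rules were written with.
#' @return list with `rules` (data.frame `pattern`, `consequent`, `weight`)
#'   and `gene_order`.
#' @export
parse_rules <- function(lines, terms = linguistic_terms()) {
  gene_order <- NULL
  rows <- lapply(lines, function(ln) {
    m <- regmatches(ln, gregexpr("\\(([^ ]+) is ([a-z]+)\\)", ln))[[1L]]
    if (!length(m)) stop("unparseable rule line: ", ln)
    g <- sub("^\\(([^ ]+) is .*", "\\1", m)
    t <- sub(".* is ([a-z]+)\\)$", "\\1", m)
    if (is.null(gene_order)) gene_order <<- g
    else if (!identical(g, gene_order)) stop("inconsistent gene order across rules")
    cons <- sub(".*THEN the sample is a (tumor|normal) sample.*", "\\1", ln)
    w <- as.numeric(sub(".*\\[weight=([0-9.eE+-]+)\\]$", "\\1", ln))
    data.frame(pattern = paste(match(t, terms$name), collapse = ","),
               consequent = cons, weight = w, stringsAsFactors = FALSE)
  })
  list(rules = do.call(rbind, rows), gene_order = gene_order)
}

#' Serialize / restore a fuzzy rulebase as versioned JSON
#'
#' @param rulebase a [fit_fuzzy()] result.
#' @param path output (input) file path.
#' @return `write_rulebase`: `path` invisibly; `read_rulebase`: the restored
#'   `fuzzy_rulebase`.
#' @export
write_rulebase <- function(rulebase, path) {
  payload <- list(format = "fuzzsig_rulebase", version = 1L,
                  terms = rulebase$terms, bounds = rulebase$bounds,
                  rules = rulebase$rules, gene_order = rulebase$gene_order,
                  majority_class = rulebase$majority_class)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rulebase
#' @export
read_rulebase <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "fuzzsig_rulebase"))
    stop("not a fuzzsig rulebase file: ", path)
  structure(list(rules = p$rules, bounds = p$bounds, terms = p$terms,
                 gene_order = p$gene_order, majority_class = p$majority_class),
            class = "fuzzy_rulebase")
}
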