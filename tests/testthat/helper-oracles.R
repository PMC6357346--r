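# Independent oracles used across the suite. Each re-derives the quantity
# it checks from first principles, sharing no code with the implementation.

# chi-squared upper tail by numeric integration of the explicit density
chisq_tail_oracle <- function(stat, df) {
  dens <- function(x) x^(df / 2 - 1) * exp(-x / 2) / (2^(df / 2) * gamma(df / 2))
  if (stat <= 0) return(1)
  stats::integrate(dens, stat, Inf, rel.tol = 1e-12,
                   abs.tol = 1e-14)$value
}

# brute-force Mamdani evaluator: loops over rules and genes, recomputing
# normalization, memberships, min, weighting and max from scratch
brute_force_classify <- function(rulebase, sample_raw) {
  g <- rulebase$gene_order
  agg <- c(tumor = 0, normal = 0)
  for (r in seq_len(nrow(rulebase$rules))) {
    terms_idx <- as.integer(strsplit(rulebase$rules$pattern[r], ",")[[1L]])
    strengths <- numeric(length(g))
    for (j in seq_along(g)) {
      b <- rulebase$bounds[rulebase$bounds$gene == g[j], ]
      z <- if (b$max == b$min) 0.5 else (sample_raw[[g[j]]] - b$min) / (b$max - b$min)
      z <- min(max(z, 0), 1)
      cen <- rulebase$terms$center[terms_idx[j]]
      strengths[j] <- exp(-(z - cen)^2 / (2 * rulebase$terms$sigma[1L]^2))
    }
    fire <- min(strengths) * rulebase$rules$weight[r]
    cls <- rulebase$rules$consequent[r]
    agg[cls] <- max(agg[cls], fire)
  }
  cls <- if (agg["tumor"] > agg["normal"]) "tumor" else "normal"
  if (all(agg == 0)) cls <- rulebase$majority_class
  list(class = unname(cls), score = unname(agg["tumor"] - agg["normal"]))
}

# all-pairs AUC with half-credit for ties
auc_all_pairs <- function(scores, labels) {
  t_sc <- scores[labels == "tumor"]
  n_sc <- scores[labels == "normal"]
  wins <- 0
  for (t in t_sc) for (n in n_sc)
    wins <- wins + if (t > n) 1 else if (t == n) 0.5 else 0
  wins / (length(t_sc) * length(n_sc))
}

# brute-force promoter interval scan (1-based, inclusive ends)
promoter_map_oracle <- function(annotation, loci, upstream = 1500,
                                downstream = 500) {
  out <- list()
  for (i in seq_len(nrow(annotation))) {
    if (annotation$strand[i] == "+") {
      lo <- annotation$tss[i] - upstream; hi <- annotation$tss[i] + downstream
    } else {
      lo <- annotation$tss[i] - downstream; hi <- annotation$tss[i] + upstream
    }
    hit <- loci$locus[loci$chrom == annotation$chrom[i] &
                      loci$pos >= lo & loci$pos <= hi]
    if (length(hit)) out[[annotation$gene[i]]] <- hit
  }
  out
}

# random small rulebase over k genes (identity bounds, valid patterns)
random_rulebase <- function(k_genes = 3L, n_rules = NULL) {
  genes <- paste0("G", seq_len(k_genes))
  n_rules <- n_rules %||% sample(2:6, 1L)
  pats <- unique(replicate(n_rules,
    paste(sample(1:3, k_genes, replace = TRUE), collapse = ",")))
  rules <- data.frame(
    pattern = pats,
    consequent = sample(c("tumor", "normal"), length(pats), replace = TRUE),
    weight = round(stats::runif(length(pats), 0.2, 1), 4),
    support = 1L, stringsAsFactors = FALSE)
  structure(list(rules = rules,
                 bounds = data.frame(gene = genes, min = 0, max = 1),
                 terms = linguistic_terms(), gene_order = genes,
                 majority_class = sample(c("tumor", "normal"), 1L)),
            class = "fuzzy_rulebase")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of a serialized object (for model-identity / leakage checks)
object_md5 <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(obj, NULL, version = 2L), tmp)
  unname(tools::md5sum(tmp))
}

# small shared simulation, built once per test run
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(synth_config(seed = 42L))
    cache
  }
})
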