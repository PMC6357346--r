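identity_bounds <- function(genes) data.frame(gene = genes, min = 0, max = 1)

test_that("Gaussian membership has unit peaks and the documented tails", {
  terms <- linguistic_terms()
  for (i in 1:3)
    expect_equal(membership(terms$center[i], terms$center[i], terms$sigma[i]), 1)
  expect_equal(membership(0, 0), membership(1, 1))
  expect_equal(membership(0.5, 0, 0.175), exp(-0.25 / (2 * 0.175^2)),
               tolerance = 1e-12)
  expect_equal(membership(0.5, 0, 0.175), 0.0169, tolerance = 1e-2)
  expect_error(linguistic_terms(sigma = 0), "sigma")
})

test_that("normalization maps endpoints, interpolates, clamps and handles constants", {
  b <- data.frame(gene = c("g1", "g2"), min = c(2, 5), max = c(6, 5))
  expect_equal(unname(normalize_bounds(c(g1 = 2), b[1, ])), 0)
  expect_equal(unname(normalize_bounds(c(g1 = 6), b[1, ])), 1)
  expect_equal(unname(normalize_bounds(c(g1 = 5), b[1, ])), 0.75)
  expect_equal(unname(normalize_bounds(c(g1 = 99), b[1, ])), 1)   # clamp high
  expect_equal(unname(normalize_bounds(c(g1 = -99), b[1, ])), 0)  # clamp low
  expect_equal(unname(normalize_bounds(c(g2 = 5), b[2, ])), 0.5)  # constant
  expect_error(normalize_bounds(c(gX = 1), b), "gX")
})

test_that("a single training sample induces its own maximal rule", {
  x <- matrix(1, 1, 3, dimnames = list("s1", c("gA", "gB", "gC")))
  rb <- fit_fuzzy(x, "tumor", bounds = identity_bounds(colnames(x)))
  expect_equal(nrow(rb$rules), 1L)
  expect_equal(rb$rules$pattern, "3,3,3")  # all large
  expect_equal(rb$rules$consequent, "tumor")
  expect_equal(rb$rules$weight, 1)
  expect_match(export_rules(rb),
               "^IF \\(gA is large\\) \\^ \\(gB is large\\) \\^ \\(gC is large\\) THEN the sample is a tumor sample")
})

test_that("conflicting identical samples merge into one half-weight rule", {
  x <- matrix(c(0.9, 0.9), 2, 1, dimnames = list(c("s1", "s2"), "gA"))
  rb <- fit_fuzzy(x, c("tumor", "normal"), bounds = identity_bounds("gA"))
  expect_equal(nrow(rb$rules), 1L)
  expect_equal(rb$rules$weight, 0.5)
  expect_equal(rb$rules$consequent, "normal")  # documented tie-break
})

test_that("clustered two-gene data induce the expected antecedent patterns", {
  set.seed(6)
  tum <- cbind(rnorm(10, 0.9, 0.03), rnorm(10, 0.1, 0.03))
  nor <- cbind(rnorm(10, 0.1, 0.03), rnorm(10, 0.9, 0.03))
  x <- rbind(tum, nor)
  colnames(x) <- c("gA", "gB")
  rb <- fit_fuzzy(x, rep(c("tumor", "normal"), each = 10),
                  bounds = identity_bounds(colnames(x)))
  # enumerate all 9 possible patterns: only the two cluster patterns appear
  expect_setequal(rb$rules$pattern, c("3,1", "1,3"))
  expect_equal(rb$rules$consequent[rb$rules$pattern == "3,1"], "tumor")
  expect_equal(rb$rules$consequent[rb$rules$pattern == "1,3"], "normal")
  expect_true(all(rb$rules$weight == 1))
  # training-set consistency on separable data
  pred <- predict(rb, x)
  expect_equal(unname(pred), rep(c("tumor", "normal"), each = 10))
})

test_that("a sample at a rule's term centers fires with the rule weight", {
  rb <- random_rulebase(3, 1)
  rb$rules$weight <- 0.7
  centers <- linguistic_terms()$center[
    as.integer(strsplit(rb$rules$pattern, ",")[[1]])]
  s <- setNames(centers, rb$gene_order)
  full <- predict(rb, s, type = "full")
  agg <- if (rb$rules$consequent == "tumor") full$tumor else full$normal
  expect_equal(agg, 0.7)
})

test_that("inference matches the brute-force evaluator on random cases", {
  set.seed(77)
  checked <- 0L
  while (checked < 1000L) {
    rb <- random_rulebase(sample(2:4, 1))
    for (i in 1:20) {
      s <- setNames(runif(length(rb$gene_order)), rb$gene_order)
      want <- brute_force_classify(rb, as.list(s))
      expect_identical(unname(predict(rb, s, type = "class")), want$class)
      expect_identical(unname(predict(rb, s, type = "score")), want$score)
      checked <- checked + 1L
    }
  }
})

test_that("zero firing falls back to the majority training class, flagged", {
  rb <- random_rulebase(2, 1)
  rb$rules$weight <- 0  # nothing can fire
  rb$majority_class <- "tumor"
  full <- predict(rb, c(G1 = 0.5, G2 = 0.5), type = "full")
  expect_true(full$no_rule_fired)
  expect_equal(full$class, "tumor")
})

test_that("rule order and consistent gene relabeling do not change predictions", {
  set.seed(91)
  x <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("gA", "gB", "gC")))
  y <- rep(c("tumor", "normal"), 10)
  rb <- fit_fuzzy(x, y, bounds = identity_bounds(colnames(x)))
  s <- matrix(runif(30), 10, 3, dimnames = list(NULL, colnames(x)))
  base_cls <- predict(rb, s)
  base_score <- predict(rb, s, type = "score")
  rb_shuf <- rb
  set.seed(1); rb_shuf$rules <- rb$rules[sample(nrow(rb$rules)), ]
  expect_equal(unname(predict(rb_shuf, s)), unname(base_cls))
  expect_equal(unname(predict(rb_shuf, s, type = "score")),
               unname(base_score))
  # permute gene columns (model refit on identical data, new column order)
  perm <- c(3, 1, 2)
  rb_perm <- fit_fuzzy(x[, perm], y,
                       bounds = identity_bounds(colnames(x)[perm]))
  expect_equal(unname(predict(rb_perm, s[, perm])), unname(base_cls))
  expect_equal(unname(predict(rb_perm, s[, perm], type = "score")),
               unname(base_score))
})

test_that("scores are antisymmetric under swapping the class consequents", {
  set.seed(92)
  for (i in 1:10) {
    rb <- random_rulebase(3)
    rb_swap <- rb
    rb_swap$rules$consequent <- ifelse(rb$rules$consequent == "tumor",
                                       "normal", "tumor")
    s <- setNames(runif(3), rb$gene_order)
    expect_equal(unname(predict(rb, s, type = "score")),
                 -unname(predict(rb_swap, s, type = "score")),
                 tolerance = 1e-15)
  }
})

test_that("exported rules follow the IF-THEN surface form and parse back", {
  sim <- default_sim()
  genes <- rownames(sim$expression$values)[1:12]
  rb <- fit_fuzzy(subset_omics(sim$expression, features = genes))
  lines <- export_rules(rb)
  expect_length(lines, nrow(rb$rules))
  rx <- "^IF \\(.+ is (small|medium|large)\\)( \\^ \\(.+ is (small|medium|large)\\))* THEN the sample is a (tumor|normal) sample"
  expect_true(all(grepl(rx, lines)))
  # a 12-gene signature yields 12 antecedent clauses per rule
  n_clauses <- lengths(gregexpr(" is (small|medium|large)\\)", lines))
  expect_true(all(n_clauses == 12L))
  parsed <- parse_rules(lines, rb$terms)
  expect_identical(parsed$gene_order, rb$gene_order)
  expect_identical(parsed$rules$pattern, rb$rules$pattern)
  expect_identical(parsed$rules$consequent, rb$rules$consequent)
  expect_equal(parsed$rules$weight, rb$rules$weight, tolerance = 1e-6)
})

test_that("rulebases round-trip through versioned JSON", {
  sim <- default_sim()
  rb <- fit_fuzzy(subset_omics(sim$expression,
                               features = rownames(sim$expression$values)[1:4]))
  path <- tempfile(fileext = ".json")
  write_rulebase(rb, path)
  back <- read_rulebase(path)
  expect_equal(back$rules, rb$rules, tolerance = 1e-12)
  expect_equal(back$bounds, rb$bounds, tolerance = 1e-12)
  expect_identical(back$gene_order, rb$gene_order)
  s <- sim$expression$values[1:4, 7]
  expect_equal(predict(back, s, type = "score"),
               predict(rb, s, type = "score"), tolerance = 1e-12)
  expect_error(read_rulebase(tempfile()), ".")
})
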