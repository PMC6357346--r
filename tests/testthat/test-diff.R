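make_expr <- function(values, n_t = 2, n_n = 2) {
  m <- matrix(values, nrow = length(values) / (n_t + n_n), byrow = TRUE)
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  colnames(m) <- c(paste0("t", seq_len(n_t)), paste0("n", seq_len(n_n)))
  omics_matrix(m, setNames(rep(c("tumor", "normal"), c(n_t, n_n)),
                           colnames(m)))
}

test_that("log2 transform applies the documented pseudocount map", {
  om <- make_expr(c(0, 7, 1023, 3, 1, 15, 0, 0))
  lt <- log2_transform(om)
  expect_equal(unname(lt$values[1, ]), c(0, 3, 10, 2))
  neg <- make_expr(c(-1, 2, 3, 4))
  expect_error(log2_transform(neg), "negative")
})

test_that("vectorised Welch statistics agree with t.test", {
  set.seed(10)
  m <- matrix(rnorm(200, sd = rep(c(1, 3), each = 100)), 20, 10)
  dimnames(m) <- list(paste0("g", 1:20), paste0("s", 1:10))
  tum <- 1:4; nor <- 5:10
  w <- fuzzsig:::row_welch(m, tum, nor)
  for (i in c(1, 7, 20)) {
    tt <- t.test(m[i, tum], m[i, nor])
    expect_equal(w$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(w$t[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(w$df[i], unname(tt$parameter), tolerance = 1e-12)
  }
})

test_that("DEG calling enforces both the fold-change and the adjusted-p gate", {
  sim <- default_sim()
  deg <- call_deg(sim$expression)
  expect_equal(deg$is_deg,
               abs(deg$log2fc) > 1 & deg$p_adj < 0.01)
  expect_equal(deg$p_adj, p.adjust(deg$p, "BH"))
  expect_true(all(deg$p_adj >= deg$p))
  # identical values in both groups: no fold change, never called
  flat <- make_expr(rep(5, 8))
  res <- call_deg(flat)
  expect_equal(res$log2fc, c(0, 0))
  expect_equal(res$p, c(1, 1))
  expect_false(any(res$is_deg))
  # a class with < 2 samples is rejected
  one <- sim$expression
  expect_error(call_deg(subset_omics(one, samples = c("T001", "N001", "N002"))),
               "2 samples")
})

test_that("DML calling enforces the delta-beta gate regardless of p", {
  set.seed(2)
  n <- 10
  tight <- c(rnorm(n, 0.55, 0.001), rnorm(n, 0.50, 0.001))  # tiny p, small delta
  wide <- c(rnorm(n, 0.9, 0.01), rnorm(n, 0.2, 0.01))
  m <- rbind(cg1 = tight, cg2 = wide)
  colnames(m) <- paste0("s", 1:(2 * n))
  om <- omics_matrix(m, setNames(rep(c("tumor", "normal"), each = n),
                                 colnames(m)), "methylation")
  res <- call_dml(om)
  expect_false(res$is_dml[res$locus == "cg1"])
  expect_lt(res$p[res$locus == "cg1"], 0.01)
  expect_true(res$is_dml[res$locus == "cg2"])
})

test_that("promoter windows are inclusive and strand-reflected", {
  ann <- data.frame(gene = c("GP", "GM"), chrom = "chr1",
                    tss = c(10000L, 10000L), strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  loci <- data.frame(locus = paste0("cg", 1:8), chrom = "chr1",
                     pos = c(8500, 8499, 10500, 10501, 11400, 11501, 9500, 9499),
                     stringsAsFactors = FALSE)
  map_p <- map_promoter_loci(ann[1, ], loci)
  expect_setequal(map_p$GP, c("cg1", "cg3", "cg7", "cg8"))
  map_m <- map_promoter_loci(ann[2, ], loci)  # window [9500, 11500]
  expect_setequal(map_m$GM, c("cg3", "cg4", "cg5", "cg7"))
  # strand-agnostic mode treats every gene as + strand
  map_ag <- map_promoter_loci(ann, loci, strand_aware = FALSE)
  expect_identical(map_ag$GM, map_ag$GP)
})

test_that("interval mapping matches a brute-force scan on random inputs", {
  set.seed(33)
  for (rep in 1:5) {
    ann <- data.frame(gene = paste0("G", 1:12),
                      chrom = sample(c("chr1", "chr2"), 12, replace = TRUE),
                      tss = sample(5000:50000, 12), strand = sample(c("+", "-"), 12, TRUE),
                      stringsAsFactors = FALSE)
    loci <- data.frame(locus = paste0("cg", 1:300),
                       chrom = sample(c("chr1", "chr2"), 300, replace = TRUE),
                       pos = sample(3000:55000, 300), stringsAsFactors = FALSE)
    got <- map_promoter_loci(ann, loci)
    want <- promoter_map_oracle(ann, loci)
    expect_setequal(names(got), names(want))
    for (g in names(want)) expect_setequal(got[[g]], want[[g]])
  }
})

test_that("Fisher combination matches its closed forms and hand values", {
  expect_equal(fisher_combine(c(1, 1))$stat, 0)
  expect_equal(fisher_combine(c(1, 1))$p, 1)
  # chi-squared(2) tail of -2 log p is exactly p
  for (p in c(0.05, 0.3, 1e-6))
    expect_equal(fisher_combine(p)$p, p, tolerance = 1e-12)
  fc <- fisher_combine(c(0.01, 0.04))
  expect_equal(fc$stat, -2 * (log(0.01) + log(0.04)), tolerance = 1e-12)
  expect_equal(fc$stat, 15.64809, tolerance = 1e-6)
  expect_equal(fc$p, chisq_tail_oracle(fc$stat, 4), tolerance = 1e-10)
  expect_error(fisher_combine(numeric()), "empty")
  expect_error(fisher_combine(c(0.5, 1.2)), "0, 1")
  expect_warning(res <- fisher_combine(c(0, 0.5)), "clamped")
  expect_true(is.finite(res$stat))
})

test_that("Fisher combination agrees with a numeric-integration oracle", {
  set.seed(44)
  for (i in 1:100) {
    p <- runif(sample(1:8, 1), min = 1e-12)
    fc <- fisher_combine(p)
    expect_equal(fc$p, chisq_tail_oracle(fc$stat, fc$df), tolerance = 1e-8)
  }
})

test_that("appending a p = 1 locus never strengthens the combined evidence", {
  set.seed(55)
  for (i in 1:25) {
    p <- runif(sample(1:5, 1))
    base <- fisher_combine(p)
    padded <- fisher_combine(c(p, 1))
    expect_equal(padded$stat, base$stat, tolerance = 1e-12)
    expect_gte(padded$p, base$p)
  }
})

test_that("DMG calling gates on DML presence and combines all promoter loci", {
  dml <- data.frame(locus = c("cg1", "cg2", "cg3"),
                    delta_beta = c(0, 0, 0.3), p = c(1, 1, 0.005),
                    is_dml = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  # gene with only p = 1 loci: considered but never a DMG
  res <- call_dmg(dml, list(GA = c("cg1", "cg2")))
  expect_equal(res$n_dml, 0L)
  expect_false(res$is_dmg)
  expect_true(is.na(res$q))
  # single gene, single significant locus: Fisher and BH are identities
  res2 <- call_dmg(dml, list(GB = "cg3"))
  expect_equal(res2$fisher_p, 0.005, tolerance = 1e-12)
  expect_equal(res2$q, 0.005, tolerance = 1e-12)
  expect_true(res2$is_dmg)
  # all promoter loci (not just DMLs) feed the combination by default
  res3 <- call_dmg(dml, list(GC = c("cg1", "cg3")))
  expect_equal(res3$fisher_stat, -2 * (log(1) + log(0.005)), tolerance = 1e-12)
  res3b <- call_dmg(dml, list(GC = c("cg1", "cg3")), combine = "dml_only")
  expect_equal(res3b$fisher_stat, -2 * log(0.005), tolerance = 1e-12)
  expect_error(call_dmg(dml, list()), "empty promoter map")
})

test_that("planted DMGs are recovered and null genes are controlled", {
  sim <- simulate_dataset(synth_config(n_genes = 400, frac_dmg = 0.1,
                                       frac_deg = 0.1, frac_joint = 0.05,
                                       n_biomarkers = 0, seed = 13))
  dml <- call_dml(sim$methylation)
  pmap <- map_promoter_loci(sim$annotation, sim$loci)
  dmg <- call_dmg(dml, pmap)
  called <- dmg$gene[dmg$is_dmg]
  expect_gte(length(intersect(called, sim$truth$dmg_genes)),
             ceiling(0.875 * length(sim$truth$dmg_genes)))
  null_called <- setdiff(called, sim$truth$dmg_genes)
  expect_lte(length(null_called), 0.02 * (400 - length(sim$truth$dmg_genes)))
})

test_that("differential flags are invariant to row and column order", {
  sim <- simulate_dataset(synth_config(n_genes = 80, n_tumor = 8, n_normal = 8,
                                       n_biomarkers = 2, seed = 21))
  deg <- call_deg(sim$expression)
  set.seed(1)
  perm <- subset_omics(sim$expression,
                       features = sample(rownames(sim$expression$values)),
                       samples = sample(colnames(sim$expression$values)))
  deg_p <- call_deg(perm)
  deg_p <- deg_p[match(deg$gene, deg_p$gene), ]
  expect_equal(deg$is_deg, deg_p$is_deg)
  expect_equal(deg$p, deg_p$p, tolerance = 1e-12)
})

test_that("shuffling labels drives DEG calls to BH-controlled levels", {
  sim <- simulate_dataset(synth_config(n_genes = 150, n_tumor = 15,
                                       n_normal = 15, n_biomarkers = 3,
                                       seed = 17))
  frac <- vapply(1:5, function(s) {
    set.seed(s)
    shuffled <- sample(sim$expression$labels)
    names(shuffled) <- names(sim$expression$labels)
    om <- omics_matrix(sim$expression$values, shuffled)
    mean(call_deg(om)$is_deg)
  }, numeric(1))
  expect_lte(mean(frac), 0.02)
})
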