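# minimal differential tables for pair-classification tests
mk_diff <- function(features, mean_A, mean_B, fdr) {
  data.frame(
    feature = features, mean_A = mean_A, mean_B = mean_B,
    fold_change = ifelse(mean_B == 0, NA, mean_A / mean_B),
    p = fdr, fdr = fdr,
    direction = "none", stringsAsFactors = FALSE
  )
}

test_that("pair classification applies strict FDR thresholds per axis", {
  db <- mk_diff(c("br1", "br2", "br3"), c(100, 100, 50), c(10, 10, 100),
    fdr = c(0.04, 0.04, 0.05)
  )
  de <- mk_diff(c("g1", "g2", "g3"), c(10, 200, 100), c(100, 20, 100),
    fdr = c(0.04, 0.5, 0.01)
  )
  pairs <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    br_id = c("br1", "br2", "br3"),
    tss_distance = c(-7L, 322L, 0L)
  )
  rec <- join_pairs(pairs, db, de, q = 0.05)
  expect_equal(rec$class, c("both-significant", "binding-only", "expression-only"))
  expect_equal(rec$quadrant, c("A+/B+", NA, NA)) # binding direction first
  # FDR exactly at the threshold is not significant on that axis
  expect_equal(rec$class[3], "expression-only")
  expect_error(
    join_pairs(data.frame(gene_id = "gX", br_id = "br1", tss_distance = 0L), db, de),
    "unknown gene"
  )
  expect_error(
    join_pairs(data.frame(gene_id = "g1", br_id = "brX", tss_distance = 0L), db, de),
    "unknown BR"
  )
  qc <- quadrant_counts(rec)
  expect_equal(sum(qc), sum(rec$class == "both-significant"))
})

test_that("concordance chi-square follows the product-marginal construction", {
  # observed equal to expected: statistic 0, p = 1
  res <- concordance_chi2(c(100, 100, 100, 100), 0.5, 0.5)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)

  res <- concordance_chi2(c(80, 0, 5, 19), 0.7, 0.8)
  expect_equal(sum(res$table$expected_freq), 1)
  expect_equal(sum(res$table$expected_count), res$n)
  expect_equal(res$chi2, sum(res$table$contribution))
  expect_true(all(res$table$contribution >= 0))
  expect_equal(res$p, pchisq(res$chi2, 3, lower.tail = FALSE))
  expect_error(concordance_chi2(c(0, 0, 0, 0), 0.5, 0.5), "no observed")
  expect_error(concordance_chi2(c(1, 2, 3, 4), 0, 0.5), "strictly inside")
})

test_that("the df=3 statistic has mean ~3 under the multinomial null", {
  set.seed(53)
  n <- 823
  pb <- 0.56
  pe <- 0.83
  freq <- c(pb * pe, pb * (1 - pe), (1 - pb) * pe, (1 - pb) * (1 - pe))
  draws <- rmultinom(10000, n, freq)
  stats <- apply(draws, 2, function(o) concordance_chi2(o, pb, pe)$chi2)
  expect_lt(abs(mean(stats) / 3 - 1), 0.05)
})

test_that("on/off genes are flagged by the strict minor-group threshold", {
  de <- mk_diff(
    c("g1", "g2", "g3", "g4", "g5"),
    mean_A = c(386.14, 100, 100, 100, 3),
    mean_B = c(0.00, 4.99, 5.00, 80, 200),
    fdr = c(0.01, 0.01, 0.01, 0.01, 0.01)
  )
  res <- onoff_classify(de, threshold = 5, q = 0.05)
  expect_equal(res$onoff, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(res$direction, c("A-up", "A-up", "A-up", "A-up", "B-up"))
  # not significant -> never on/off
  de$fdr <- 0.5
  expect_false(any(onoff_classify(de)$onoff))
})

test_that("cluster preparation normalizes columns then rows to unit sum of squares", {
  set.seed(59)
  m <- matrix(rpois(400, 50), 50, 8)
  rownames(m) <- paste0("f", 1:50)
  x <- cluster_prep(m)
  expect_equal(unname(rowSums(x^2)), rep(1, 50), tolerance = 1e-12)

  # direct recomputation oracle of the three steps
  l <- log(m + 1)
  z <- scale(l)
  expect_equal(unname(colMeans(z)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 8), tolerance = 1e-12)
  z_unit <- z / sqrt(rowSums(z^2))
  expect_equal(unname(x), unname(z_unit), tolerance = 1e-12, ignore_attr = TRUE)

  # degenerate inputs
  expect_error(cluster_prep(m[, 1, drop = FALSE]), ">= 2 columns")
  m2 <- m
  m2[, 3] <- 5
  expect_warning(x2 <- cluster_prep(m2), "constant column")
  expect_true(all(x2[, 3] == 0))
})

test_that("the synthetic pipeline recovers planted concordant regulation", {
  res <- run_pipeline(sim_config(seed = 7))
  s <- res$summary
  # conservation across the bundle
  cls <- table(res$pairs$class)
  expect_equal(sum(cls), s$n_pairs)
  expect_equal(sum(res$quadrants), s$n_both_significant)
  expect_equal(unname(sum(cls["both-significant"])), s$n_both_significant)
  # planted regulation is concordant: A+/A+ dominates, chi-square decisive
  expect_equal(names(which.max(res$quadrants)), "A+/A+")
  expect_lt(res$concordance$p, 1e-6)
  # strong recovery of planted effects at the default design
  expect_gt(res$recovery$binding$sensitivity, 0.9)
  expect_gt(res$recovery$expression$sensitivity, 0.9)
})

test_that("report bundles are deterministic and degrade gracefully when empty", {
  cfg <- sim_config(n_genes = 120, n_brs = 100, seed = 23)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_pipeline(cfg, outdir = d1)
  run_pipeline(cfg, outdir = d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      info = f
    )
  }
  expect_true(all(c(
    "binding_regions.bed", "differential_binding.tsv",
    "differential_expression.tsv", "pairs.tsv", "concordance.tsv",
    "onoff.tsv", "truth.tsv", "manifest.json"
  ) %in% f1))

  # no planted effects at a tiny threshold: concordance stage skipped
  null_cfg <- sim_config(
    n_genes = 80, n_brs = 60,
    frac_diff = c(binding = 0, expression = 0), seed = 29
  )
  d3 <- withr::local_tempdir()
  res <- run_pipeline(null_cfg, fdr = 1e-12, outdir = d3)
  expect_null(res$concordance)
  expect_false(file.exists(file.path(d3, "concordance.tsv")))
  expect_equal(res$summary$n_both_significant, 0)
})
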