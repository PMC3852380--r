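test_that("size factors reproduce the median-of-ratios hand example", {
  k <- matrix(c(10, 100, 1, 20, 200, 2), 3, 2,
    dimnames = list(paste0("f", 1:3), c("l1", "l2"))
  )
  s <- estimate_size_factors(k)
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # identical libraries -> unit factors
  k2 <- cbind(l1 = c(5, 50), l2 = c(5, 50))
  rownames(k2) <- c("f1", "f2")
  expect_equal(unname(estimate_size_factors(k2)), c(1, 1))

  # features containing any zero are excluded from the median
  k3 <- rbind(k, f4 = c(0, 1000))
  expect_equal(estimate_size_factors(k3), s)

  # all-zero-containing matrix errors unless the pseudo-reference is allowed
  k4 <- cbind(l1 = c(0, 4), l2 = c(3, 0))
  rownames(k4) <- c("f1", "f2")
  expect_error(estimate_size_factors(k4), "pseudo_reference")
  expect_silent(estimate_size_factors(k4, pseudo_reference = TRUE))
})

test_that("scaling one library by c rescales factors as c^(1-1/m) vs c^(-1/m)", {
  set.seed(9)
  for (m in c(2, 5)) {
    k <- matrix(rpois(40 * m, 100), 40, m,
      dimnames = list(paste0("f", 1:40), paste0("l", seq_len(m)))
    )
    s0 <- estimate_size_factors(k)
    cc <- 3
    k2 <- k
    k2[, 1] <- k2[, 1] * cc
    s1 <- estimate_size_factors(k2)
    expect_equal(s1[1] / s0[1], cc^(1 - 1 / m), tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(unname(s1[-1] / s0[-1]), rep(cc^(-1 / m), m - 1), tolerance = 1e-9)
  }
})

test_that("size factors agree with the DESeq2 reference estimator", {
  set.seed(77)
  k <- matrix(rnbinom(200 * 6, mu = 80, size = 5), 200, 6,
    dimnames = list(paste0("f", 1:200), paste0("l", 1:6))
  )
  ref <- DESeq2::estimateSizeFactorsForMatrix(k)
  expect_equal(unname(estimate_size_factors(k)), unname(ref), tolerance = 1e-4)
})

test_that("dispersion estimation recovers planted overdispersion and the Poisson floor", {
  set.seed(13)
  n <- 2000
  groups <- rep(c("A", "B"), each = 4)

  # constant counts across replicates -> raw dispersion 0
  kc <- matrix(7L, 5, 8, dimnames = list(paste0("f", 1:5), paste0("l", 1:8)))
  d <- estimate_dispersions(make_cm(kc, groups))
  expect_true(all(d$groups$A$raw == 0))

  # Poisson generator -> small final dispersions
  kp <- matrix(rpois(n * 8, exp(rnorm(n, log(150), 1))), n, 8)
  d <- estimate_dispersions(make_cm(kp, groups))
  expect_lt(stats::median(d$groups$A$final), 0.05)
  expect_lt(stats::median(d$groups$B$final), 0.05)

  # planted alpha = 0.2 at high means recovered within 25%
  mu <- exp(rnorm(n, log(800), 0.6))
  ka <- matrix(rnbinom(n * 8, mu = rep(mu, 8), size = 1 / 0.2), n, 8)
  d <- estimate_dispersions(make_cm(ka, groups))
  expect_lt(abs(stats::median(d$groups$A$final) / 0.2 - 1), 0.25)

  # single-replicate groups error unless blind pooling is requested
  cm1 <- make_cm(kp[1:50, 1:3], c("A", "A", "B"))
  expect_error(estimate_dispersions(cm1), "blind")
  expect_silent(d1 <- estimate_dispersions(cm1, blind = TRUE))
  expect_identical(d1$groups$A, d1$groups$B)
})

test_that("the exact test is modal-1, symmetric, and binomial in the Poisson limit", {
  # balanced design, observed split at the mode
  expect_equal(nb_exact_test(10, 10, 10, 15, 10, 15), 1)

  # Poisson limit with equal size factors: conditional distribution is
  # Binomial(n, 1/2); oracle by direct enumeration
  n <- 5
  for (kA in 0:n) {
    pr <- dbinom(0:n, n, 0.5)
    oracle <- sum(pr[pr <= pr[kA + 1] * (1 + 1e-7)])
    expect_equal(
      nb_exact_test(kA, n - kA, 2.5, 2.5, 2.5, 2.5),
      oracle,
      tolerance = 1e-10
    )
  }

  # group relabeling symmetry on random cases
  set.seed(19)
  for (i in 1:20) {
    kA <- rpois(1, 40)
    kB <- rpois(1, 40)
    muA <- runif(1, 20, 60)
    muB <- runif(1, 20, 60)
    vA <- muA * runif(1, 1, 3)
    vB <- muB * runif(1, 1, 3)
    expect_equal(
      nb_exact_test(kA, kB, muA, vA, muB, vB),
      nb_exact_test(kB, kA, muB, vB, muA, vA)
    )
  }

  # underdispersed inputs clamp to Poisson with a warning
  expect_warning(p <- nb_exact_test(5, 5, 5, 2, 5, 2), "Poisson")
  expect_equal(p, nb_exact_test(5, 5, 5, 5, 5, 5))

  # above the cap the normal approximation tracks the exact tail
  p_exact <- nb_exact_test(6000, 5000, 5500, 6000, 5500, 6000, cap = 20000)
  p_norm <- nb_exact_test(6000, 5000, 5500, 6000, 5500, 6000, cap = 10000)
  expect_equal(p_norm, p_exact, tolerance = 0.05)
})

test_that("BH adjustment matches the hand step-up example and its properties", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(29)
  p <- runif(100)^2
  adj <- bh_adjust(p)
  expect_gte(min(adj), min(p))
  # thresholding the adjusted values reproduces the BH step-up rejection set
  for (q in c(0.05, 0.2)) {
    ps <- sort(p)
    k <- which(ps <= q * seq_along(ps) / length(ps))
    bh_set <- if (length(k)) p <= ps[max(k)] else rep(FALSE, length(p))
    expect_identical(adj <= q, bh_set)
  }
})

test_that("differential testing is calibrated on null data and scale invariant", {
  cm <- null_binding_counts(2000, seed = 301)
  res <- run_differential(cm)
  expect_s3_class(res, "differential_table")
  # null: essentially no BH discoveries
  expect_lt(mean(res$fdr < 0.05), 0.01)
  expect_true(all(res$direction[res$fdr >= 0.05] == "none"))

  # integer rescaling of one library changes size factors, not decisions
  cm2 <- cm
  cm2$counts[, 3] <- cm2$counts[, 3] * 4L
  res2 <- run_differential(cm2)
  expect_lt(abs(sum(res2$p < 0.05) - sum(res$p < 0.05)), 30)
  expect_equal(
    attr(res2, "size_factors")[3] / attr(res, "size_factors")[3],
    4 * 4^(-1 / 8),
    tolerance = 0.02, ignore_attr = TRUE
  )
})

test_that("fold changes and directions follow the strict-FDR contract", {
  set.seed(37)
  base <- rpois(32, 200)
  k <- matrix(base, 4, 8, dimnames = list(paste0("f", 1:4), paste0("l", 1:8)))
  k[1, 1:4] <- k[1, 1:4] * 60L # strong A-up
  k[2, ] <- 0L # all-zero feature
  cm <- make_cm(k, rep(c("A", "B"), each = 4))
  res <- run_differential(cm)
  expect_equal(res$direction[1], "A-up")
  expect_true(res$fold_change[1] > 1)
  expect_true(is.na(res$fold_change[2])) # 0/0 -> N/A
  expect_equal(res$p[2], 1)
  expect_true(all(res$fdr >= res$p - 1e-12))
})
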