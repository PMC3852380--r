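## Two-group differential testing of count features (binding regions or
## genes) under a negative-binomial model: median-of-ratios size factors,
## method-of-moments dispersions with a mean-dispersion trend, a conditioned
## two-sided exact test on summed group counts, and Benjamini-Hochberg
## correction. Group A is the fold-change numerator throughout.

#' Median-of-ratios size factors
#'
#' For each library j, `s_j` is the median over features of
#' `k_ij / (prod_v k_iv)^(1/m)`, the count divided by the feature's
#' geometric mean across libraries. Features containing any zero are
#' excluded from the median. Size factors put libraries on a common scale:
#' dividing column j by `s_j` makes counts comparable across sequencing
#' depths.
#'
#' @param counts integer matrix (features x libraries) or a
#'   [count_matrix()].
#' @param pseudo_reference if no feature is all-positive the estimator is
#'   undefined; with `pseudo_reference = TRUE` geometric means are computed
#'   over the positive entries of each feature instead (and the median runs
#'   over features with any positive count).
#' @return Named numeric vector of positive size factors, one per library.
#' @export
estimate_size_factors <- function(counts, pseudo_reference = FALSE) {
  k <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (ncol(k) < 1L || nrow(k) < 1L) stop("empty count matrix")
  lk <- log(k)
  loggeo <- rowMeans(lk)
  ok <- is.finite(loggeo)
  if (!any(ok)) {
    if (!pseudo_reference) {
      stop(
        "no feature has all-positive counts; size factors undefined ",
        "(consider pseudo_reference = TRUE)"
      )
    }
    lk[!is.finite(lk)] <- NA
    loggeo <- rowMeans(lk, na.rm = TRUE)
    ok <- is.finite(loggeo)
    if (!any(ok)) stop("all-zero count matrix: size factors undefined")
  }
  geo <- exp(loggeo[ok])
  s <- apply(k[ok, , drop = FALSE], 2, function(col) stats::median(col / geo))
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("degenerate size factor estimate (non-positive median of ratios)")
  }
  s
}

# per-feature method-of-moments dispersion from one group's libraries:
# alpha_i = max(0, (w_i - q_i * mean(1/s)) / q_i^2), with w_i the sample
# variance and q_i the mean of size-factor-normalized counts
.raw_dispersion <- function(k, s) {
  kn <- sweep(k, 2, s, "/")
  q <- rowMeans(kn)
  n <- ncol(kn)
  w <- rowSums((kn - q)^2) / (n - 1)
  a <- (w - q * mean(1 / s)) / q^2
  a[!is.finite(a)] <- 0
  pmax(0, a)
}

# least-squares fit of raw dispersion on a0 + a1/mean over features with
# positive mean; returns the fitted-value function (floored at 0)
.fit_dispersion_trend <- function(q, raw) {
  sel <- q > 0 & is.finite(raw)
  if (sum(sel) < 3L) {
    a <- c(stats::median(raw[sel]) %||% 0, 0)
  } else {
    fit <- lm(raw[sel] ~ I(1 / q[sel]))
    a <- unname(coef(fit))
    a[is.na(a)] <- 0
  }
  function(qq) {
    f <- a[1] + a[2] / qq
    f[!is.finite(f)] <- 0
    pmax(0, f)
  }
}

#' Per-group negative-binomial dispersion estimates
#'
#' Within each group, the per-feature raw dispersion is the
#' method-of-moments excess of the sample variance of normalized counts
#' over shot noise; a mean-dispersion trend `a0 + a1/mean` is then fitted
#' by least squares across features. The dispersion used downstream is the
#' fitted trend value by default (`sharing = "fit-only"`), or the
#' feature-wise maximum of raw and fitted (`sharing = "maximum"`, more
#' conservative), floored at `floor`.
#'
#' @param counts a [count_matrix()] (groups taken from its sample sheet).
#' @param size_factors from [estimate_size_factors()]; estimated when
#'   `NULL`.
#' @param sharing `"fit-only"` or `"maximum"`.
#' @param blind pool all libraries as one group when some group has fewer
#'   than 2 replicates (otherwise that is an error).
#' @param floor lower bound for the final dispersion.
#' @return List with per-group data.frames (`mean`, `raw`, `fitted`,
#'   `final`) plus the size factors used.
#' @export
estimate_dispersions <- function(counts, size_factors = NULL,
                                 sharing = c("fit-only", "maximum"),
                                 blind = FALSE, floor = 1e-8) {
  stopifnot(inherits(counts, "count_matrix"))
  sharing <- match.arg(sharing)
  k <- counts$counts
  grp <- counts$samples$group
  s <- size_factors %||% estimate_size_factors(k)
  groups <- sort(unique(grp))
  small <- groups[vapply(groups, function(g) sum(grp == g) < 2L, logical(1))]
  if (length(small) > 0 && !blind) {
    stop(
      "group(s) with a single replicate: ", paste(small, collapse = ", "),
      " (use blind = TRUE to pool libraries)"
    )
  }
  one <- function(cols) {
    raw <- .raw_dispersion(k[, cols, drop = FALSE], s[cols])
    q <- rowMeans(sweep(k[, cols, drop = FALSE], 2, s[cols], "/"))
    trend <- .fit_dispersion_trend(q, raw)
    fitted <- trend(q)
    final <- switch(sharing,
      "fit-only" = fitted,
      "maximum" = pmax(raw, fitted)
    )
    data.frame(
      mean = q, raw = raw, fitted = fitted,
      final = pmax(final, floor), row.names = rownames(k)
    )
  }
  est <- if (blind && length(small) > 0) {
    pooled <- one(seq_along(grp))
    setNames(rep(list(pooled), length(groups)), groups)
  } else {
    setNames(lapply(groups, function(g) one(which(grp == g))), groups)
  }
  list(groups = est, size_factors = s, sharing = sharing)
}

# conditioned two-sided exact NB p-value for one feature; mu/var describe
# the summed group counts. Above `cap` total counts, a normal approximation
# of the conditional distribution is used.
.exact_test_one <- function(kA, kB, muA, varA, muB, varB, cap = 10000) {
  n <- kA + kB
  if (n == 0L) {
    return(1)
  }
  normal_p <- function() {
    m <- muA + varA / (varA + varB) * (n - muA - muB)
    sd <- sqrt(varA * varB / (varA + varB))
    z <- (abs(kA - m) - 0.5) / sd
    min(1, 2 * pnorm(-z))
  }
  if (n > cap) {
    return(normal_p())
  }
  a <- 0:n
  dens <- function(x, mu, v) {
    if (v <= mu * (1 + 1e-8)) dpois(x, mu) else dnbinom(x, mu = mu, size = mu^2 / (v - mu))
  }
  pr <- dens(a, muA, varA) * dens(n - a, muB, varB)
  tot <- sum(pr)
  if (!is.finite(tot) || tot <= 0) {
    return(normal_p())
  }
  pobs <- pr[kA + 1L]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]) / tot)
}

#' Conditioned two-sided negative-binomial exact test
#'
#' Tests whether the observed split of a feature's total count between the
#' two groups is compatible with equal underlying abundance. Conditional on
#' the total `kA + kB`, the p-value sums the probabilities of all splits
#' `a + b = kA + kB` whose joint NB probability does not exceed that of the
#' observed split, normalized by the total over all splits. Each group's
#' summed count is modeled as NB with the supplied mean and variance
#' (variance is clamped to the Poisson floor, with a warning, if below the
#' mean). For totals above `cap`, a normal approximation of the conditional
#' distribution is used.
#'
#' @param kA,kB summed raw counts in groups A and B.
#' @param muA,varA,muB,varB fitted mean and variance of each group's summed
#'   count under the null of shared abundance.
#' @param cap total-count switch point to the normal approximation.
#' @return p-value in (0, 1]; symmetric under group relabeling; equal to 1
#'   when the observed split attains the modal probability.
#' @export
nb_exact_test <- function(kA, kB, muA, varA, muB, varB, cap = 10000) {
  stopifnot(
    length(kA) == 1L, length(kB) == 1L,
    kA >= 0, kB >= 0, muA > 0, muB > 0
  )
  if (varA < muA || varB < muB) {
    warning("variance below mean (underdispersion): clamped to Poisson")
  }
  .exact_test_one(kA, kB, muA, max(varA, muA), muB, max(varB, muB), cap = cap)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]); values are clipped at
#' 1 and returned in input order. Thresholding the result at `q`
#' reproduces the BH rejection set at level `q`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (FDR), same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be numeric in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Fold change between group means
#'
#' `mean_a / mean_b`; undefined (NA, printed `"N/A"`) when the denominator
#' is 0.
#'
#' @param mean_a,mean_b normalized group means (group A is the numerator).
#' @return Numeric vector; `NA` where `mean_b == 0`.
#' @export
fold_change <- function(mean_a, mean_b) {
  ifelse(mean_b == 0, NA_real_, mean_a / mean_b)
}

#' Two-group differential test of a count matrix
#'
#' The full negative-binomial pipeline: size factors
#' ([estimate_size_factors()]), per-group dispersions
#' ([estimate_dispersions()]), the conditioned exact test per feature
#' ([nb_exact_test()]), and BH correction ([bh_adjust()]). Group means are
#' reported on the normalized scale averaged over libraries; fold change is
#' `mean_A / mean_B` (`NA` when `mean_B` is 0); a direction (`"A-up"` /
#' `"B-up"`) is assigned only at strict `fdr < q`, otherwise `"none"`.
#'
#' @param counts a [count_matrix()] with both groups represented by >= 2
#'   libraries.
#' @param q FDR significance threshold (strict `<`).
#' @param sharing,blind,cap passed to [estimate_dispersions()] and
#'   [nb_exact_test()].
#' @return A `data.frame` (class `differential_table`) with columns
#'   `feature`, `mean_A`, `mean_B`, `fold_change`, `p`, `fdr`,
#'   `direction`; size factors attached as attribute `size_factors`.
#' @export
run_differential <- function(counts, q = 0.05, sharing = c("fit-only", "maximum"),
                             blind = FALSE, cap = 10000) {
  stopifnot(inherits(counts, "count_matrix"))
  sharing <- match.arg(sharing)
  k <- counts$counts
  grp <- counts$samples$group
  if (!all(c("A", "B") %in% grp)) stop("both groups 'A' and 'B' required")
  A <- grp == "A"
  B <- grp == "B"
  if (sum(A) < 2L || sum(B) < 2L) {
    if (!blind) stop("each group needs >= 2 libraries for testing (or blind = TRUE)")
  }
  s <- estimate_size_factors(k)
  disp <- estimate_dispersions(counts,
    size_factors = s, sharing = sharing, blind = blind
  )
  kn <- sweep(k, 2, s, "/")
  q0 <- rowMeans(kn)
  mean_A <- rowMeans(kn[, A, drop = FALSE])
  mean_B <- rowMeans(kn[, B, drop = FALSE])
  aA <- disp$groups[["A"]]$final
  aB <- disp$groups[["B"]]$final
  SA <- sum(s[A])
  SB <- sum(s[B])
  SA2 <- sum(s[A]^2)
  SB2 <- sum(s[B]^2)
  kA <- as.integer(rowSums(k[, A, drop = FALSE]))
  kB <- as.integer(rowSums(k[, B, drop = FALSE]))
  muA <- q0 * SA
  muB <- q0 * SB
  varA <- pmax(muA + aA * q0^2 * SA2, muA)
  varB <- pmax(muB + aB * q0^2 * SB2, muB)
  p <- vapply(seq_len(nrow(k)), function(i) {
    if (q0[i] <= 0) {
      return(1)
    }
    .exact_test_one(kA[i], kB[i], muA[i], varA[i], muB[i], varB[i], cap = cap)
  }, numeric(1))
  fdr <- bh_adjust(p)
  direction <- rep("none", nrow(k))
  sig <- fdr < q
  direction[sig & mean_A > mean_B] <- "A-up"
  direction[sig & mean_B > mean_A] <- "B-up"
  res <- data.frame(
    feature = rownames(k),
    mean_A = mean_A, mean_B = mean_B,
    fold_change = fold_change(mean_A, mean_B),
    p = p, fdr = fdr, direction = direction,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(res) <- c("differential_table", "data.frame")
  attr(res, "size_factors") <- s
  attr(res, "q") <- q
  bc_log(
    "run_differential: %d features tested, %d significant at FDR < %g (%d A-up, %d B-up)",
    nrow(res), sum(sig), q, sum(direction == "A-up"), sum(direction == "B-up")
  )
  res
}

#' Direction proportions among significant features
#'
#' Summarizes a differential table: how many significant features are
#' up in each group, and as percentages of the significant set.
#'
#' @param table a `differential_table` from [run_differential()].
#' @return List with `n_significant`, `n_A_up`, `n_B_up`, `pct_A_up`,
#'   `pct_B_up`.
#' @export
direction_proportions <- function(table) {
  n_A <- sum(table$direction == "A-up")
  n_B <- sum(table$direction == "B-up")
  n <- n_A + n_B
  list(
    n_significant = n, n_A_up = n_A, n_B_up = n_B,
    pct_A_up = if (n > 0) 100 * n_A / n else NA_real_,
    pct_B_up = if (n > 0) 100 * n_B / n else NA_real_
  )
}
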