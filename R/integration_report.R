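## Integration of differential binding with differential expression:
## gene/BR pair classification, the quadrant concordance chi-square,
## the on/off expression rule, clustering-ready matrices, and the
## end-to-end synthetic pipeline with its report bundle.

QUADRANTS <- c("A+/A+", "A+/B+", "B+/A+", "B+/B+")

#' Join gene/BR pairs with both differential tables
#'
#' Each associated (gene, BR) pair is classified by strict `FDR < q` on
#' each axis: `both-significant`, `binding-only`, `expression-only` or
#' `neither`. Pairs significant on both axes get a direction quadrant,
#' binding direction first (`"A+/B+"` = binding up in group A, expression
#' up in group B).
#'
#' @param pairs `data.frame` from [associate_regions()] (`gene_id`,
#'   `br_id`, `tss_distance`).
#' @param diff_binding,diff_expression `differential_table`s from
#'   [run_differential()], keyed by BR id and gene id respectively.
#' @param q FDR significance threshold (strict `<`) applied to both axes.
#' @return `data.frame` with the pair keys, TSS distance, both fold
#'   changes and FDRs, `class` and `quadrant` (`NA` unless
#'   both-significant).
#' @export
join_pairs <- function(pairs, diff_binding, diff_expression, q = 0.05) {
  ib <- match(pairs$br_id, diff_binding$feature)
  if (anyNA(ib)) {
    stop("pair references unknown BR: ", pairs$br_id[which(is.na(ib))[1]])
  }
  ie <- match(pairs$gene_id, diff_expression$feature)
  if (anyNA(ie)) {
    stop("pair references unknown gene: ", pairs$gene_id[which(is.na(ie))[1]])
  }
  dir_of <- function(tbl, i) {
    ifelse(tbl$mean_A[i] > tbl$mean_B[i], "A+",
      ifelse(tbl$mean_B[i] > tbl$mean_A[i], "B+", NA)
    )
  }
  sig_b <- diff_binding$fdr[ib] < q
  sig_e <- diff_expression$fdr[ie] < q
  class <- ifelse(sig_b & sig_e, "both-significant",
    ifelse(sig_b, "binding-only",
      ifelse(sig_e, "expression-only", "neither")
    )
  )
  quadrant <- rep(NA_character_, nrow(pairs))
  both <- which(sig_b & sig_e)
  quadrant[both] <- paste0(
    dir_of(diff_binding, ib[both]), "/", dir_of(diff_expression, ie[both])
  )
  quadrant[!quadrant %in% QUADRANTS] <- NA
  out <- data.frame(
    gene_id = pairs$gene_id, br_id = pairs$br_id,
    tss_distance = pairs$tss_distance,
    binding_fc = diff_binding$fold_change[ib],
    binding_fdr = diff_binding$fdr[ib],
    expression_fc = diff_expression$fold_change[ie],
    expression_fdr = diff_expression$fdr[ie],
    class = class, quadrant = quadrant,
    stringsAsFactors = FALSE
  )
  tab <- table(factor(class, levels = c(
    "both-significant", "binding-only", "expression-only", "neither"
  )))
  bc_log(
    "join_pairs: %d pairs (%s)", nrow(out),
    paste(names(tab), tab, sep = "=", collapse = ", ")
  )
  out
}

#' Quadrant counts of both-significant pairs
#'
#' @param pair_records from [join_pairs()].
#' @return Named integer vector over the four quadrants
#'   (binding/expression direction), in the order `A+/A+`, `A+/B+`,
#'   `B+/A+`, `B+/B+`.
#' @export
quadrant_counts <- function(pair_records) {
  qd <- pair_records$quadrant[pair_records$class == "both-significant"]
  as.integer(table(factor(qd, levels = QUADRANTS))) |>
    setNames(QUADRANTS)
}

#' Quadrant concordance chi-square (goodness of fit, df = 3)
#'
#' Compares the observed quadrant counts of dual-significant gene/BR pairs
#' with the counts expected if binding and expression directions were
#' independent: the expected frequency of each quadrant is the product of
#' the supplied binding and expression A-up marginal proportions (which
#' may come from the genome-wide differential tables rather than from the
#' pairs themselves), the expected count is `n` times that frequency, and
#' the statistic is the df = 3 goodness-of-fit chi-square.
#'
#' Contributions `(o - e)^2 / e` are computed from the unrounded expected
#' counts; display columns additionally give the integer-truncated
#' expected counts and the contributions recomputed from them, the
#' convention of printed summary tables.
#'
#' @param observed 4 quadrant counts in the order `A+/A+`, `A+/B+`,
#'   `B+/A+`, `B+/B+` (binding direction first).
#' @param p_bind,p_expr marginal proportions of A-up binding and A-up
#'   expression, in (0, 1).
#' @return Object of class `concordance_result`: per-quadrant table
#'   (observed, expected frequency/count, display counts, contributions),
#'   `chi2`, `df = 3`, `p`, and the display-statistic `chi2_display`.
#' @export
concordance_chi2 <- function(observed, p_bind, p_expr) {
  if (length(observed) != 4L || any(observed < 0)) {
    stop("observed must be 4 nonnegative quadrant counts")
  }
  n <- sum(observed)
  if (n <= 0) stop("no observed pairs")
  if (p_bind <= 0 || p_bind >= 1 || p_expr <= 0 || p_expr >= 1) {
    stop("marginal proportions must lie strictly inside (0, 1)")
  }
  freq <- c(
    p_bind * p_expr, p_bind * (1 - p_expr),
    (1 - p_bind) * p_expr, (1 - p_bind) * (1 - p_expr)
  )
  expected <- n * freq
  if (any(expected == 0)) stop("expected count of 0")
  contrib <- (observed - expected)^2 / expected
  exp_disp <- trunc(expected)
  contrib_disp <- (observed - exp_disp)^2 / exp_disp
  chi2 <- sum(contrib)
  tab <- data.frame(
    quadrant = QUADRANTS,
    expected_freq = freq,
    expected_count = expected,
    expected_count_display = exp_disp,
    observed = as.integer(observed),
    contribution = contrib,
    contribution_display = contrib_disp,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      table = tab, n = n, p_bind = p_bind, p_expr = p_expr,
      chi2 = chi2, chi2_display = sum(contrib_disp), df = 3L,
      p = pchisq(chi2, df = 3, lower.tail = FALSE)
    ),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("Binding/expression quadrant concordance (goodness of fit)\n")
  tab <- x$table
  tab$expected_freq <- sprintf("%.1f%%", 100 * tab$expected_freq)
  tab$expected_count <- sprintf("%.2f", tab$expected_count)
  tab$contribution <- sprintf("%.2f", tab$contribution)
  tab$contribution_display <- sprintf("%.2f", tab$contribution_display)
  print(tab, row.names = FALSE)
  cat(sprintf(
    "n = %d, chi-square = %.2f (display %.2f), d.f. = %d, P = %.3g\n",
    x$n, x$chi2, x$chi2_display, x$df, x$p
  ))
  invisible(x)
}

#' Flag on/off genes
#'
#' A significantly differential gene is "on/off" toward its up group when
#' its mean normalized count in the other (minor) group falls strictly
#' below `threshold` — expression effectively restricted to one group.
#'
#' @param diff_expression a `differential_table`.
#' @param threshold minor-group normalized-mean cutoff (strict `<`).
#' @param q FDR significance threshold (strict `<`).
#' @return `data.frame` with `feature`, `direction`, `onoff`.
#' @export
onoff_classify <- function(diff_expression, threshold = 5, q = 0.05) {
  sig <- diff_expression$fdr < q
  a_up <- sig & diff_expression$mean_A > diff_expression$mean_B
  b_up <- sig & diff_expression$mean_B > diff_expression$mean_A
  onoff <- (a_up & diff_expression$mean_B < threshold) |
    (b_up & diff_expression$mean_A < threshold)
  out <- data.frame(
    feature = diff_expression$feature,
    direction = ifelse(a_up, "A-up", ifelse(b_up, "B-up", "none")),
    onoff = onoff, stringsAsFactors = FALSE
  )
  bc_log(
    "onoff_classify: %d significant genes, %d on/off (threshold %g)",
    sum(sig), sum(onoff), threshold
  )
  out
}

#' Prepare a count matrix for clustering
#'
#' Three steps: elementwise `log(count + 1)`; per-library (column)
#' centering and unit-variance scaling (columns with zero spread become
#' zeros, with a warning); per-feature (row) scaling to unit sum of
#' squares (all-zero rows are left as zeros).
#'
#' @param matrix nonnegative numeric matrix, features x libraries, with at
#'   least 2 columns.
#' @return The transformed matrix.
#' @export
cluster_prep <- function(matrix) {
  m <- as.matrix(matrix)
  if (ncol(m) < 2L) stop("per-library standardization needs >= 2 columns")
  if (any(m < 0)) stop("matrix must be nonnegative")
  x <- log(m + 1)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  if (any(sd == 0)) {
    warning("constant column(s): standardized to zero")
  }
  x <- sweep(x, 2, mu, "-")
  x <- sweep(x, 2, ifelse(sd == 0, 1, sd), "/")
  x[, sd == 0] <- 0
  ss <- sqrt(rowSums(x^2))
  x <- sweep(x, 1, ifelse(ss == 0, 1, ss), "/")
  x
}

#' Run the full pipeline on a synthetic dataset
#'
#' End to end: simulate ([simulate_dataset()]), merge peaks into BRs and
#' filter by support, attach the NB count matrices, test both assays
#' differentially ([run_differential()]), build regulatory domains and
#' associate BRs with genes, join and classify pairs, compute the quadrant
#' concordance chi-square (marginals default to the A-up proportions among
#' significant features of the two differential tables), flag on/off
#' genes, and prepare clustering matrices. Recovery against the planted
#' truth is summarized alongside.
#'
#' Binding counts are carried per planted BR: merged-and-filtered BRs map
#' one-to-one onto planted BRs (planted regions are spaced beyond the peak
#' jitter), so surviving BRs keep their planted feature ids.
#'
#' @param cfg a [sim_config()].
#' @param fdr FDR threshold for both axes (strict `<`).
#' @param min_lines minimum cell-line support for BRs.
#' @param onoff_threshold minor-group mean cutoff for on/off genes.
#' @param marginals optional `c(p_bind, p_expr)` for the chi-square;
#'   defaults to the genome-wide A-up direction proportions.
#' @param outdir optional directory: when given, the result bundle is
#'   written there via [write_report()].
#' @return Object of class `pipeline_result`.
#' @export
run_pipeline <- function(cfg = sim_config(), fdr = 0.05, min_lines = 2L,
                         onoff_threshold = 5, marginals = NULL,
                         outdir = NULL) {
  sim <- simulate_dataset(cfg)
  brs <- merge_peaks(sim$peaks)
  brs_f <- filter_by_support(brs, min_lines = min_lines)

  ## map surviving merged BRs back to planted BRs to pick up their counts
  hits <- GenomicRanges::findOverlaps(brs_f, sim$brs, ignore.strand = TRUE)
  planted_id <- rep(NA_character_, length(brs_f))
  planted_id[queryHits(hits)] <- names(sim$brs)[subjectHits(hits)]
  keep <- !is.na(planted_id) & !duplicated(planted_id)
  brs_f <- brs_f[keep]
  mcols(brs_f)$br_id <- planted_id[keep]
  mcols(brs_f)$name <- planted_id[keep]
  names(brs_f) <- planted_id[keep]

  cm_b <- sim$counts_binding
  cm_b$counts <- cm_b$counts[names(brs_f), , drop = FALSE]
  cm_e <- sim$counts_expression

  diff_b <- run_differential(cm_b, q = fdr)
  diff_e <- run_differential(cm_e, q = fdr)

  domains <- build_domains(sim$genes)
  pairs <- associate_regions(brs_f, domains)
  pair_records <- join_pairs(pairs, diff_b, diff_e, q = fdr)
  qc <- quadrant_counts(pair_records)

  prop_b <- direction_proportions(diff_b)
  prop_e <- direction_proportions(diff_e)
  concordance <- NULL
  if (is.null(marginals)) {
    if (prop_b$n_significant > 0 && prop_e$n_significant > 0 &&
      prop_b$n_A_up > 0 && prop_b$n_B_up > 0 &&
      prop_e$n_A_up > 0 && prop_e$n_B_up > 0) {
      marginals <- c(prop_b$pct_A_up / 100, prop_e$pct_A_up / 100)
    }
  }
  if (!is.null(marginals) && sum(qc) > 0) {
    concordance <- concordance_chi2(qc, marginals[1], marginals[2])
  } else {
    bc_log("concordance stage skipped: empty significant set or degenerate marginals")
  }

  onoff <- onoff_classify(diff_e, threshold = onoff_threshold, q = fdr)

  cluster <- list(binding = NULL, expression = NULL)
  norm_sig <- function(cm, tbl) {
    sig <- tbl$feature[tbl$direction != "none"]
    if (length(sig) < 2L) {
      return(NULL)
    }
    kn <- sweep(cm$counts, 2, attr(tbl, "size_factors"), "/")
    cluster_prep(kn[sig, , drop = FALSE])
  }
  cluster$binding <- norm_sig(cm_b, diff_b)
  cluster$expression <- norm_sig(cm_e, diff_e)

  ## recovery vs the planted truth
  truth <- sim$truth
  recov <- function(tbl, kind) {
    tt <- truth[match(tbl$feature, truth$feature_id), ]
    stopifnot(all(tt$kind == kind))
    sig <- tbl$direction != "none"
    list(
      sensitivity = if (any(tt$is_diff)) mean(sig[tt$is_diff]) else NA_real_,
      observed_fdr = if (any(sig)) mean(!tt$is_diff[sig]) else NA_real_
    )
  }
  res <- list(
    cfg = cfg, sim = sim, brs = brs_f,
    diff_binding = diff_b, diff_expression = diff_e,
    pairs = pair_records, quadrants = qc, concordance = concordance,
    onoff = onoff, cluster = cluster,
    recovery = list(
      binding = recov(diff_b, "BR"),
      expression = recov(diff_e, "gene")
    ),
    summary = list(
      n_peaks = sum(vapply(sim$peaks, length, 0L)),
      n_brs_merged = length(brs),
      n_brs = length(brs_f),
      n_genes = length(sim$genes),
      n_diff_brs = sum(diff_b$direction != "none"),
      n_de_genes = sum(diff_e$direction != "none"),
      n_pairs = nrow(pair_records),
      n_both_significant = sum(qc),
      n_onoff = sum(onoff$onoff)
    )
  )
  class(res) <- "pipeline_result"
  if (!is.null(outdir)) write_report(res, outdir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("Integrative differential binding/expression pipeline\n")
  cat(sprintf(
    "  peaks: %d  merged BRs: %d  BRs (support >= 2): %d\n",
    s$n_peaks, s$n_brs_merged, s$n_brs
  ))
  cat(sprintf(
    "  differential BRs: %d   differential genes: %d (on/off: %d)\n",
    s$n_diff_brs, s$n_de_genes, s$n_onoff
  ))
  cat(sprintf(
    "  gene/BR pairs: %d, dual-significant: %d\n",
    s$n_pairs, s$n_both_significant
  ))
  if (!is.null(x$concordance)) {
    cat(sprintf(
      "  concordance chi-square = %.2f (d.f. = %d), P = %.3g\n",
      x$concordance$chi2, x$concordance$df, x$concordance$p
    ))
  }
  invisible(x)
}

#' Write the pipeline result bundle
#'
#' A deterministic file set: BR BED, both differential tables, the pair
#' table, concordance table, on/off table, clustering matrices, the truth
#' ledger, and a JSON run manifest (config, seed, package version, summary
#' counts). Reruns with the same seed are byte-identical. When the
#' significant set is empty, tables carry headers only and the concordance
#' file is omitted with a notice.
#'
#' @param result from [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(result$brs, file.path(dir, "binding_regions.bed"))
  write_results(result$diff_binding, file.path(dir, "differential_binding.tsv"))
  write_results(result$diff_expression, file.path(dir, "differential_expression.tsv"))
  write_results(result$pairs, file.path(dir, "pairs.tsv"))
  write.table(result$onoff, file.path(dir, "onoff.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(result$concordance)) {
    ct <- result$concordance$table
    for (cl in c("expected_freq", "expected_count", "contribution", "contribution_display")) {
      ct[[cl]] <- sprintf("%.6g", ct[[cl]])
    }
    write.table(ct, file.path(dir, "concordance.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  } else {
    bc_log("write_report: concordance table skipped (stage not run)")
  }
  for (assay in c("binding", "expression")) {
    m <- result$cluster[[assay]]
    if (!is.null(m)) {
      df <- data.frame(feature = rownames(m), signif(m, 8), check.names = FALSE)
      write.table(df, file.path(dir, paste0("cluster_", assay, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
  }
  write.table(result$sim$truth, file.path(dir, "truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  manifest <- list(
    package = "bindconcord",
    version = as.character(packageVersion("bindconcord")),
    seed = result$cfg$seed,
    config = result$cfg[setdiff(names(result$cfg), "genome")],
    genome = result$cfg$genome,
    summary = result$summary,
    concordance = if (!is.null(result$concordance)) {
      list(
        chi2 = result$concordance$chi2, df = result$concordance$df,
        p = result$concordance$p
      )
    }
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
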