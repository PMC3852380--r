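## Shared fixtures and brute-force oracles, independent of the interval
## machinery used by the package (plain data.frames in 0-based half-open
## coordinates, quadratic all-pairs scans, fixed-point closure merging).

options(bindconcord.verbose = FALSE)
suppressPackageStartupMessages(library(GenomicRanges))

# random interval set as a data.frame (0-based half-open)
random_intervals0 <- function(n, chrom_len = 1e5, width = c(10, 500),
                              chroms = "chr1") {
  chrom <- sample(chroms, n, replace = TRUE)
  w <- floor(runif(n, width[1], width[2]))
  s <- floor(runif(n, 0, chrom_len - w))
  data.frame(chrom = chrom, start0 = s, end0 = s + w)
}

df_to_granges <- function(df, ...) {
  gr <- GRanges(df$chrom, IRanges(df$start0 + 1, df$end0))
  extra <- list(...)
  for (nm in names(extra)) mcols(gr)[[nm]] <- extra[[nm]]
  gr
}

granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(seqnames(gr)),
    start0 = start(gr) - 1, end0 = end(gr)
  )
}

# >= 1 bp overlap in half-open coordinates
overlaps0 <- function(a, b) {
  a$chrom == b$chrom & a$start0 < b$end0 & b$start0 < a$end0
}

# overlap-or-abutting relation used for merging
touches0 <- function(a, b) {
  a$chrom == b$chrom & a$start0 <= b$end0 & b$start0 <= a$end0
}

# brute-force merge by fixed-point pairwise closure over the touching
# relation; returns merged spans plus per-span member index lists
bf_merge <- function(df) {
  n <- nrow(df)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (comp[i] != comp[j] &&
          touches0(df[i, , drop = FALSE], df[j, , drop = FALSE])) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(cc) {
    mem <- which(comp == cc)
    data.frame(
      chrom = df$chrom[mem[1]],
      start0 = min(df$start0[mem]), end0 = max(df$end0[mem]),
      n_members = length(mem),
      members = I(list(mem))
    )
  }))
  out[order(out$chrom, out$start0), , drop = FALSE]
}

# all-pairs overlap counting: rows of `a` against rows of `b`
bf_count_overlaps <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    sum(vapply(seq_len(nrow(b)), function(j) {
      overlaps0(a[i, , drop = FALSE], b[j, , drop = FALSE])
    }, logical(1)))
  }, integer(1))
}

# quick count_matrix from a bare matrix with a 2-group sheet
make_cm <- function(k, groups, assay = "binding") {
  colnames(k) <- colnames(k) %||% paste0("lib", seq_len(ncol(k)))
  rownames(k) <- rownames(k) %||% paste0("f", seq_len(nrow(k)))
  sheet <- sample_sheet(
    library = colnames(k),
    cell_line = colnames(k),
    group = groups,
    assay = assay,
    replicate = 1L
  )
  count_matrix(k, sheet)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# NB central moment by direct enumeration (oracle for moment checks)
nb_central_moment <- function(order, mu, alpha) {
  size <- 1 / alpha
  kmax <- qnbinom(1e-14, size = size, mu = mu, lower.tail = FALSE) + 10
  k <- 0:kmax
  sum((k - mu)^order * dnbinom(k, size = size, mu = mu))
}

# simulate a null NB count_matrix through the generator's own machinery
null_binding_counts <- function(n_features, seed, alpha0 = 0.05, alpha1 = 2,
                                meanlog = 5, sdlog = 1.2) {
  cfg <- sim_config(
    n_brs = n_features, n_genes = 10, frac_diff = c(binding = 0, expression = 0),
    frac_singleton = 0, alpha0 = alpha0, alpha1 = alpha1,
    baseline_meanlog = meanlog, baseline_sdlog = sdlog, seed = seed
  )
  truth <- data.frame(
    feature_id = sprintf("f%05d", seq_len(n_features)),
    kind = "BR", log2fc = 0,
    baseline = {
      set.seed(seed)
      rlnorm(n_features, meanlog, sdlog)
    }
  )
  truth_g <- data.frame(
    feature_id = "g1", kind = "gene", log2fc = 0, baseline = 100
  )
  simulate_counts(cfg, rbind(truth, truth_g))$binding
}
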