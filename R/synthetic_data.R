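## Seeded synthetic-data generator emulating the two-group, multi-cell-line
## study design: a gene annotation, per-cell-line peak sets with
## group-specific occupancy, NB-distributed binding/expression counts with
## library size factors and a mean-linked dispersion, planted fold changes,
## on/off genes, and a ground-truth ledger for recovery tests.

# sub-seeds per stage so each stage is reproducible independent of order;
# kept below 2^31 - 1
.stage_seed <- function(seed, stage) {
  offs <- c(
    annotation = 1, truth = 2, occupancy = 3,
    size_factors = 4, counts_binding = 5, counts_expression = 6
  )
  as.integer((abs(as.numeric(seed)) * 97 + offs[[stage]] * 10007) %% 2147483647)
}

#' Simulation configuration
#'
#' Defaults mirror the emulated study design: 8 cell lines in two groups of
#' 4 (group A = the high-occupancy, ABC-like group), one pooled binding
#' library per cell line and 2 expression replicates per cell line,
#' log-normal baseline abundances, NB dispersion `alpha0 + alpha1/mean`,
#' 34% of binding regions and 7.4% of genes planted differential (56% and
#' 81% of them A-up, respectively), planted |log2 fold changes| uniform on
#' \[1.5, 6\], 61% of A-up (7% of B-up) differential genes "on/off" with
#' group-minor mean below 1, and library size factors log-uniform on
#' \[0.5, 2\].
#'
#' @param n_genes,n_brs numbers of genes and planted binding regions.
#' @param n_cell_lines named vector, cell lines per group.
#' @param replicates named vector, libraries per cell line and assay.
#' @param genome data.frame with `chrom` and `length` (bp).
#' @param min_spacing minimum TSS spacing, bp.
#' @param gene_width range of gene body widths, bp (capped at
#'   `min_spacing / 2` so gene bodies cannot overlap).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline abundance.
#' @param alpha0,alpha1 dispersion model `alpha0 + alpha1 / mean`.
#' @param frac_diff named fractions of differential features per assay.
#' @param frac_up_A named fractions of differential features that are A-up.
#' @param lfc_range planted |log2 fold change| range.
#' @param frac_onoff named (A, B): fraction of differential genes in each
#'   direction that are on/off.
#' @param onoff_minor_mean range of the on/off minor-group mean (< 1).
#' @param size_factor_range library size factors, log-uniform.
#' @param br_width planted BR width range, bp.
#' @param br_near_tss_frac fraction of BRs placed near a gene TSS.
#' @param br_tss_window TSS placement window half-width, bp.
#' @param frac_linked fraction of differential BRs planted inside the
#'   regulatory window of a differential gene with the gene's direction
#'   (the concordant regulation the integration stage should recover).
#' @param occ_major,occ_minor,occ_shared per-cell-line peak occupancy
#'   probabilities (up-group / down-group of differential BRs; both groups
#'   of shared BRs).
#' @param frac_singleton extra BRs present in exactly one cell line, as a
#'   fraction of `n_brs` (exercise the support filter).
#' @param jitter peak-edge jitter half-width, bp (never crosses adjacent
#'   planted BRs, which are kept >= `min_br_gap` apart).
#' @param min_br_gap minimum gap between planted BRs, bp.
#' @param seed RNG seed for the whole run.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 600, n_brs = 400,
                       n_cell_lines = c(A = 4, B = 4),
                       replicates = c(binding = 1, expression = 2),
                       genome = data.frame(
                         chrom = c("chr1", "chr2"),
                         length = c(120e6, 80e6)
                       ),
                       min_spacing = 30000,
                       gene_width = c(2000, 15000),
                       baseline_meanlog = 5, baseline_sdlog = 1.5,
                       alpha0 = 0.05, alpha1 = 2,
                       frac_diff = c(binding = 0.34, expression = 0.074),
                       frac_up_A = c(binding = 0.56, expression = 0.81),
                       lfc_range = c(1.5, 6),
                       frac_onoff = c(A = 0.61, B = 0.07),
                       onoff_minor_mean = c(0.1, 0.8),
                       size_factor_range = c(0.5, 2),
                       br_width = c(200, 800),
                       br_near_tss_frac = 0.8, br_tss_window = 20000,
                       frac_linked = 0.7,
                       occ_major = 0.95, occ_minor = 0.25, occ_shared = 0.9,
                       frac_singleton = 0.05,
                       jitter = 20, min_br_gap = 100,
                       seed = 1L) {
  cfg <- as.list(environment())
  fracs <- c(
    cfg$frac_diff, cfg$frac_up_A, cfg$frac_onoff, cfg$frac_singleton,
    cfg$br_near_tss_frac, cfg$frac_linked,
    cfg$occ_major, cfg$occ_minor, cfg$occ_shared
  )
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (any(cfg$size_factor_range <= 0) || any(cfg$lfc_range < 0) ||
    cfg$alpha0 < 0 || cfg$alpha1 < 0) {
    stop("means/size factors must be positive and dispersions nonnegative")
  }
  if (cfg$jitter * 2 >= cfg$min_br_gap) {
    stop("min_br_gap must exceed twice the peak jitter")
  }
  if (cfg$n_genes < 0 || cfg$n_brs < 0) stop("negative feature counts")
  structure(cfg, class = "sim_config")
}

#' Cell line ids of a simulation configuration
#' @param cfg a [sim_config()].
#' @return Named character vector of cell line ids; names give the group.
#' @export
sim_cell_lines <- function(cfg) {
  lines <- unlist(lapply(names(cfg$n_cell_lines), function(g) {
    setNames(
      paste0("line", g, seq_len(cfg$n_cell_lines[[g]])),
      rep(g, cfg$n_cell_lines[[g]])
    )
  }))
  lines
}

#' Sample sheet implied by a simulation configuration
#' @param cfg a [sim_config()].
#' @param assay `"binding"` or `"expression"`.
#' @return A [sample_sheet()] `data.frame`.
#' @export
sim_sample_sheet <- function(cfg, assay = c("binding", "expression")) {
  assay <- match.arg(assay)
  lines <- sim_cell_lines(cfg)
  reps <- cfg$replicates[[assay]]
  sample_sheet(
    library = paste0(
      rep(lines, each = reps), "_", substr(assay, 1, 4), "_r",
      rep(seq_len(reps), length(lines))
    ),
    cell_line = rep(lines, each = reps),
    group = rep(names(lines), each = reps),
    assay = assay,
    replicate = rep(seq_len(reps), length(lines))
  )
}

#' Simulate a gene annotation
#'
#' Genes are packed per chromosome with pairwise TSS gaps of at least
#' `min_spacing` (TSS positions otherwise uniform), both strands
#' represented, gene bodies non-overlapping. Deterministic for a fixed
#' config seed.
#'
#' @param cfg a [sim_config()].
#' @return `GRanges` of gene bodies with `gene_id`, strands set,
#'   `seqlengths` from the config genome.
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.stage_seed(cfg$seed, "annotation"))
  genome <- cfg$genome
  sl <- setNames(genome$length, genome$chrom)
  if (cfg$n_genes == 0) {
    gr <- GenomicRanges::GRanges(gene_id = character(0))
    suppressWarnings(seqlengths(gr) <- sl[seqlevels(gr)])
    return(gr)
  }
  n_per <- pmax(1, round(cfg$n_genes * genome$length / sum(genome$length)))
  n_per[length(n_per)] <- cfg$n_genes - sum(n_per[-length(n_per)])
  edge <- cfg$min_spacing
  rows <- Map(function(ch, len, n) {
    if (n <= 0) {
      return(NULL)
    }
    avail <- len - 2 * edge - (n - 1) * cfg$min_spacing
    if (avail <= 0) {
      stop("infeasible packing: ", n, " genes at spacing ", cfg$min_spacing,
        " exceed ", ch,
        call. = FALSE
      )
    }
    tss0 <- edge + sort(runif(n, 0, avail)) + (seq_len(n) - 1) * cfg$min_spacing
    tss0 <- floor(tss0)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    if (n >= 2 && length(unique(strand)) == 1L) {
      strand[n] <- setdiff(c("+", "-"), strand[1])
    }
    w <- floor(runif(n, cfg$gene_width[1], min(cfg$gene_width[2], cfg$min_spacing / 2)))
    start0 <- ifelse(strand == "+", tss0, tss0 - w + 1)
    end0 <- ifelse(strand == "+", tss0 + w, tss0 + 1)
    data.frame(chrom = ch, start0 = start0, end0 = end0, strand = strand)
  }, genome$chrom, genome$length, n_per)
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start0), , drop = FALSE]
  df$gene_id <- sprintf("g%04d", seq_len(nrow(df)))
  gr <- GenomicRanges::GRanges(df$chrom,
    IRanges::IRanges(df$start0 + 1, df$end0),
    strand = df$strand, gene_id = df$gene_id
  )
  names(gr) <- df$gene_id
  suppressWarnings(seqlengths(gr) <- sl[seqlevels(gr)])
  gr
}

# Plant the ground truth: differential flags, directions, planted log2
# fold changes, baselines, on/off genes, BR placement and gene linkage.
# Returns list(truth = data.frame, brs = GRanges).
.plant_truth <- function(cfg, genes) {
  set.seed(.stage_seed(cfg$seed, "truth"))
  n_g <- length(genes)

  ## ---- genes ----
  g_diff <- rep(FALSE, n_g)
  n_diff_g <- round(cfg$frac_diff[["expression"]] * n_g)
  g_diff[sample(n_g, n_diff_g)] <- TRUE
  g_dir <- rep("none", n_g)
  di <- which(g_diff)
  n_up <- round(cfg$frac_up_A[["expression"]] * n_diff_g)
  up <- di[sample(length(di), n_up)]
  g_dir[up] <- "A-up"
  g_dir[setdiff(di, up)] <- "B-up"
  baseline <- rlnorm(n_g, cfg$baseline_meanlog, cfg$baseline_sdlog)
  lfc <- numeric(n_g)
  mag <- runif(n_g, cfg$lfc_range[1], cfg$lfc_range[2])
  lfc[g_dir == "A-up"] <- mag[g_dir == "A-up"]
  lfc[g_dir == "B-up"] <- -mag[g_dir == "B-up"]
  onoff <- rep(FALSE, n_g)
  for (side in c("A", "B")) {
    cand <- which(g_dir == paste0(side, "-up"))
    n_oo <- round(cfg$frac_onoff[[side]] * length(cand))
    if (n_oo > 0) onoff[cand[sample(length(cand), n_oo)]] <- TRUE
  }
  ## on/off: minor-group mean < 1 by construction
  if (any(onoff)) {
    minor <- runif(sum(onoff), cfg$onoff_minor_mean[1], cfg$onoff_minor_mean[2])
    major <- pmax(baseline[onoff], 20)
    baseline[onoff] <- sqrt(major * minor)
    lfc[onoff] <- sign(lfc[onoff]) * log2(major / minor)
  }
  gene_truth <- data.frame(
    feature_id = mcols(genes)$gene_id,
    kind = "gene", is_diff = g_diff, direction = g_dir,
    log2fc = lfc, baseline = baseline, onoff = onoff,
    linked_gene = NA_character_, stringsAsFactors = FALSE
  )

  ## ---- binding regions ----
  n_b <- cfg$n_brs
  n_single <- round(cfg$frac_singleton * n_b)
  n_tot <- n_b + n_single
  b_diff <- c(rep(FALSE, n_tot))
  if (n_b > 0) {
    b_diff[sample(n_b, round(cfg$frac_diff[["binding"]] * n_b))] <- TRUE
  }
  b_dir <- rep("none", n_tot)
  b_link <- rep(NA_character_, n_tot)
  dbi <- which(b_diff)
  diff_genes <- which(g_diff)
  n_linked <- if (length(diff_genes) > 0) round(cfg$frac_linked * length(dbi)) else 0
  linked <- if (n_linked > 0) dbi[sample(length(dbi), n_linked)] else integer(0)
  if (length(linked) > 0) {
    tgt <- diff_genes[sample(length(diff_genes), length(linked), replace = TRUE)]
    b_link[linked] <- mcols(genes)$gene_id[tgt]
    b_dir[linked] <- g_dir[tgt]
  }
  rest <- setdiff(dbi, linked)
  if (length(rest) > 0) {
    b_dir[rest] <- ifelse(runif(length(rest)) < cfg$frac_up_A[["binding"]],
      "A-up", "B-up"
    )
  }
  b_mag <- runif(n_tot, cfg$lfc_range[1], cfg$lfc_range[2])
  b_lfc <- ifelse(b_dir == "A-up", b_mag, ifelse(b_dir == "B-up", -b_mag, 0))
  b_base <- rlnorm(n_tot, cfg$baseline_meanlog, cfg$baseline_sdlog)

  ## placement: linked BRs near their gene's TSS; others near a random TSS
  ## with prob br_near_tss_frac, else uniform on the genome
  genome <- cfg$genome
  chrom <- character(n_tot)
  start0 <- numeric(n_tot)
  width <- floor(runif(n_tot, cfg$br_width[1], cfg$br_width[2]))
  tss1 <- if (n_g > 0) gene_tss(genes) else integer(0)
  g_chrom <- if (n_g > 0) as.character(seqnames(genes)) else character(0)
  near_gene <- function(gidx, w) {
    off <- floor(runif(1, -cfg$br_tss_window, cfg$br_tss_window - w))
    c(g_chrom[gidx], max(0, tss1[gidx] - 1 + off))
  }
  for (i in seq_len(n_tot)) {
    gi <- NA_integer_
    if (!is.na(b_link[i])) {
      gi <- match(b_link[i], mcols(genes)$gene_id)
    } else if (n_g > 0 && runif(1) < cfg$br_near_tss_frac) {
      gi <- sample(n_g, 1)
    }
    if (!is.na(gi)) {
      pos <- near_gene(gi, width[i])
      chrom[i] <- pos[1]
      start0[i] <- as.numeric(pos[2])
    } else {
      ci <- sample(nrow(genome), 1, prob = genome$length)
      chrom[i] <- genome$chrom[ci]
      start0[i] <- floor(runif(1, 0, genome$length[ci] - width[i]))
    }
  }
  br <- data.frame(
    chrom = chrom, start0 = start0, end0 = start0 + width,
    is_diff = b_diff, direction = b_dir, log2fc = b_lfc,
    baseline = b_base, linked_gene = b_link,
    singleton = seq_len(n_tot) > n_b, stringsAsFactors = FALSE
  )
  ## enforce the minimum inter-BR gap (shift right; drop past chrom end)
  br <- br[order(br$chrom, br$start0), , drop = FALSE]
  for (ch in unique(br$chrom)) {
    ix <- which(br$chrom == ch)
    if (length(ix) < 2) next
    for (u in 2:length(ix)) {
      lo <- br$end0[ix[u - 1]] + cfg$min_br_gap
      if (br$start0[ix[u]] < lo) {
        w <- br$end0[ix[u]] - br$start0[ix[u]]
        br$start0[ix[u]] <- lo
        br$end0[ix[u]] <- lo + w
      }
    }
  }
  lens <- setNames(genome$length, genome$chrom)
  br <- br[br$end0 <= lens[br$chrom], , drop = FALSE]
  br$feature_id <- sprintf("pbr%04d", seq_len(nrow(br)))
  brs <- GenomicRanges::GRanges(br$chrom,
    IRanges::IRanges(br$start0 + 1, br$end0),
    br_id = br$feature_id, is_diff = br$is_diff,
    direction = br$direction, singleton = br$singleton
  )
  names(brs) <- br$feature_id
  suppressWarnings(seqlengths(brs) <- lens[seqlevels(brs)])
  br_truth <- data.frame(
    feature_id = br$feature_id, kind = "BR", is_diff = br$is_diff,
    direction = br$direction, log2fc = br$log2fc, baseline = br$baseline,
    onoff = FALSE, linked_gene = br$linked_gene, stringsAsFactors = FALSE
  )
  list(truth = rbind(gene_truth, br_truth), brs = brs)
}

#' Simulate per-cell-line peak sets
#'
#' Plants binding regions (and the full ground-truth ledger), then emits
#' each BR as a peak, with uniform edge jitter, in every cell line where it
#' is occupied. Occupancy is sampled per group: differential BRs use
#' `occ_major` in their up group and `occ_minor` in the other, shared BRs
#' `occ_shared` in both; singleton BRs appear in exactly one cell line.
#'
#' @param cfg a [sim_config()].
#' @param annotation from [simulate_annotation()].
#' @return List: `peaks` (named list of per-cell-line `GRanges`), `brs`
#'   (planted BR `GRanges`), `truth` (ground-truth `data.frame` covering
#'   genes and BRs).
#' @export
simulate_peaks <- function(cfg, annotation) {
  stopifnot(inherits(cfg, "sim_config"))
  planted <- .plant_truth(cfg, annotation)
  set.seed(.stage_seed(cfg$seed, "occupancy"))
  brs <- planted$brs
  lines <- sim_cell_lines(cfg)
  groups <- names(lines)
  n <- length(brs)
  occ <- matrix(FALSE, n, length(lines), dimnames = list(names(brs), lines))
  for (i in seq_len(n)) {
    if (mcols(brs)$singleton[i]) {
      occ[i, sample(length(lines), 1)] <- TRUE
    } else if (mcols(brs)$is_diff[i]) {
      up <- if (mcols(brs)$direction[i] == "A-up") "A" else "B"
      p <- ifelse(groups == up, cfg$occ_major, cfg$occ_minor)
      occ[i, ] <- runif(length(lines)) < p
    } else {
      occ[i, ] <- runif(length(lines)) < cfg$occ_shared
    }
  }
  peaks <- lapply(lines, function(ln) {
    ix <- which(occ[, ln])
    if (length(ix) == 0) {
      gr <- GenomicRanges::GRanges(cell_line = character(0), name = character(0), score = numeric(0))
      return(gr)
    }
    js <- floor(runif(length(ix), -cfg$jitter, cfg$jitter + 1))
    je <- floor(runif(length(ix), -cfg$jitter, cfg$jitter + 1))
    s1 <- pmax(1, GenomicRanges::start(brs)[ix] + js)
    e1 <- pmax(s1 + 1, GenomicRanges::end(brs)[ix] + je)
    GenomicRanges::GRanges(seqnames(brs)[ix], IRanges::IRanges(s1, e1),
      cell_line = ln,
      name = paste0(names(brs)[ix], "_", ln), score = 0
    )
  })
  names(peaks) <- lines
  bc_log(
    "simulate_peaks: %d planted BRs -> %s peaks per cell line",
    n, paste(range(vapply(peaks, length, 0L)), collapse = "-")
  )
  list(peaks = peaks, brs = brs, truth = planted$truth)
}

#' Simulate NB count matrices for binding and expression
#'
#' Counts for feature i in library j are drawn from a negative binomial
#' with mean `s_j * q_i * f_i(group_j)` and variance
#' `mean + alpha_i * mean^2`, where `q_i` is the planted baseline, `f_i`
#' applies half the planted log2 fold change to each group
#' (`2^(+-lfc/2)`), `alpha_i = alpha0 + alpha1 / q_i`, and `s_j` is a
#' library size factor drawn log-uniformly from the configured range.
#' `alpha = 0` reduces to Poisson. Fixed seeds give identical matrices.
#'
#' @param cfg a [sim_config()].
#' @param truth ground-truth `data.frame` from [simulate_peaks()] (or a
#'   hand-built one with columns `feature_id`, `kind`, `log2fc`,
#'   `baseline`).
#' @return List: `binding` and `expression` [count_matrix()] objects and
#'   `size_factors` (named list of the planted per-library factors).
#' @export
simulate_counts <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  need <- c("feature_id", "kind", "log2fc", "baseline")
  stopifnot(all(need %in% names(truth)))
  set.seed(.stage_seed(cfg$seed, "size_factors"))
  sheets <- list(
    binding = sim_sample_sheet(cfg, "binding"),
    expression = sim_sample_sheet(cfg, "expression")
  )
  sf <- lapply(sheets, function(sh) {
    setNames(
      exp(runif(
        nrow(sh), log(cfg$size_factor_range[1]),
        log(cfg$size_factor_range[2])
      )),
      sh$library
    )
  })
  draw <- function(assay, kind) {
    tt <- truth[truth$kind == kind, , drop = FALSE]
    sh <- sheets[[assay]]
    s <- sf[[assay]]
    set.seed(.stage_seed(cfg$seed, paste0("counts_", assay)))
    q <- tt$baseline
    alpha <- cfg$alpha0 + ifelse(q > 0, cfg$alpha1 / q, 0)
    fA <- 2^(tt$log2fc / 2)
    fB <- 2^(-tt$log2fc / 2)
    k <- vapply(seq_len(nrow(sh)), function(j) {
      f <- if (sh$group[j] == "A") fA else fB
      mu <- s[j] * q * f
      out <- numeric(length(mu))
      od <- alpha > 0
      out[od] <- rnbinom(sum(od), mu = mu[od], size = 1 / alpha[od])
      out[!od] <- rpois(sum(!od), mu[!od])
      out
    }, numeric(nrow(tt)))
    k <- matrix(as.integer(k),
      nrow = nrow(tt),
      dimnames = list(tt$feature_id, sh$library)
    )
    count_matrix(k, sh)
  }
  list(
    binding = draw("binding", "BR"),
    expression = draw("expression", "gene"),
    size_factors = sf
  )
}

#' Simulate a complete dataset
#'
#' Annotation, per-cell-line peak sets, both count matrices, sample sheets
#' and the ground-truth ledger, all reproducible from the config seed.
#'
#' @param cfg a [sim_config()].
#' @return List with `cfg`, `genes`, `peaks`, `brs`, `truth`,
#'   `counts_binding`, `counts_expression`, `size_factors`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  genes <- simulate_annotation(cfg)
  pk <- simulate_peaks(cfg, genes)
  cnt <- simulate_counts(cfg, pk$truth)
  list(
    cfg = cfg, genes = genes, peaks = pk$peaks, brs = pk$brs,
    truth = pk$truth,
    counts_binding = cnt$binding, counts_expression = cnt$expression,
    size_factors = cnt$size_factors
  )
}

#' Write a simulated dataset to disk
#'
#' Emits exactly the formats the readers consume: one BED per cell line,
#' TSV count tables, a TSV gene annotation, sample sheets and the truth
#' ledger.
#'
#' @param sim from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ln in names(sim$peaks)) {
    write_bed(sim$peaks[[ln]], file.path(dir, paste0("peaks_", ln, ".bed")))
  }
  write_gene_models(sim$genes, file.path(dir, "annotation.tsv"))
  write_count_table(sim$counts_binding, file.path(dir, "counts_binding.tsv"))
  write_count_table(sim$counts_expression, file.path(dir, "counts_expression.tsv"))
  write_sample_sheet(sim$counts_binding$samples, file.path(dir, "samples_binding.tsv"))
  write_sample_sheet(sim$counts_expression$samples, file.path(dir, "samples_expression.tsv"))
  write.table(sim$truth, file.path(dir, "truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}
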