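# build a GRanges annotation from 0-based TSS positions
genes_at <- function(tss0, strand, chrom = "chr1", chrom_len = 1e7, width = 1000) {
  start0 <- ifelse(strand == "+", tss0, tss0 - width + 1)
  end0 <- ifelse(strand == "+", tss0 + width, tss0 + 1)
  gr <- GRanges(chrom, IRanges(start0 + 1, end0),
    strand = strand,
    gene_id = sprintf("g%d", seq_along(tss0))
  )
  names(gr) <- mcols(gr)$gene_id
  suppressWarnings(seqlengths(gr) <- setNames(
    rep(chrom_len, length(unique(chrom))), unique(chrom)
  ))
  gr
}

dom0 <- function(d) {
  data.frame(
    ext_start0 = start(d) - 1, ext_end0 = end(d),
    basal_start0 = mcols(d)$basal_start - 1, basal_end0 = mcols(d)$basal_end
  )
}

test_that("basal-plus-extension arithmetic matches hand computation", {
  # lone + strand gene, TSS at 2,000,000 on a 10 Mb chromosome
  d <- dom0(build_domains(genes_at(2e6, "+")))
  expect_equal(d$basal_start0, 1995000)
  expect_equal(d$basal_end0, 2001000)
  expect_equal(d$ext_start0, 995000)
  expect_equal(d$ext_end0, 3001000)

  # mirrored on the - strand: 5000 bp upstream (rightward), TSS, 999 bp
  # downstream, i.e. the exact reflection of the + strand window
  d <- dom0(build_domains(genes_at(2e6, "-")))
  expect_equal(d$basal_start0, 1999001)
  expect_equal(d$basal_end0, 2005001)
  expect_equal(d$basal_end0 - d$basal_start0, 6000)
  expect_equal(d$ext_start0, 999001)
  expect_equal(d$ext_end0, 3005001)

  # near-origin gene: extension clamped at 0
  d <- dom0(build_domains(genes_at(1000, "+", width = 500)))
  expect_equal(d$ext_start0, 0)
  expect_equal(d$basal_start0, 0)

  # two + strand genes 10 kb apart: gene 1's downstream extension stops at
  # gene 2's basal start (TSS2 - 5 kb)
  d <- dom0(build_domains(genes_at(c(1e6, 1e6 + 1e4), c("+", "+"), width = 2000)))
  expect_equal(d$ext_end0[1], 1e6 + 1e4 - 5000)
  expect_equal(d$ext_start0[2], 1e6 + 1000) # stops at gene 1's basal end

  # unknown chromosome length: clamp only at 0, with a warning
  g <- genes_at(2e6, "+")
  seqlengths(g) <- NA
  expect_warning(build_domains(g), "unknown chromosome length")
})

test_that("extensions never cross a neighboring basal domain", {
  for (seed in c(2, 8)) {
    cfg <- sim_config(
      n_genes = 80, min_spacing = 12000, seed = seed,
      genome = data.frame(chrom = c("chr1", "chr2"), length = c(3e6, 2e6))
    )
    genes <- simulate_annotation(cfg)
    d <- build_domains(genes)
    df <- dom0(d)
    df$chrom <- as.character(seqnames(d))
    for (i in seq_len(nrow(df))) {
      others <- df[-i, , drop = FALSE]
      others <- others[others$chrom == df$chrom[i], , drop = FALSE]
      if (nrow(others) == 0) next
      # extension pieces outside the gene's own basal domain
      left <- c(df$ext_start0[i], df$basal_start0[i])
      right <- c(df$basal_end0[i], df$ext_end0[i])
      crosses <- (others$basal_start0 < left[2] & others$basal_end0 > left[1]) |
        (others$basal_start0 < right[2] & others$basal_end0 > right[1])
      expect_false(any(crosses))
    }
  }
})

test_that("association equals all-pairs brute force and grows with max_ext", {
  genes <- genes_at(2e6, "+")
  dom <- build_domains(genes)
  inside <- df_to_granges(data.frame(chrom = "chr1", start0 = 1996000, end0 = 1996200))
  mcols(inside)$br_id <- "BR1"
  expect_equal(nrow(associate_regions(inside, dom)), 1L)
  desert <- df_to_granges(data.frame(chrom = "chr1", start0 = 8e6, end0 = 8e6 + 200))
  mcols(desert)$br_id <- "BR1"
  expect_equal(nrow(associate_regions(desert, dom)), 0L)

  set.seed(43)
  tss0 <- sort(sample(seq(5e4, 9.5e6, by = 1), 20))
  genes <- genes_at(tss0, sample(c("+", "-"), 20, replace = TRUE))
  dom <- build_domains(genes, max_ext = 2e5)
  brs <- random_intervals0(300, chrom_len = 1e7, width = c(200, 800))
  br_gr <- df_to_granges(brs)
  mcols(br_gr)$br_id <- sprintf("BR%03d", 1:300)
  pairs <- associate_regions(br_gr, dom)
  dom_df <- data.frame(
    chrom = as.character(seqnames(dom)),
    start0 = start(dom) - 1, end0 = end(dom)
  )
  oracle <- do.call(rbind, lapply(1:300, function(i) {
    hit <- which(overlaps0(brs[i, ], dom_df))
    if (length(hit) == 0) {
      return(NULL)
    }
    data.frame(gene_id = mcols(dom)$gene_id[hit], br_id = sprintf("BR%03d", i))
  }))
  oracle <- oracle[order(oracle$gene_id, oracle$br_id), ]
  expect_equal(
    pairs[, c("gene_id", "br_id")], oracle,
    ignore_attr = TRUE
  )

  # monotonicity: a larger extension never removes a pair
  pairs_big <- associate_regions(br_gr, build_domains(genes, max_ext = 1e6))
  key <- function(p) paste(p$gene_id, p$br_id)
  expect_true(all(key(pairs) %in% key(pairs_big)))
})

test_that("TSS distances are signed, strand-aware midpoint offsets", {
  g_plus <- genes_at(10000, "+")
  g_minus <- genes_at(10000, "-")
  at <- function(mid0, half = 50) {
    df_to_granges(data.frame(
      chrom = "chr1",
      start0 = mid0 - half, end0 = mid0 + half
    ))
  }
  expect_equal(tss_distance(at(10000), g_plus), 0L)
  expect_equal(tss_distance(at(9900), g_plus), -100L)
  expect_equal(tss_distance(at(9900), g_minus), 100L)
  expect_equal(tss_distance(at(10100), g_minus), -100L)

  # distances surfaced by association match the direct computation
  dom <- build_domains(g_plus)
  br <- at(9900)
  mcols(br)$br_id <- "BR1"
  expect_equal(associate_regions(br, dom)$tss_distance, -100L)
})

test_that("binomial enrichment reproduces the closed-form tail", {
  expect_equal(binomial_enrichment(10, 0, 0.5), 1)
  expect_equal(binomial_enrichment(10, 10, 1), 1)
  # 1 - sum_{i<=2} C(10,i) 0.1^i 0.9^(10-i), hand tail sum
  oracle <- 1 - sum(choose(10, 0:2) * 0.1^(0:2) * 0.9^(10 - (0:2)))
  expect_equal(binomial_enrichment(10, 3, 0.1), oracle, tolerance = 1e-12)
  expect_equal(round(binomial_enrichment(10, 3, 0.1), 4), 0.0702)
  expect_warning(p <- binomial_enrichment(10, 2, 0), "p = 0")
  expect_equal(p, 0)
  expect_error(binomial_enrichment(10, 11, 0.5))
})

test_that("ontology enrichment ranks the truly annotated term first", {
  set.seed(47)
  tss0 <- seq(2e5, 9.8e6, length.out = 25)
  genes <- genes_at(tss0, rep(c("+", "-"), length.out = 25))
  dom <- build_domains(genes, max_ext = 1e5)
  term_genes <- sprintf("g%d", 1:5)
  # regions stacked at the midpoints of the term genes' basal domains
  hit_brs <- df_to_granges(data.frame(
    chrom = "chr1", start0 = tss0[1:5] - 100, end0 = tss0[1:5] + 100
  ))
  far_brs <- df_to_granges(random_intervals0(20, chrom_len = 1e7))
  ont <- rbind(
    data.frame(term = "hit_term", gene_id = term_genes),
    data.frame(term = "other", gene_id = sprintf("g%d", 21:25))
  )
  res <- enrich_regions(c(hit_brs, far_brs), dom, ont, genome_size = 1e7)
  expect_equal(res$term[1], "hit_term")
  expect_gte(res$hit_count[res$term == "hit_term"], 5)
  expect_lt(res$p[res$term == "hit_term"], 1e-4)
  expect_lt(
    res$p[res$term == "hit_term"],
    res$p[res$term == "other"]
  )
})
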