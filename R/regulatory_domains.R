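## GREAT-style regulatory domains: a basal domain around each TSS (5 kb
## upstream / 1 kb downstream by default) extended outward up to 1 Mb per
## side but truncated at the nearest neighboring gene's basal domain.
## Association of binding regions with genes is whole-region >= 1 bp
## overlap with the extended domain; the binomial enrichment test counts
## region midpoints inside annotated domains.

#' Build basal-plus-extension regulatory domains
#'
#' For a `+`-strand gene with 0-based TSS `t`, the basal domain is
#' `[t - basal_up, t + basal_down)` (mirrored for `-` strand). The
#' extended domain reaches up to `max_ext` bp beyond each basal edge but
#' stops at the nearest neighboring gene's basal domain; basal domains
#' themselves may overlap and are never truncated. Domains are clamped to
#' `[0, chromosome length)`; when a chromosome length is unknown only the
#' lower bound is applied (with a warning).
#'
#' @param genes `GRanges` of gene bodies with `+`/`-` strands and a
#'   `gene_id` column (or names); `seqlengths` used for clamping when set.
#' @param basal_up,basal_down basal extent upstream/downstream of the TSS,
#'   bp.
#' @param max_ext maximum extension beyond the basal domain per side, bp.
#' @return `GRanges` of extended domains with metadata `gene_id`, `tss`
#'   (1-based), `basal_start`, `basal_end` (1-based closed), strand kept
#'   from the gene.
#' @export
build_domains <- function(genes, basal_up = 5000, basal_down = 1000,
                          max_ext = 1e6) {
  ids <- mcols(genes)$gene_id %||% names(genes)
  if (is.null(ids)) stop("genes need a 'gene_id' column or names")
  st <- as.character(GenomicRanges::strand(genes))
  if (!all(st %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  tss <- gene_tss(genes)
  plus <- st == "+"
  ## 1-based closed basal window around the TSS; the - strand window is the
  ## exact mirror of the + strand one (basal_up bases upstream, the TSS,
  ## basal_down - 1 bases downstream)
  b_start <- ifelse(plus, tss - basal_up, tss - basal_down + 1)
  b_end <- ifelse(plus, tss + basal_down - 1, tss + basal_up)
  b_start <- pmax(b_start, 1)
  chrom <- as.character(seqnames(genes))
  lens <- seqlengths(genes)[chrom]
  if (anyNA(lens)) {
    warning("unknown chromosome length(s): domains clamped only at 0")
  }
  b_end <- ifelse(is.na(lens), b_end, pmin(b_end, lens))
  e_start <- numeric(length(genes))
  e_end <- numeric(length(genes))
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    bs <- b_start[ix]
    be <- b_end[ix]
    for (u in seq_along(ix)) {
      left <- which(bs <= bs[u])
      left <- left[left != u]
      lb <- if (length(left)) max(pmin(be[left] + 1, bs[u])) else 1
      right <- which(be >= be[u])
      right <- right[right != u]
      rb <- if (length(right)) min(pmax(bs[right] - 1, be[u])) else Inf
      e_start[ix[u]] <- max(bs[u] - max_ext, lb, 1)
      ln <- lens[ix[u]]
      e_end[ix[u]] <- min(be[u] + max_ext, rb, if (is.na(ln)) Inf else ln)
    }
  }
  out <- GenomicRanges::GRanges(chrom, IRanges::IRanges(e_start, e_end),
    strand = st,
    gene_id = ids, tss = tss,
    basal_start = as.integer(b_start), basal_end = as.integer(b_end)
  )
  suppressWarnings(seqlengths(out) <- seqlengths(genes)[seqlevels(out)])
  names(out) <- ids
  bc_log("build_domains: %d genes -> %d regulatory domains", length(genes), length(out))
  out
}

# signed midpoint-to-TSS distance in bp; negative = upstream of the TSS in
# the gene's orientation. Computed in 0-based coordinates from the region
# midpoint (summits are not available after merging).
.tss_dist <- function(start1, end1, tss1, strand) {
  mid0 <- floor((start1 - 1 + end1) / 2)
  d <- mid0 - (tss1 - 1)
  ifelse(strand == "-", -d, d)
}

#' Signed distance from a region midpoint to a gene's TSS
#'
#' Negative values are upstream of the TSS, strand-aware: for `-`-strand
#' genes the raw coordinate difference is negated.
#'
#' @param br a `GRanges` of regions.
#' @param gene a length-1 `GRanges` gene (or any object with a strand and a
#'   TSS via [gene_tss()]).
#' @return Integer vector of signed distances, one per region.
#' @export
tss_distance <- function(br, gene) {
  stopifnot(length(gene) == 1L)
  as.integer(.tss_dist(
    GenomicRanges::start(br), GenomicRanges::end(br),
    gene_tss(gene), as.character(GenomicRanges::strand(gene))
  ))
}

#' Associate binding regions with genes via regulatory domains
#'
#' A (gene, BR) pair is emitted iff the BR overlaps the gene's extended
#' regulatory domain by >= 1 bp; a BR may pair with 0, 1 or many genes and
#' vice versa. Each pair carries the signed midpoint-to-TSS distance.
#'
#' @param brs `GRanges` of binding regions (ids from `br_id` or names).
#' @param domains from [build_domains()].
#' @return `data.frame` with columns `gene_id`, `br_id`, `tss_distance`;
#'   one row per unique pair.
#' @export
associate_regions <- function(brs, domains) {
  br_ids <- mcols(brs)$br_id %||% names(brs)
  if (is.null(br_ids)) stop("brs need a 'br_id' column or names")
  hits <- GenomicRanges::findOverlaps(brs, domains,
    minoverlap = 1L, ignore.strand = TRUE
  )
  qi <- queryHits(hits)
  si <- subjectHits(hits)
  pairs <- data.frame(
    gene_id = mcols(domains)$gene_id[si],
    br_id = br_ids[qi],
    tss_distance = as.integer(.tss_dist(
      GenomicRanges::start(brs)[qi], GenomicRanges::end(brs)[qi],
      mcols(domains)$tss[si],
      as.character(GenomicRanges::strand(domains))[si]
    )),
    stringsAsFactors = FALSE
  )
  pairs <- pairs[order(pairs$gene_id, pairs$br_id), , drop = FALSE]
  rownames(pairs) <- NULL
  bc_log(
    "associate_regions: %d BRs x %d genes -> %d pairs (%d BRs associated)",
    length(brs), length(domains), nrow(pairs), length(unique(pairs$br_id))
  )
  pairs
}

#' Region-based binomial enrichment p-value
#'
#' Upper-tail probability `P(X >= hit_count)` for
#' `X ~ Binomial(n_regions, annotated_fraction)`: the chance that at least
#' as many of the `n_regions` region midpoints fall into domains carrying
#' an annotation term, when the term's domains cover `annotated_fraction`
#' of the genome.
#'
#' @param n_regions number of regions tested.
#' @param hit_count regions whose midpoint lies in an annotated domain.
#' @param annotated_fraction fraction of genome bp covered by the term's
#'   extended domains, in \[0, 1\].
#' @return p-value; 1 when `hit_count` is 0 or `annotated_fraction` is 1;
#'   exactly 0 (with a warning) when `annotated_fraction` is 0 with hits.
#' @export
binomial_enrichment <- function(n_regions, hit_count, annotated_fraction) {
  stopifnot(
    length(n_regions) == 1L, length(hit_count) == 1L,
    n_regions >= 0, hit_count >= 0, hit_count <= n_regions,
    annotated_fraction >= 0, annotated_fraction <= 1
  )
  if (hit_count == 0) {
    return(1)
  }
  if (annotated_fraction == 0) {
    warning("annotated fraction 0 with hits > 0: p = 0 exactly")
    return(0)
  }
  pbinom(hit_count - 1, n_regions, annotated_fraction, lower.tail = FALSE)
}

#' Enrichment of regions across an ontology
#'
#' For each term, the annotated fraction is the union of the extended
#' domains of the term's genes divided by the genome size, a region "hits"
#' if its midpoint lies in that union, and the p-value is
#' [binomial_enrichment()].
#'
#' @param brs `GRanges` of regions.
#' @param domains from [build_domains()].
#' @param ontology `data.frame` with columns `term` and `gene_id`.
#' @param genome_size total genome bp.
#' @return `data.frame`: `term`, `n_genes`, `annotated_fraction`,
#'   `hit_count`, `p`, sorted by `p`.
#' @export
enrich_regions <- function(brs, domains, ontology, genome_size) {
  stopifnot(all(c("term", "gene_id") %in% names(ontology)), genome_size > 0)
  mids0 <- floor((GenomicRanges::start(brs) - 1 + GenomicRanges::end(brs)) / 2)
  midpoints <- GenomicRanges::GRanges(
    seqnames(brs), IRanges::IRanges(mids0 + 1, width = 1)
  )
  terms <- unique(ontology$term)
  rows <- lapply(terms, function(tm) {
    g <- unique(ontology$gene_id[ontology$term == tm])
    dom <- domains[mcols(domains)$gene_id %in% g]
    cover <- GenomicRanges::reduce(dom, ignore.strand = TRUE)
    frac <- min(1, sum(as.numeric(GenomicRanges::width(cover))) / genome_size)
    hits <- sum(GenomicRanges::countOverlaps(midpoints, cover,
      ignore.strand = TRUE
    ) > 0)
    data.frame(
      term = tm, n_genes = length(g), annotated_fraction = frac,
      hit_count = hits,
      p = binomial_enrichment(length(midpoints), hits, frac),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
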