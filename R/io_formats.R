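## I/O for the plain-text formats the pipeline touches: BED peak/region sets,
## TSV count tables, sample sheets, gene annotations, result tables, and a
## small YAML run configuration. On-disk interval coordinates are BED-style
## 0-based half-open; in memory everything is a GRanges (1-based closed),
## converted at these boundaries.

#' Construct and validate a sample sheet
#'
#' A sample sheet maps sequencing libraries to cell lines and to one of the
#' two contrasted groups (`"A"` and `"B"`, e.g. ABC-like vs GCB-like lines).
#'
#' @param library character, unique library identifiers.
#' @param cell_line character, cell line of each library.
#' @param group character, `"A"` or `"B"`; every cell line must map to
#'   exactly one group and each group must contain at least one cell line.
#' @param assay character, `"binding"` or `"expression"`.
#' @param replicate integer replicate index within cell line.
#' @return A validated `data.frame` with those five columns.
#' @export
sample_sheet <- function(library, cell_line, group, assay, replicate = 1L) {
  sheet <- data.frame(
    library = as.character(library),
    cell_line = as.character(cell_line),
    group = as.character(group),
    assay = as.character(assay),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  validate_sample_sheet(sheet)
}

#' @rdname sample_sheet
#' @param sheet a data.frame with the five sample-sheet columns.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("library", "cell_line", "group", "assay", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss) > 0) {
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(sheet$library)) {
    stop("sample sheet library ids must be unique")
  }
  if (!all(sheet$group %in% c("A", "B"))) {
    stop("sample sheet group labels must be 'A' or 'B'")
  }
  if (!all(sheet$assay %in% c("binding", "expression"))) {
    stop("sample sheet assay must be 'binding' or 'expression'")
  }
  by_line <- unique(sheet[, c("cell_line", "group")])
  if (anyDuplicated(by_line$cell_line)) {
    stop("each cell line must map to exactly one group")
  }
  if (length(unique(sheet$group)) < 1L) stop("empty sample sheet")
  sheet
}

#' Read a sample sheet from TSV
#'
#' @param path TSV file with header columns `library`, `cell_line`, `group`,
#'   `assay`, `replicate`.
#' @return A validated sample-sheet `data.frame`.
#' @export
read_sample_sheet <- function(path) {
  validate_sample_sheet(read.delim(path, stringsAsFactors = FALSE))
}

#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(validate_sample_sheet(sheet), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a BED3/BED6 file into a GRanges
#'
#' BED coordinates are 0-based half-open on disk and become 1-based closed
#' in the returned `GRanges`. Comment, `track` and `browser` lines are
#' skipped. Records with `end <= start` or non-numeric coordinates raise an
#' error naming the offending line.
#'
#' @param path path to a BED file with >= 3 tab-separated columns.
#' @return `GRanges` with metadata columns `name` and `score`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(GenomicRanges::GRanges(
      name = character(0), score = numeric(0)
    ))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED record with fewer than 3 fields at line ", idx[which(nf < 3L)[1]])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start0) | is.na(end0)
  if (any(bad)) stop("non-numeric BED coordinates at line ", idx[which(bad)[1]])
  bad <- end0 <= start0 | start0 < 0
  if (any(bad)) {
    stop(
      "invalid BED interval (end <= start or negative start) at line ",
      idx[which(bad)[1]]
    )
  }
  name <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else ".", "")
  score <- suppressWarnings(as.numeric(
    vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else "0", "")
  ))
  score[is.na(score)] <- 0
  strand <- vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else "*", "")
  strand[!strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = strand,
    name = name,
    score = score
  )
}

#' Write a GRanges as BED6
#'
#' Inverse of [read_bed()]: emits 0-based half-open coordinates; `name` and
#' `score` metadata columns are used when present.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  n <- length(gr)
  name <- if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name) else rep(".", n)
  score <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else rep(0, n)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = format(GenomicRanges::start(gr) - 1, scientific = FALSE, trim = TRUE),
    end = format(GenomicRanges::end(gr), scientific = FALSE, trim = TRUE),
    name = name, score = score, strand = strand
  )
  write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read gene models from a TSV annotation
#'
#' Expects header columns `gene_id`, `chrom`, `start`, `end`, `strand`.
#' Coordinates are 0-based half-open by default (BED convention); set
#' `one_based = TRUE` for GTF-lite tables (1-based inclusive), which are
#' converted on read. The TSS is the `start` of `+`-strand genes and the
#' last base of `-`-strand genes (see [gene_tss()]).
#'
#' @param path TSV file path.
#' @param one_based logical; input coordinates are 1-based inclusive.
#' @return `GRanges` with metadata column `gene_id`; strands are `+`/`-`.
#' @export
read_gene_models <- function(path, one_based = FALSE) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in annotation")
  if (!all(df$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  start1 <- if (one_based) df$start else df$start + 1
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(start1, df$end),
    strand = df$strand, gene_id = df$gene_id
  )
  names(gr) <- df$gene_id
  gr
}

#' @export
write_gene_models <- function(genes, path) {
  df <- data.frame(
    gene_id = mcols(genes)$gene_id %||% names(genes),
    chrom = as.character(seqnames(genes)),
    start = GenomicRanges::start(genes) - 1,
    end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes))
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Transcription start sites of gene models
#'
#' @param genes `GRanges` of gene bodies with `+`/`-` strands.
#' @return Integer vector of 1-based TSS positions (start for `+`,
#'   end for `-`).
#' @export
gene_tss <- function(genes) {
  st <- as.character(GenomicRanges::strand(genes))
  if (!all(st %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  ifelse(st == "+", GenomicRanges::start(genes), GenomicRanges::end(genes))
}

#' Count matrix with sample annotations
#'
#' Bundles a nonnegative integer features-by-libraries matrix with the
#' sample-sheet rows describing its columns, the container consumed by
#' [run_differential()].
#'
#' @param counts integer matrix; rownames are feature ids, colnames library
#'   ids.
#' @param samples sample-sheet `data.frame` (see [sample_sheet()]) whose
#'   rows match `colnames(counts)`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature rownames and library colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  storage.mode(counts) <- "integer"
  samples <- validate_sample_sheet(samples)
  if (!setequal(samples$library, colnames(counts)) ||
    length(samples$library) != ncol(counts)) {
    stop("sample sheet libraries do not match count columns")
  }
  samples <- samples[match(colnames(counts), samples$library), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(
    "count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
    "libraries (", paste(table(x$samples$group), collapse = " vs "),
    "by group )\n"
  )
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count table and align it to a sample sheet
#'
#' The TSV must have a header of library ids and a first column of feature
#' ids; cells must be nonnegative integers. Every header library must be
#' present in `sheet`; offending cells are reported by feature and library.
#'
#' @param path TSV file path.
#' @param sheet sample sheet describing (at least) the table's libraries.
#' @return A [count_matrix()].
#' @export
read_count_table <- function(path, sheet) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs a feature column and >=1 library")
  feats <- as.character(df[[1L]])
  if (anyDuplicated(feats)) {
    stop("duplicate feature id in count table: ", feats[duplicated(feats)][1])
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  sheet <- validate_sample_sheet(sheet)
  unknown <- setdiff(colnames(m), sheet$library)
  if (length(unknown) > 0) {
    stop("library not in sample sheet: ", paste(unknown, collapse = ", "))
  }
  suppressWarnings(storage.mode(m) <- "numeric")
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(
      "invalid count (negative, missing or non-integer) at feature '",
      feats[bad[1, 1]], "', library '", colnames(m)[bad[1, 2]], "'"
    )
  }
  rownames(m) <- feats
  count_matrix(m, sheet[match(colnames(m), sheet$library), , drop = FALSE])
}

#' @export
write_count_table <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(feature = rownames(cm$counts), cm$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- result-table formatting -----------------------------------------------

# printed precision: 2 dp for means/fold changes, 2-decimal scientific for
# p/FDR, "N/A" for undefined fold changes
.fmt_result_col <- function(name, x) {
  if (!is.numeric(x)) {
    return(as.character(x))
  }
  if (grepl("(^|_)(p|fdr)$", name)) {
    return(ifelse(is.na(x), "N/A", sprintf("%.2e", x)))
  }
  if (grepl("(fold_change|_fc)$", name)) {
    return(ifelse(is.na(x), "N/A", sprintf("%.2f", x)))
  }
  if (grepl("^mean_", name)) {
    return(sprintf("%.2f", x))
  }
  if (name %in% c("tss_distance")) {
    return(sprintf("%d", as.integer(x)))
  }
  as.character(x)
}

#' Write a results table as TSV
#'
#' Works for differential tables and gene/BR pair tables. Columns are kept
#' in their deterministic order; fold changes print with 2 decimals
#' (`"N/A"` when undefined, e.g. a zero denominator mean), p-values and
#' FDRs in 2-decimal scientific notation.
#'
#' @param table a `data.frame` (e.g. from [run_differential()] or
#'   [join_pairs()]).
#' @param path output TSV path.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- as.data.frame(
    lapply(seq_along(table), function(j) .fmt_result_col(names(table)[j], table[[j]])),
    stringsAsFactors = FALSE
  )
  names(out) <- names(table)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results TSV written by [write_results()]
#'
#' `"N/A"` fields become `NA`; numeric-looking columns are parsed.
#'
#' @param path TSV path.
#' @return A `data.frame`.
#' @export
read_results <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "N/A")
  for (j in seq_along(df)) {
    x <- df[[j]]
    if (is.character(x)) {
      xn <- suppressWarnings(as.numeric(x))
      if (all(is.na(xn) == is.na(x))) df[[j]] <- xn
    }
  }
  df
}

#' Read pipeline configuration from YAML
#'
#' Unspecified keys fall back to the package defaults: FDR cutoff 0.05,
#' on/off read-count threshold 5, minimum cell-line support 2, and the
#' merge policy (`"abutting"`: zero-gap peaks merge, 1-bp gaps do not).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    fdr = 0.05,
    onoff_threshold = 5,
    min_lines = 2L,
    merge_policy = "abutting",
    fragment_extension = 200L
  )
  if (is.null(path)) {
    return(defaults)
  }
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  utils::modifyList(defaults, user)
}
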