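## Binding-region construction: merge per-cell-line peak sets into BRs,
## filter by cross-line support, rescore fragment counts, and compare BR
## sets between datasets. Interval engine: GenomicRanges.

#' Merge per-cell-line peaks into binding regions
#'
#' Overlapping or abutting peaks (zero gap in half-open coordinates; 1-bp
#' gaps are kept apart) are merged transitively into binding regions (BRs).
#' Each BR records the distinct cell lines whose peaks it absorbed
#' (`support`) and the number of source peaks (`n_peaks`); every input peak
#' lands in exactly one BR.
#'
#' @param peaks a `GRanges` with a `cell_line` metadata column, or a named
#'   list of per-cell-line `GRanges` (names become cell lines; replicate
#'   lists for one cell line may simply be concatenated, support counts
#'   distinct lines, not peaks).
#' @return `GRanges` sorted by (chrom, start) with metadata columns
#'   `br_id`, `support` (a `CharacterList`), `n_peaks`, `name`, `score`
#'   (= support size).
#' @export
merge_peaks <- function(peaks) {
  if (is.list(peaks) && !inherits(peaks, "GRanges")) {
    if (is.null(names(peaks))) stop("per-cell-line peak list must be named")
    peaks <- do.call(c, unname(Map(function(gr, line) {
      mcols(gr)$cell_line <- line
      gr[, "cell_line"]
    }, peaks, names(peaks))))
  }
  if (is.null(mcols(peaks)$cell_line)) {
    stop("peaks need a 'cell_line' metadata column")
  }
  n_in <- length(peaks)
  GenomicRanges::strand(peaks) <- "*"
  # canonical chromosome order so BR ids are input-order invariant
  seqlevels(peaks) <- sort(seqlevels(peaks))
  brs <- GenomicRanges::reduce(peaks, min.gapwidth = 1L, with.revmap = TRUE)
  revmap <- mcols(brs)$revmap
  support <- IRanges::CharacterList(lapply(revmap, function(i) {
    sort(unique(mcols(peaks)$cell_line[i]))
  }))
  mcols(brs) <- NULL
  ids <- sprintf("BR%05d", seq_along(brs))
  mcols(brs)$br_id <- ids
  mcols(brs)$support <- support
  mcols(brs)$n_peaks <- lengths(revmap)
  mcols(brs)$name <- ids
  mcols(brs)$score <- lengths(support)
  names(brs) <- ids
  bc_log("merge_peaks: %d peaks -> %d binding regions", n_in, length(brs))
  brs
}

#' Filter binding regions by cell-line support
#'
#' Removes BRs observed in fewer than `min_lines` distinct cell lines
#' (single-line BRs are discarded at the default).
#'
#' @param brs `GRanges` from [merge_peaks()] (needs the `support` column).
#' @param min_lines minimum number of distinct supporting cell lines; must
#'   be >= 1 (`min_lines = 1` is the identity).
#' @return The retained BRs, input order preserved.
#' @export
filter_by_support <- function(brs, min_lines = 2L) {
  if (!is.numeric(min_lines) || min_lines < 1) {
    stop("min_lines must be >= 1")
  }
  if (is.null(mcols(brs)$support)) stop("brs lack a 'support' column")
  keep <- lengths(mcols(brs)$support) >= min_lines
  bc_log(
    "filter_by_support: %d BRs in, %d retained (%d discarded at min_lines=%d)",
    length(brs), sum(keep), sum(!keep), as.integer(min_lines)
  )
  brs[keep]
}

#' Rescore fragment counts over binding regions
#'
#' Counts, per library, the fragments overlapping each BR by at least 1 bp.
#' A fragment spanning the gap between two BRs is counted in both.
#' Fragments on chromosomes absent from the BR set contribute zero counts
#' (warned once per chromosome).
#'
#' @param brs `GRanges` of binding regions (metadata `br_id` used as
#'   rownames when present).
#' @param fragments named list of per-library `GRanges` of sequenced
#'   fragments (reads already extended to fragment intervals).
#' @return Integer matrix, BRs x libraries.
#' @export
rescore_fragments <- function(brs, fragments) {
  if (is.null(names(fragments))) stop("fragments must be a named list (library ids)")
  br_chroms <- unique(as.character(seqnames(brs)))
  seen <- character(0)
  counts <- vapply(fragments, function(fr) {
    extra <- setdiff(unique(as.character(seqnames(fr))), br_chroms)
    new <- setdiff(extra, seen)
    if (length(new) > 0) {
      warning(
        "fragments on chromosome(s) absent from BR set: ",
        paste(new, collapse = ", "), call. = FALSE
      )
      seen <<- c(seen, new)
    }
    # suppress the engine's "no sequence levels in common" chatter;
    # the per-chromosome warning above already covers it
    suppressWarnings(GenomicRanges::countOverlaps(brs, fr,
      minoverlap = 1L, ignore.strand = TRUE
    ))
  }, integer(length(brs)))
  counts <- matrix(counts,
    nrow = length(brs),
    dimnames = list(
      mcols(brs)$br_id %||% names(brs),
      names(fragments)
    )
  )
  bc_log(
    "rescore_fragments: %d BRs x %d libraries, %d fragments total",
    nrow(counts), ncol(counts), sum(lengths(fragments))
  )
  counts
}

#' Overlap between two binding-region sets
#'
#' Counts the regions of `brs_a` having >= 1 bp intersection with any
#' region of `brs_b` (the 1-bp overlap convention for cross-dataset
#' comparisons).
#'
#' @param brs_a,brs_b `GRanges`.
#' @return List with `count` (a-regions overlapping b) and `fraction`
#'   (`count / length(brs_a)`; 0 with a warning when `brs_a` is empty).
#' @export
overlap_sets <- function(brs_a, brs_b) {
  if (length(brs_a) == 0L) {
    warning("empty query set: overlap fraction undefined, reporting 0")
    return(list(count = 0L, fraction = 0))
  }
  hits <- GenomicRanges::countOverlaps(brs_a, brs_b,
    minoverlap = 1L, ignore.strand = TRUE
  ) > 0L
  list(count = sum(hits), fraction = sum(hits) / length(brs_a))
}
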