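#' Call enriched domains from a coverage track
#'
#' A simplified sparse-enrichment caller in the spirit of CUT&RUN peak
#' callers: candidate blocks are maximal runs of strictly positive signal,
#' each scored by its area under the curve (signal summed over the block,
#' in value x bp). With a control track, blocks whose score exceeds the
#' maximum control block score are kept; without one, the top
#' `threshold_quantile` fraction of blocks by score is kept. Externally
#' called peak BEDs read with [read_region_bed()] are a first-class
#' alternative input for downstream steps.
#'
#' @param signal A per-bp or finely binned `coverage_track`.
#' @param control Optional `coverage_track` of a control sample (e.g. IgG)
#'   at the same resolution, or `NULL`.
#' @param threshold_quantile Fraction of blocks to keep when no control is
#'   given (default 0.01).
#' @param min_width Minimum block width in bp to report (default 1).
#' @return A [region_set()] of the retained blocks, sorted and
#'   non-overlapping.
#' @export
call_domains <- function(signal, control = NULL, threshold_quantile = 0.01,
                         min_width = 1) {
  if (!is.null(control)) {
    if (control$bin_width != signal$bin_width ||
        !identical(names(control$values), names(signal$values)))
      stop("call_domains: signal and control resolution/genome mismatch")
  }
  blocks <- signal_blocks(signal)
  if (nrow(blocks) == 0L)
    return(region_set(label = "called_domains"))
  blocks <- blocks[blocks$end - blocks$start >= min_width, , drop = FALSE]
  if (nrow(blocks) == 0L)
    return(region_set(label = "called_domains"))
  if (!is.null(control)) {
    ctrl <- signal_blocks(control)
    cutoff <- if (nrow(ctrl)) max(ctrl$score) else 0
    keep <- blocks$score > cutoff
  } else {
    n_keep <- min(nrow(blocks), ceiling(threshold_quantile * nrow(blocks)))
    ord <- order(-blocks$score, match(blocks$chrom, names(signal$sizes)),
                 blocks$start)
    keep <- logical(nrow(blocks))
    keep[ord[seq_len(n_keep)]] <- TRUE
  }
  kept <- blocks[keep, , drop = FALSE]
  region_set(kept$chrom, kept$start, kept$end, label = "called_domains")
}

# maximal runs of strictly positive signal, with AUC score (value x bp)
signal_blocks <- function(track) {
  bw <- track$bin_width
  rows <- lapply(names(track$values), function(chrom) {
    v <- track$values[[chrom]]
    len <- unclass(track$sizes)[[chrom]]
    ir <- IRanges::IRanges(v > 0)
    if (length(ir) == 0L) return(NULL)
    # bin indices -> bp coordinates
    starts <- (IRanges::start(ir) - 1) * bw
    ends <- pmin(IRanges::end(ir) * bw, len)
    sc <- IRanges::viewSums(IRanges::Views(v, start = IRanges::start(ir),
                                           end = IRanges::end(ir))) * bw
    data.frame(chrom = chrom, start = starts, end = ends,
               score = as.numeric(sc), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    return(data.frame(chrom = character(), start = double(), end = double(),
                      score = double(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Merge replicate peak lists
#'
#' Union of two region sets with overlapping or abutting intervals
#' coalesced (intervals that share a boundary coordinate join), matching
#' the merge semantics of the classical BED merge utilities. The operation
#' is idempotent, commutative and associative.
#'
#' @param a,b [region_set()] objects on the same genome.
#' @param label Label for the merged set (default combines the inputs').
#' @return A merged [region_set()].
#' @export
merge_replicates <- function(a, b, label = NULL) {
  if (is.null(label))
    label <- paste(attr(a, "label"), attr(b, "label"), sep = "+")
  df <- rbind(as.data.frame(a)[c("chrom", "start", "end")],
              as.data.frame(b)[c("chrom", "start", "end")])
  if (nrow(df) == 0L) return(region_set(label = label))
  gr <- GenomicRanges::reduce(df_to_gr(df), min.gapwidth = 1L)
  out <- gr_to_df(gr)
  region_set(out$chrom, out$start, out$end, label = label)
}
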