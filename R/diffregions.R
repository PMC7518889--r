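#' Partition labeled region sets into disjoint segments
#'
#' Decomposes the union of several merged peak lists into maximal disjoint
#' segments of constant set-membership: the boundary set is every start and
#' end of every input interval, and each segment between consecutive
#' boundaries that lies inside at least one input becomes one output
#' segment, annotated with the labels of the sets that cover it. Segments
#' abut exactly where membership changes; those shared boundaries are
#' recorded as adjacency flags, which drive the dominant-segment filter.
#'
#' @param inputs Named list of two or more [region_set()] objects on the
#'   same genome (individual sets may be empty, but the union must not be).
#' @return A `partitioned_segments` object: a data.frame with columns
#'   chrom, start, end, membership (comma-separated input labels),
#'   adj_left, adj_right.
#' @examples
#' a <- region_set("chr1", 0, 10, label = "A")
#' b <- region_set("chr1", 5, 15, label = "B")
#' partition_regions(list(A = a, B = b))
#' @export
partition_regions <- function(inputs) {
  if (is.null(names(inputs)) || any(!nzchar(names(inputs))))
    stop("partition_regions: inputs must be a named list")
  if (length(inputs) < 2L)
    stop("partition_regions: need at least two input sets")
  labels <- names(inputs)
  dfs <- lapply(labels, function(l) {
    d <- as.data.frame(inputs[[l]])[, c("chrom", "start", "end"), drop = FALSE]
    if (nrow(d)) d$src <- l
    d
  })
  all_df <- do.call(rbind, dfs[vapply(dfs, nrow, 0L) > 0L])
  if (is.null(all_df) || nrow(all_df) == 0L)
    stop("partition_regions: all input sets are empty")
  out <- lapply(split(all_df, all_df$chrom), function(sub) {
    bounds <- sort(unique(c(sub$start, sub$end)))
    seg_start <- bounds[-length(bounds)]
    seg_end <- bounds[-1L]
    # membership of each candidate segment: a segment never straddles an
    # input boundary, so covered-at-start implies fully covered
    memb <- matrix(FALSE, length(seg_start), length(labels),
                   dimnames = list(NULL, labels))
    for (l in unique(sub$src)) {
      s <- sub[sub$src == l, , drop = FALSE]
      idx <- findInterval(seg_start, s$start)
      memb[, l] <- idx >= 1L & seg_start < s$end[pmax(idx, 1L)]
    }
    inside <- rowSums(memb) > 0L
    if (!any(inside)) return(NULL)
    memb <- memb[inside, , drop = FALSE]
    seg_start <- seg_start[inside]
    seg_end <- seg_end[inside]
    n <- length(seg_start)
    adj_left <- c(FALSE, seg_start[-1L] == seg_end[-n])
    adj_right <- c(seg_start[-1L] == seg_end[-n], FALSE)
    data.frame(chrom = sub$chrom[1L], start = seg_start, end = seg_end,
               membership = apply(memb, 1L, function(r)
                 paste(labels[r], collapse = ",")),
               adj_left = adj_left, adj_right = adj_right,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, labels = labels,
            class = c("partitioned_segments", "data.frame"))
}

#' @export
print.partitioned_segments <- function(x, ...) {
  cat(sprintf("<partitioned_segments: %d segment(s) from sets {%s}>\n",
              nrow(x), paste(attr(x, "labels"), collapse = ", ")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 6L))
  invisible(x)
}

#' Dominant-segment length filter for differential domains
#'
#' Applies the two length rules that turn partitioned segments into the
#' differential-domain list used for clustering: a segment directly
#' adjacent to another partitioned segment (sharing a boundary coordinate
#' on either side) is kept only if it is at least `adjacent_min` bp long —
#' selecting the dominant segment in each region of partitioning overlap
#' and avoiding doubly mapping adjacent segments — and a free-standing
#' segment is kept only if it is at least `freestanding_min` bp long.
#' Segments shorter than the applicable threshold are dropped; length
#' exactly at the threshold is kept. In a chain of three or more mutually
#' adjacent segments the adjacent rule applies to every segment
#' independently, and both members of an adjacent pair may be dropped.
#'
#' @param parts A `partitioned_segments` object from [partition_regions()].
#' @param adjacent_min Minimum length (bp) for adjacent segments
#'   (default 10000).
#' @param freestanding_min Minimum length (bp) for free-standing segments
#'   (default 3000).
#' @return A [region_set()] of surviving segments, membership annotation
#'   retained.
#' @export
filter_dominant <- function(parts, adjacent_min = 10000,
                            freestanding_min = 3000) {
  len <- parts$end - parts$start
  adjacent <- parts$adj_left | parts$adj_right
  keep <- ifelse(adjacent, len >= adjacent_min, len >= freestanding_min)
  kept <- as.data.frame(parts)[keep, , drop = FALSE]
  region_set(kept$chrom, kept$start, kept$end,
             label = "differential_domains", membership = kept$membership)
}
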