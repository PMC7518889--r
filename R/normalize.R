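#' Spike-in calibration factor
#'
#' The per-sample spike-in normalization factor is a fixed constant
#' (default 10,000) divided by the number of spike-in reads mapped for that
#' sample. Multiplying a sample's primary-genome signal by this factor puts
#' all samples on a common absolute scale, because each CUT&RUN reaction
#' received the same quantity of spike-in chromatin.
#'
#' @param spike_reads Positive integer count of mapped spike-in reads
#'   (fragments).
#' @param constant Numerator constant; 10,000 by default.
#' @return A `spike_scale` object with fields `spike_reads`, `constant`
#'   and `factor = constant / spike_reads`.
#' @examples
#' spike_scale_factor(20000)$factor   # 0.5
#' @export
spike_scale_factor <- function(spike_reads, constant = 10000) {
  if (length(spike_reads) != 1L || is.na(spike_reads) || spike_reads <= 0 ||
      spike_reads != floor(spike_reads))
    stop("spike_scale_factor: spike_reads must be a positive integer; ",
         "a sample with no spike-in reads cannot be calibrated")
  if (!is.finite(constant) || constant <= 0)
    stop("spike_scale_factor: constant must be positive")
  structure(list(spike_reads = as.double(spike_reads),
                 constant = as.double(constant),
                 factor = constant / spike_reads),
            class = "spike_scale")
}

#' @export
print.spike_scale <- function(x, ...) {
  cat(sprintf("<spike_scale: %g / %g spike reads = %.6g>\n",
              x$constant, x$spike_reads, x$factor))
  invisible(x)
}

#' Binned base-pair coverage of a genome
#'
#' Sums fragment base-pair counts into fixed-width bins. A fragment spanning
#' a bin boundary contributes to each bin pro-rata by overlap, so the sum
#' over all bins equals the total fragment base pairs exactly. With
#' `bin_width = 1` the track is per-base-pair fragment coverage.
#'
#' @param frags A [fragment_set()] (primary fragments are used).
#' @param sizes Primary-genome [chrom_sizes()].
#' @param bin_width Bin width in bp (default 5000).
#' @return A `coverage_track`: per-chromosome run-length encoded bin values,
#'   with the bin width and any applied scale factor recorded.
#' @export
binned_coverage <- function(frags, sizes, bin_width = 5000) {
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("binned_coverage: bin_width must be positive")
  bin_width <- as.integer(bin_width)
  df <- if (inherits(frags, "fragment_set")) frags$primary else frags
  validate_intervals(df, sizes, "fragment")
  vals <- lapply(names(sizes), function(chrom) {
    len <- unclass(sizes)[[chrom]]
    sub <- df[df$chrom == chrom, , drop = FALSE]
    cov <- IRanges::coverage(IRanges::IRanges(start = sub$start + 1L,
                                              end = sub$end),
                             width = len)
    if (bin_width == 1L) return(S4Vectors::Rle(as.numeric(S4Vectors::runValue(cov)),
                                               S4Vectors::runLength(cov)))
    starts <- seq.int(1L, len, by = bin_width)
    ends <- pmin(starts + bin_width - 1L, len)
    v <- IRanges::viewSums(IRanges::Views(cov, start = starts, end = ends))
    S4Vectors::Rle(as.numeric(v))
  })
  names(vals) <- names(sizes)
  structure(list(sizes = sizes, bin_width = bin_width, values = vals,
                 scale_factor = NULL),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track: %d chromosome(s), bin %d bp, %s>\n",
              length(x$values), x$bin_width,
              if (is.null(x$scale_factor)) "unscaled"
              else sprintf("scale factor %.6g", x$scale_factor)))
  invisible(x)
}

#' Numeric bin values of one chromosome of a coverage track
#' @param track A `coverage_track`.
#' @param chrom Chromosome name.
#' @return Numeric vector, one value per bin.
#' @export
track_values <- function(track, chrom) {
  as.numeric(track$values[[chrom]])
}

#' Apply a spike-in scale factor to a coverage track
#'
#' Every bin value is multiplied by the sample's spike factor. A track can
#' be scaled once; re-scaling is an error (it would silently double-apply
#' calibration).
#'
#' @param track An unscaled `coverage_track`.
#' @param scale A [spike_scale_factor()] object.
#' @return The scaled track, with the factor recorded.
#' @export
scale_track <- function(track, scale) {
  if (!is.null(track$scale_factor))
    stop("scale_track: track already scaled (factor ",
         format(track$scale_factor), ")")
  f <- if (inherits(scale, "spike_scale")) scale$factor else as.double(scale)
  track$values <- lapply(track$values, function(v) v * f)
  track$scale_factor <- f
  track
}

#' Rank genome-wide bin counts in descending order
#'
#' Flattens a binned track into one row per bin and orders rows by
#' descending value; ties are broken by genomic position (chromosome order
#' in the track, then start), so the ranking is deterministic.
#'
#' A steeply decaying ranked curve indicates signal concentrated in few
#' bins (peaky, turnover-coupled deposition); a flat curve indicates
#' uniform genome-wide signal (replication-coupled deposition).
#'
#' @param track A `coverage_track`.
#' @return data.frame with columns chrom, start, end, value, rank.
#' @export
ranked_bin_counts <- function(track) {
  rows <- lapply(names(track$values), function(chrom) {
    v <- track_values(track, chrom)
    len <- unclass(track$sizes)[[chrom]]
    starts <- seq.int(0L, by = track$bin_width, length.out = length(v))
    data.frame(chrom = chrom, start = starts,
               end = pmin(starts + track$bin_width, len),
               value = v, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  chrom_rank <- match(df$chrom, names(track$sizes))
  df <- df[order(-df$value, chrom_rank, df$start), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Write a coverage track as bedGraph
#'
#' Four columns (chrom, start, end, value), 0-based half-open, values with
#' six decimal places. Runs of equal value are emitted as single lines and
#' zero-valued runs are omitted.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    rl <- S4Vectors::runLength(v) * track$bin_width
    rv <- S4Vectors::runValue(v)
    ends <- pmin(cumsum(as.numeric(rl)), unclass(track$sizes)[[chrom]])
    starts <- c(0, ends[-length(ends)])
    keep <- rv != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%.6f", chrom,
                       as.integer(starts[keep]), as.integer(ends[keep]),
                       rv[keep]), con)
  }
  invisible(path)
}

#' Read a bedGraph file back into a coverage track
#'
#' Inverse of [write_bedgraph()] for tracks written by this package:
#' intervals must be sorted and non-overlapping; gaps are zero-filled.
#'
#' @param path bedGraph file.
#' @param sizes [chrom_sizes()] governing the track.
#' @param bin_width Bin width the track was built with (1 for per-bp).
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, sizes, bin_width = 1) {
  n <- file.size(path)
  empty <- is.na(n) || n == 0L
  df <- if (empty) NULL else
    utils::read.table(path, sep = "\t", header = FALSE,
                      col.names = c("chrom", "start", "end", "value"),
                      stringsAsFactors = FALSE)
  vals <- lapply(names(sizes), function(chrom) {
    len <- unclass(sizes)[[chrom]]
    nb <- ceiling(len / bin_width)
    out <- S4Vectors::Rle(0, nb)
    sub <- if (is.null(df)) NULL else df[df$chrom == chrom, , drop = FALSE]
    if (!is.null(sub) && nrow(sub)) {
      sub <- sub[order(sub$start), , drop = FALSE]
      if (any(sub$start[-1L] < sub$end[-nrow(sub)]))
        stop("read_bedgraph: overlapping intervals")
      i0 <- sub$start %/% bin_width
      i1 <- (sub$end - 1) %/% bin_width
      for (r in seq_len(nrow(sub)))
        out[(i0[r] + 1):(i1[r] + 1)] <- sub$value[r]
    }
    out
  })
  names(vals) <- names(sizes)
  structure(list(sizes = sizes, bin_width = as.integer(bin_width),
                 values = vals, scale_factor = NULL),
            class = "coverage_track")
}
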