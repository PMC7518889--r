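#' @importFrom utils read.table write.table head tail
#' @importFrom stats quantile rnorm runif setNames
NULL

# All coordinates throughout the package are BED-standard 0-based half-open:
# an interval covers base pairs start .. end-1 and has length end - start.

#' Chromosome sizes for one genome
#'
#' A `chrom_sizes` object is a named integer vector of chromosome lengths in
#' base pairs, tagged with a genome label distinguishing the primary (e.g.
#' human) genome from the heterologous spike-in genome.
#'
#' @param lengths Named numeric/integer vector of chromosome lengths (bp).
#' @param genome Genome label, `"primary"` or `"spike"`.
#' @return A `chrom_sizes` object.
#' @examples
#' chrom_sizes(c(chr1 = 5e6, chr2 = 5e6), "primary")
#' @export
chrom_sizes <- function(lengths, genome = c("primary", "spike")) {
  genome <- match.arg(genome)
  if (length(lengths) == 0L) stop("chrom_sizes: no chromosomes given")
  nm <- names(lengths)
  if (is.null(nm) || any(!nzchar(nm))) stop("chrom_sizes: chromosomes must be named")
  if (anyDuplicated(nm)) stop("chrom_sizes: duplicate chromosome name")
  if (any(!is.finite(lengths)) || any(lengths != floor(lengths)))
    stop("chrom_sizes: lengths must be integers")
  if (any(lengths <= 0)) stop("chrom_sizes: non-positive chromosome length")
  structure(setNames(as.double(lengths), nm),
            genome = genome, class = "chrom_sizes")
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a whitespace-delimited text file with columns
#'   chromosome name and length (bp).
#' @inheritParams chrom_sizes
#' @return A [chrom_sizes()] object with entries in file order.
#' @export
read_chrom_sizes <- function(path, genome = c("primary", "spike")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("read_chrom_sizes: empty file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(fields) < 2L)) stop("read_chrom_sizes: line with fewer than 2 fields")
  nm <- vapply(fields, `[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  if (any(is.na(len))) stop("read_chrom_sizes: non-integer length")
  chrom_sizes(setNames(len, nm), genome)
}

#' @export
print.chrom_sizes <- function(x, ...) {
  cat(sprintf("<chrom_sizes: %s genome, %d chromosome(s), %s bp>\n",
              attr(x, "genome"), length(x),
              format(sum(x), big.mark = ",")))
  invisible(x)
}

# validate a chrom/start/end data.frame against a chrom_sizes object
validate_intervals <- function(df, sizes, what = "interval") {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start < 0)) stop(what, ": negative start coordinate")
  if (any(df$end <= df$start)) stop(what, ": end <= start (intervals are 0-based half-open)")
  bad <- !(df$chrom %in% names(sizes))
  if (any(bad)) stop(what, ": unknown chromosome ", df$chrom[which(bad)[1L]])
  if (any(df$end > unclass(sizes)[df$chrom]))
    stop(what, ": interval exceeds chromosome length")
  invisible(df)
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = double(), end = double(),
             stringsAsFactors = FALSE)
}

sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

#' Sorted non-overlapping region set
#'
#' Strand-less genomic intervals (peaks or domains) on the primary genome,
#' sorted by (chrom, start) and pairwise non-overlapping. Abutting intervals
#' are permitted; overlap is not.
#'
#' @param chrom,start,end Parallel vectors (0-based half-open coordinates).
#' @param label Set label carried as an attribute (e.g. a sample name).
#' @param membership Optional character vector of per-region provenance
#'   annotations (comma-separated source labels), carried through
#'   partitioning and filtering.
#' @return A `region_set`: a data.frame with columns chrom/start/end and
#'   optionally membership.
#' @export
region_set <- function(chrom = character(), start = double(), end = double(),
                       label = NA_character_, membership = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.double(start),
                   end = as.double(end), stringsAsFactors = FALSE)
  if (!is.null(membership)) df$membership <- as.character(membership)
  if (nrow(df) > 0L) {
    if (any(df$start < 0)) stop("region_set: negative start")
    if (any(df$end <= df$start)) stop("region_set: end <= start")
    df <- sort_intervals(df)
    same <- df$chrom[-1L] == df$chrom[-nrow(df)]
    if (nrow(df) > 1L && any(same & df$start[-1L] < df$end[-nrow(df)]))
      stop("region_set: overlapping intervals")
  }
  rownames(df) <- NULL
  structure(df, label = label, class = c("region_set", "data.frame"))
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set '%s': %d interval(s), %s bp>\n",
              attr(x, "label"), nrow(x),
              format(sum(x$end - x$start), big.mark = ",")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 6L))
  invisible(x)
}

#' A sample's mapped paired-end fragments
#'
#' Holds one CUT&RUN sample's fragments as genomic intervals, split by
#' genome of origin. The spike read count is the number of fragments mapped
#' to the spike-in genome and drives spike calibration.
#'
#' @param sample_id Sample identifier.
#' @param target Profiled target label (e.g. `"H3K27me3"`, `"IgG"`).
#' @param primary data.frame chrom/start/end of primary-genome fragments.
#' @param spike data.frame chrom/start/end of spike-genome fragments.
#' @param primary_sizes,spike_sizes [chrom_sizes()] the fragments are
#'   validated against; `spike_sizes` may be `NULL` when no spike fragments
#'   are present.
#' @return A `fragment_set` object.
#' @export
fragment_set <- function(sample_id, target, primary, spike = empty_intervals(),
                         primary_sizes = NULL, spike_sizes = NULL) {
  if (!is.null(primary_sizes)) validate_intervals(primary, primary_sizes, "fragment")
  if (!is.null(spike_sizes)) validate_intervals(spike, spike_sizes, "spike fragment")
  structure(list(sample_id = sample_id, target = target,
                 primary = sort_intervals(primary),
                 spike = sort_intervals(spike),
                 spike_reads = nrow(spike)),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set '%s' (%s): %d primary, %d spike fragment(s)>\n",
              x$sample_id, x$target, nrow(x$primary), x$spike_reads))
  invisible(x)
}

#' Read a paired-end fragment BED file
#'
#' Fragments are routed to the primary or spike genome by chromosome-name
#' membership: a combined fragment file carries both genomes in one
#' namespace, with spike chromosomes identified by the spike
#' [chrom_sizes()]. Coordinates are 0-based half-open.
#'
#' @param path BED3(+) file of fragment intervals.
#' @param primary,spike [chrom_sizes()] for the two genomes.
#' @param sample_id,target Labels stored on the returned set.
#' @param unknown_chrom `"skip"` drops fragments on chromosomes in neither
#'   genome (with a message giving the count); `"error"` aborts.
#' @return A [fragment_set()].
#' @export
read_fragment_bed <- function(path, primary, spike = NULL,
                              sample_id = basename(path), target = NA_character_,
                              unknown_chrom = c("skip", "error")) {
  unknown_chrom <- match.arg(unknown_chrom)
  n <- file.size(path)
  if (is.na(n)) stop("read_fragment_bed: no such file: ", path)
  if (n == 0L) {
    return(fragment_set(sample_id, target, empty_intervals(), empty_intervals(),
                        primary, spike))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, fill = FALSE,
                          comment.char = "#", blank.lines.skip = TRUE,
                          colClasses = "character")
  if (ncol(df) < 3L) stop("read_fragment_bed: BED needs >= 3 columns")
  out <- data.frame(chrom = df[[1L]],
                    start = suppressWarnings(as.numeric(df[[2L]])),
                    end = suppressWarnings(as.numeric(df[[3L]])),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$start)) || any(is.na(out$end)))
    stop("read_fragment_bed: non-numeric coordinate")
  if (any(out$end <= out$start))
    stop("read_fragment_bed: end <= start (0-based half-open intervals)")
  spike_names <- if (is.null(spike)) character() else names(spike)
  is_primary <- out$chrom %in% names(primary)
  is_spike <- out$chrom %in% spike_names
  unknown <- !(is_primary | is_spike)
  if (any(unknown)) {
    if (unknown_chrom == "error")
      stop("read_fragment_bed: unknown chromosome ", out$chrom[which(unknown)[1L]])
    message(sprintf("read_fragment_bed: skipped %d fragment(s) on unknown chromosomes",
                    sum(unknown)))
  }
  fragment_set(sample_id, target,
               primary = out[is_primary, , drop = FALSE],
               spike = out[is_spike, , drop = FALSE],
               primary_sizes = primary, spike_sizes = spike)
}

#' Read a BED3 region file
#'
#' The reader sorts intervals; overlapping input is either rejected or
#' merged (union) according to `overlap`. Abutting intervals are kept as-is.
#'
#' @param path BED3 file.
#' @param label Label for the returned set.
#' @param overlap `"error"` (default) or `"merge"`.
#' @return A [region_set()].
#' @export
read_region_bed <- function(path, label = basename(path),
                            overlap = c("error", "merge")) {
  overlap <- match.arg(overlap)
  n <- file.size(path)
  if (is.na(n)) stop("read_region_bed: no such file: ", path)
  if (n == 0L) return(region_set(label = label))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  out <- data.frame(chrom = as.character(df[[1L]]), start = as.numeric(df[[2L]]),
                    end = as.numeric(df[[3L]]), stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) stop("read_region_bed: end <= start")
  out <- sort_intervals(out)
  same <- out$chrom[-1L] == out$chrom[-nrow(out)]
  has_overlap <- nrow(out) > 1L && any(same & out$start[-1L] < out$end[-nrow(out)])
  if (has_overlap) {
    if (overlap == "error") stop("read_region_bed: overlapping intervals")
    gr <- GenomicRanges::reduce(df_to_gr(out), min.gapwidth = 0L)
    out <- gr_to_df(gr)
  }
  region_set(out$chrom, out$start, out$end, label = label)
}

#' Write a region set as BED
#'
#' BED3, or BED4 with the membership annotation as the name column when
#' present. Tab-delimited, LF endings.
#'
#' @param regions A [region_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(regions, path) {
  if (nrow(regions) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  cols <- sprintf("%s\t%d\t%d", regions$chrom, as.integer(regions$start),
                  as.integer(regions$end))
  if (!is.null(regions$membership))
    cols <- paste(cols, regions$membership, sep = "\t")
  writeLines(cols, path, sep = "\n")
  invisible(path)
}

# data.frame (0-based half-open) <-> GRanges (1-based closed)
df_to_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

gr_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = as.double(GenomicRanges::end(gr)),
             stringsAsFactors = FALSE)
}
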