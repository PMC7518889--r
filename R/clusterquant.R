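#' Region-by-sample fragment count matrix
#'
#' Counts, for every region and sample, the primary-genome fragments that
#' overlap the region by at least `min_overlap` bp (default 1, the classic
#' intersect convention). When per-sample spike scales are supplied, each
#' sample's counts are multiplied by its spike factor, putting columns on
#' a common absolute scale.
#'
#' @param regions A non-overlapping [region_set()] (overlap would count a
#'   fragment twice ambiguously and is an error — enforced by the class).
#' @param samples Named list of [fragment_set()] objects; names become
#'   column names.
#' @param scales Optional named list of [spike_scale_factor()] objects
#'   (same names as `samples`), or `NULL` for raw counts.
#' @param min_overlap Minimum fragment/region overlap in bp.
#' @return A `signal_matrix`: numeric matrix (regions x samples) with the
#'   region set and a per-sample scaling record in attributes.
#' @export
signal_matrix <- function(regions, samples, scales = NULL, min_overlap = 1) {
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    stop("signal_matrix: samples must be a named list")
  if (!is.null(scales) && !setequal(names(scales), names(samples)))
    stop("signal_matrix: scales must be named like samples")
  gr <- df_to_gr(as.data.frame(regions))
  counts <- vapply(names(samples), function(s) {
    frags <- samples[[s]]$primary
    if (nrow(frags) == 0L) return(double(length(gr)))
    fgr <- df_to_gr(frags)
    as.double(GenomicRanges::countOverlaps(gr, fgr,
                                           minoverlap = as.integer(min_overlap)))
  }, double(length(gr)))
  counts <- matrix(counts, nrow = length(gr), ncol = length(samples),
                   dimnames = list(NULL, names(samples)))
  scaling <- data.frame(sample = names(samples), spike_factor = NA_real_,
                        fpk = FALSE, stringsAsFactors = FALSE)
  if (!is.null(scales)) {
    f <- vapply(names(samples), function(s) scales[[s]]$factor, 0)
    counts <- sweep(counts, 2L, f, `*`)
    scaling$spike_factor <- f
  }
  structure(counts, regions = regions, scaling = scaling,
            class = c("signal_matrix", class(counts)))
}

#' Fragments-per-kilobase scaling of a signal matrix
#'
#' Region quantification scaling: each entry is first scaled by fragments
#' per kilobase (multiplied by 1000 / region length) and then by a
#' per-sample scaling constant inversely proportional to the sample's
#' mapped spike-in reads.
#'
#' @param matrix A raw-count `signal_matrix` from [signal_matrix()] (built
#'   with `scales = NULL`).
#' @param constants Named numeric vector or list of per-sample scaling
#'   constants (e.g. `spike_scale_factor(n)$factor`), or
#'   [spike_scale_factor()] objects.
#' @return The scaled `signal_matrix`; the scaling record notes FPK and the
#'   constants.
#' @export
fpk_scale <- function(matrix, constants) {
  scaling <- attr(matrix, "scaling")
  if (any(scaling$fpk) || !all(is.na(scaling$spike_factor)))
    stop("fpk_scale: matrix already scaled")
  cn <- colnames(matrix)
  if (is.null(names(constants)) || !setequal(names(constants), cn))
    stop("fpk_scale: constants must be named like the matrix columns")
  f <- vapply(cn, function(s) {
    k <- constants[[s]]
    if (inherits(k, "spike_scale")) k$factor else as.double(k)
  }, 0)
  regions <- attr(matrix, "regions")
  len <- regions$end - regions$start
  out <- unclass(matrix) * (1000 / len)
  out <- sweep(out, 2L, f, `*`)
  scaling$fpk <- TRUE
  scaling$spike_factor <- f
  structure(out, regions = regions, scaling = scaling,
            class = class(matrix))
}

#' K-means clustering of matrix rows
#'
#' Standard k-means (Lloyd's algorithm, Euclidean distance on rows) with
#' `restarts` random initializations, keeping the solution with the lowest
#' total within-cluster sum of squares. Fully deterministic given `seed`.
#' By default rows are log2(x + 1)-transformed first, which tames the
#' heavy-tailed fragment-count distributions; set `transform = "none"` to
#' cluster the values as-is.
#'
#' @param matrix A `signal_matrix` (or plain numeric matrix).
#' @param k Number of clusters, 2 <= k <= nrow.
#' @param seed Integer seed.
#' @param restarts Number of random starts (default 25).
#' @param transform `"log2"` (default) or `"none"`.
#' @return A `cluster_assignment`: list with `k`, `cluster` (per-row id in
#'   1..k), `tot_withinss`, `seed`, `restarts`.
#' @export
kmeans_cluster <- function(matrix, k, seed, restarts = 25,
                           transform = c("log2", "none")) {
  transform <- match.arg(transform)
  x <- unclass(matrix)
  attr(x, "regions") <- NULL
  attr(x, "scaling") <- NULL
  if (k < 2L) stop("kmeans_cluster: k must be >= 2")
  if (nrow(x) < k) stop("kmeans_cluster: fewer rows than clusters")
  if (transform == "log2") x <- log2(x + 1)
  set.seed(seed)
  fit <- NULL
  for (i in seq_len(restarts)) {
    # Lloyd's algorithm can abandon a start when a cluster empties out;
    # such starts are skipped and the best surviving solution kept
    f <- tryCatch(suppressWarnings(
      stats::kmeans(x, centers = k, nstart = 1L,
                    iter.max = 200L, algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(fit) || f$tot.withinss < fit$tot.withinss))
      fit <- f
  }
  if (is.null(fit))
    stop("kmeans_cluster: no restart converged (k = ", k, ")")
  structure(list(k = k, cluster = as.integer(fit$cluster),
                 tot_withinss = fit$tot.withinss,
                 centers = fit$centers, seed = seed, restarts = restarts,
                 transform = transform),
            class = "cluster_assignment")
}

#' Select the number of clusters at the knee of the within-cluster curve
#'
#' Runs [kmeans_cluster()] for every k from `k_min` to `k_max`, plus the
#' trivial one-cluster solution (total sum of squares), and selects the k
#' with the largest discrete second difference of the within-cluster
#' distance curve — the point of maximum curvature, i.e. the knee. Ties go
#' to the smaller k.
#'
#' @inheritParams kmeans_cluster
#' @param k_min,k_max Scan range (defaults 2 and 15).
#' @return List with `k` (selected), `withinss` (named vector over the
#'   scan, including k = 1), and `assignments` (per-k
#'   `cluster_assignment`s).
#' @export
select_k_knee <- function(matrix, k_min = 2, k_max = 15, seed = 1,
                          restarts = 25, transform = c("log2", "none")) {
  transform <- match.arg(transform)
  x <- unclass(matrix)
  if (nrow(x) < k_max) stop("select_k_knee: fewer rows than k_max")
  if (k_min < 2 || k_min >= k_max) stop("select_k_knee: need 2 <= k_min < k_max")
  fits <- lapply(k_min:k_max, function(k)
    kmeans_cluster(matrix, k, seed = seed + k, restarts = restarts,
                   transform = transform))
  xt <- if (transform == "log2") log2(x + 1) else x
  w1 <- sum(scale(xt, scale = FALSE)^2)
  w <- c(w1, vapply(fits, `[[`, 0, "tot_withinss"))
  names(w) <- as.character(c(1L, k_min:k_max))
  if (any(diff(w) > 0))
    message("select_k_knee: within-cluster distance not monotone over the scan")
  # second difference at interior points k_min .. k_max-1
  ks <- k_min:(k_max - 1L)
  d2 <- w[as.character(ks - 1L)] - 2 * w[as.character(ks)] +
    w[as.character(ks + 1L)]
  sel <- ks[which.max(d2)]   # which.max takes the first maximum: smaller k
  list(k = sel, withinss = w, assignments = setNames(fits, k_min:k_max),
       selected = fits[[match(sel, k_min:k_max)]])
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Overlap summary from counts
#'
#' @param shared,total Interval counts, 0 <= shared <= total, total > 0.
#' @param decimals Decimal places for the percentage (round half up).
#' @return An `overlap_summary`: list with `shared`, `total`, `percent`.
#' @examples
#' overlap_summary(5259, 24733, 1)$percent  # 21.3
#' @export
overlap_summary <- function(shared, total, decimals = 1) {
  if (total <= 0) stop("overlap_summary: total must be positive")
  if (shared < 0 || shared > total) stop("overlap_summary: need 0 <= shared <= total")
  structure(list(shared = shared, total = total,
                 percent = round_half_up(100 * shared / total, decimals),
                 decimals = decimals),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("%s of %s intervals shared (%s%%)\n",
              format(x$shared, big.mark = ","), format(x$total, big.mark = ","),
              formatC(x$percent, format = "f", digits = x$decimals)))
  invisible(x)
}

#' Fraction of query intervals overlapping a reference set
#'
#' Counts query intervals that overlap at least one reference interval by
#' at least `min_overlap` bp, and reports the percentage of the query
#' total (round half up at `decimals`).
#'
#' @param query,reference [region_set()] objects.
#' @param decimals Decimal places of the reported percentage.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return An [overlap_summary()].
#' @export
overlap_fraction <- function(query, reference, decimals = 1, min_overlap = 1) {
  if (nrow(query) == 0L)
    stop("overlap_fraction: empty query (percentage undefined)")
  qgr <- df_to_gr(as.data.frame(query))
  rgr <- df_to_gr(as.data.frame(reference))
  hits <- GenomicRanges::countOverlaps(qgr, rgr,
                                       minoverlap = as.integer(min_overlap))
  overlap_summary(sum(hits > 0), length(qgr), decimals)
}

#' TSS-centered signal matrix
#'
#' Builds one row per transcription start site: binned, optionally
#' spike-scaled fragment coverage in `[pos - window, pos + window)`, with
#' rows ordered by descending signal in a +/-500 bp core window (or by a
#' caller-supplied score). Windows truncated by a chromosome edge are
#' zero-padded.
#'
#' @param frags A [fragment_set()].
#' @param sizes Primary [chrom_sizes()].
#' @param tss data.frame with columns chrom, pos (0-based TSS coordinate).
#' @param window Half-window in bp (default 1000).
#' @param bin_width Column bin width in bp (default 100).
#' @param scale Optional [spike_scale_factor()].
#' @param order_by Optional numeric per-TSS score; default is the scaled
#'   fragment count within +/-500 bp of each TSS.
#' @return Numeric matrix (TSS x bins), ordered rows; attribute `order`
#'   maps rows back to input TSS indices, `score` holds the ordering score.
#' @export
tss_matrix <- function(frags, sizes, tss, window = 1000, bin_width = 100,
                       scale = NULL, order_by = NULL) {
  if (window <= 0) stop("tss_matrix: window must be positive")
  f <- if (is.null(scale)) 1 else scale$factor
  nb <- ceiling(2 * window / bin_width)
  covs <- lapply(names(sizes), function(chrom) {
    sub <- frags$primary[frags$primary$chrom == chrom, , drop = FALSE]
    IRanges::coverage(IRanges::IRanges(sub$start + 1L, sub$end),
                      width = unclass(sizes)[[chrom]])
  })
  names(covs) <- names(sizes)
  n_edge <- 0L
  rows <- matrix(0, nrow(tss), nb)
  core <- double(nrow(tss))
  for (i in seq_len(nrow(tss))) {
    chrom <- tss$chrom[i]
    len <- unclass(sizes)[[chrom]]
    lo <- tss$pos[i] - window
    hi <- tss$pos[i] + window
    if (lo < 0 || hi > len) n_edge <- n_edge + 1L
    starts <- seq.int(lo, hi - 1, by = bin_width) + 1
    ends <- pmin(starts + bin_width - 1, len)
    ok <- starts >= 1 & starts <= len
    v <- double(nb)
    if (any(ok))
      v[ok] <- as.numeric(IRanges::viewSums(
        IRanges::Views(covs[[chrom]], start = starts[ok], end = ends[ok])))
    rows[i, ] <- v * f
    cs <- max(tss$pos[i] - 500, 0) + 1
    ce <- min(tss$pos[i] + 500, len)
    core[i] <- f * sum(IRanges::viewSums(
      IRanges::Views(covs[[chrom]], start = cs, end = ce)))
  }
  if (n_edge > 0L)
    message(sprintf("tss_matrix: %d TSS window(s) truncated at a chromosome edge",
                    n_edge))
  score <- if (is.null(order_by)) core else as.double(order_by)
  ord <- order(-score, seq_along(score))
  structure(rows[ord, , drop = FALSE], order = ord, score = score[ord])
}

#' Squared correlation between promoter signal and expression
#'
#' Pearson R^2 between log2(x + 1)-transformed promoter-window fragment
#' counts and per-gene expression counts.
#'
#' @param tss_counts,expression Paired non-negative numeric vectors,
#'   length >= 3.
#' @return Squared Pearson correlation (scalar).
#' @export
tss_window_correlation <- function(tss_counts, expression) {
  if (length(tss_counts) != length(expression) || length(tss_counts) < 3L)
    stop("tss_window_correlation: need paired vectors of length >= 3")
  x <- log2(tss_counts + 1)
  y <- log2(expression + 1)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("tss_window_correlation: zero-variance vector")
  stats::cor(x, y)^2
}

#' Per-cluster, per-sample five-number summaries
#'
#' Box-and-whisker statistics (min, Q1, median, Q3, max; quartiles by the
#' standard type-7 quantile) of an FPK-scaled signal matrix, split by
#' cluster assignment. Empty clusters yield NA rows with a message.
#'
#' @param matrix A `signal_matrix` (typically after [fpk_scale()]).
#' @param assignment A `cluster_assignment` (or integer vector of cluster
#'   ids per row).
#' @return data.frame with columns cluster, sample, n, min, q1, median,
#'   q3, max.
#' @export
cluster_region_stats <- function(matrix, assignment) {
  cl <- if (inherits(assignment, "cluster_assignment")) assignment$cluster
        else as.integer(assignment)
  if (length(cl) != nrow(matrix))
    stop("cluster_region_stats: assignment length != matrix rows")
  out <- expand.grid(cluster = sort(unique(cl)), sample = colnames(matrix),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stats_rows <- lapply(seq_len(nrow(out)), function(i) {
    v <- unclass(matrix)[cl == out$cluster[i], out$sample[i]]
    if (length(v) == 0L) {
      message("cluster_region_stats: empty cluster ", out$cluster[i])
      return(c(n = 0, min = NA, q1 = NA, median = NA, q3 = NA, max = NA))
    }
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
    c(n = length(v), min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
  })
  cbind(out, do.call(rbind, stats_rows))
}
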