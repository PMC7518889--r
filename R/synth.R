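#' Default toy genome for simulations
#'
#' Two 5 Mb primary chromosomes plus one 500 kb spike-in chromosome: large
#' enough that 5 kb bins and the 10 kb / 3 kb dominant-segment filters are
#' meaningful, small enough for seconds-scale simulation.
#'
#' @return List with elements `primary` and `spike`, both [chrom_sizes()].
#' @export
toy_genome <- function() {
  list(primary = chrom_sizes(c(chr1 = 5e6, chr2 = 5e6), "primary"),
       spike = chrom_sizes(c(spikeI = 5e5), "spike"))
}

#' Ground-truth deposition model for simulated CUT&RUN samples
#'
#' Encodes one of four biological regimes as a piecewise-constant fragment
#' intensity over a primary plus spike-in genome:
#' \describe{
#'   \item{`domain_mark`}{broad silenced domains (widths sampled between
#'     `domain_width[1]` and `domain_width[2]`, default 10-200 kb) at
#'     `domain_multiplier` times a uniform background — an H3K27me3-like
#'     Polycomb landscape.}
#'   \item{`turnover_peaky`}{narrow promoter peaks over a low uniform
#'     background, with per-peak multipliers drawn log-uniformly between 1
#'     and `peak_multiplier` to emulate expression-graded histone turnover
#'     — an H3.3K27M-like landscape.}
#'   \item{`replication_coupled_uniform`}{a uniform genome-wide rate with
#'     no planted features — an H3.1K27M-like, replication-coupled
#'     landscape.}
#'   \item{`flat_background`}{uniform low rate — an IgG-like control.}
#' }
#' Spike-in chromatin is modeled as uniform coverage of the spike genome
#' whose intensity share follows from the spike:primary cell ratio
#' (default 1:20) and the two genome sizes.
#'
#' @param profile One of the four regime names above.
#' @param genome List with `primary` and `spike` [chrom_sizes()]
#'   (default [toy_genome()]).
#' @param seed Integer seed for all placements.
#' @param n_domains,domain_width,domain_multiplier Domain count, width
#'   range (bp) and enrichment multiplier for `domain_mark`.
#' @param domains Optional pre-specified [region_set()] of domains
#'   (overrides sampling); `domain_multiplier` may then be a vector.
#' @param tss Optional data.frame (chrom, pos) of promoter positions for
#'   `turnover_peaky`; one peak is planted per TSS. Defaults to `n_peaks`
#'   positions sampled uniformly.
#' @param n_peaks,peak_width,peak_multiplier Peak count (when `tss` is
#'   NULL), width (bp) and maximum multiplier.
#' @param background_rate Background intensity (arbitrary units per bp;
#'   only ratios matter).
#' @param spike_ratio Spike:primary cell ratio (default 1/20).
#' @param spike_rate Spike-genome intensity per bp per cell-equivalent
#'   (default = `background_rate`).
#' @param frag_len_mean,frag_len_sd Nucleosomal fragment length
#'   distribution (bp), truncated at 50.
#' @return A `truth_model` object.
#' @export
make_truth <- function(profile = c("domain_mark", "turnover_peaky",
                                   "replication_coupled_uniform",
                                   "flat_background"),
                       genome = toy_genome(), seed = 1,
                       n_domains = 15, domain_width = c(10000, 200000),
                       domain_multiplier = 20, domains = NULL,
                       tss = NULL, n_peaks = 100, peak_width = 1000,
                       peak_multiplier = 50,
                       background_rate = 1, spike_ratio = 1 / 20,
                       spike_rate = background_rate,
                       frag_len_mean = 170, frag_len_sd = 25) {
  profile <- match.arg(profile)
  primary <- genome$primary
  spike <- genome$spike
  if (is.null(primary) || is.null(spike))
    stop("make_truth: genome must have primary and spike chrom_sizes")
  if (spike_ratio <= 0 || spike_ratio >= 1)
    stop("make_truth: spike_ratio must be in (0, 1)")
  if (background_rate <= 0 || spike_rate <= 0)
    stop("make_truth: rates must be positive")
  set.seed(seed)
  dom <- region_set(label = "planted_domains")
  dom_mult <- double()
  peaks <- data.frame(chrom = character(), start = double(), end = double(),
                      multiplier = double(), stringsAsFactors = FALSE)
  if (profile == "domain_mark") {
    if (is.null(domains)) {
      if (max(domain_width) >= min(unclass(primary)))
        stop("make_truth: domain width exceeds chromosome size")
      dom <- sample_disjoint_regions(primary, n_domains, domain_width,
                                     label = "planted_domains")
    } else {
      dom <- domains
    }
    dom_mult <- rep_len(domain_multiplier, nrow(dom))
    if (any(dom_mult < 1)) stop("make_truth: multipliers must be >= 1")
  } else if (profile == "turnover_peaky") {
    if (is.null(tss)) {
      if (peak_width >= min(unclass(primary)))
        stop("make_truth: peak width exceeds chromosome size")
      tss <- sample_positions(primary, n_peaks, margin = peak_width)
    }
    mult <- exp(runif(nrow(tss), 0, log(peak_multiplier)))
    peaks <- data.frame(chrom = tss$chrom,
                        start = pmax(tss$pos - peak_width / 2, 0),
                        end = tss$pos + peak_width / 2,
                        multiplier = mult, stringsAsFactors = FALSE)
    peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  structure(list(profile = profile, primary = primary, spike = spike,
                 background_rate = background_rate,
                 domains = dom, domain_multiplier = dom_mult,
                 peaks = peaks, spike_ratio = spike_ratio,
                 spike_rate = spike_rate,
                 frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
                 seed = seed),
            class = "truth_model")
}

#' @export
print.truth_model <- function(x, ...) {
  cat(sprintf("<truth_model '%s': %d domain(s), %d peak(s), spike ratio 1:%g>\n",
              x$profile, nrow(x$domains), nrow(x$peaks), 1 / x$spike_ratio))
  invisible(x)
}

# rejection-sample non-overlapping regions; seeded by the caller
sample_disjoint_regions <- function(sizes, n, width_range, label,
                                    max_tries = 10000L) {
  chroms <- names(sizes)
  lens <- unclass(sizes)
  acc <- empty_intervals()
  tries <- 0L
  while (nrow(acc) < n && tries < max_tries) {
    tries <- tries + 1L
    chrom <- sample(chroms, 1L, prob = lens)
    w <- round(runif(1L, width_range[1L], width_range[2L]))
    if (w >= lens[[chrom]]) next
    s <- floor(runif(1L, 0, lens[[chrom]] - w))
    sub <- acc[acc$chrom == chrom, , drop = FALSE]
    if (nrow(sub) == 0L || all(s + w <= sub$start | s >= sub$end)) {
      acc <- rbind(acc, data.frame(chrom = chrom, start = s, end = s + w,
                                   stringsAsFactors = FALSE))
    }
  }
  if (nrow(acc) < n)
    stop("make_truth: could not place ", n, " disjoint domains; ",
         "genome too small for the requested widths")
  region_set(acc$chrom, acc$start, acc$end, label = label)
}

#' Sample random genomic positions
#'
#' Draws `n` positions uniformly over a genome (chromosomes weighted by
#' length), at least `margin` bp from either end — e.g. synthetic TSS
#' coordinates. Uses the current RNG state; seed with `set.seed()`.
#'
#' @param sizes A [chrom_sizes()] object.
#' @param n Number of positions.
#' @param margin Minimum distance from chromosome ends (bp).
#' @return data.frame with columns chrom, pos, sorted by position.
#' @export
sample_positions <- function(sizes, n, margin = 0) {
  chroms <- sample(names(sizes), n, replace = TRUE, prob = unclass(sizes))
  pos <- floor(runif(n, margin, unclass(sizes)[chroms] - margin))
  out <- data.frame(chrom = chroms, pos = pos, stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

# piecewise-constant intensity segments implied by a truth model:
# background everywhere, multiplied inside planted domains/peaks
truth_intensity <- function(truth) {
  feats <- rbind(
    if (nrow(truth$domains))
      data.frame(chrom = truth$domains$chrom, start = truth$domains$start,
                 end = truth$domains$end,
                 multiplier = truth$domain_multiplier,
                 stringsAsFactors = FALSE),
    truth$peaks[, c("chrom", "start", "end", "multiplier"), drop = FALSE])
  segs <- lapply(names(truth$primary), function(chrom) {
    len <- unclass(truth$primary)[[chrom]]
    f <- feats[feats$chrom == chrom, , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    bounds <- sort(unique(c(0, len, f$start, f$end)))
    s <- bounds[-length(bounds)]
    e <- bounds[-1L]
    mult <- rep(1, length(s))
    if (nrow(f)) {
      idx <- findInterval(s, f$start)
      inside <- idx >= 1L & s < f$end[pmax(idx, 1L)]
      mult[inside] <- f$multiplier[idx[inside]]
    }
    data.frame(chrom = chrom, start = s, end = e,
               intensity = truth$background_rate * mult,
               genome = "primary", stringsAsFactors = FALSE)
  })
  spike_segs <- data.frame(chrom = names(truth$spike), start = 0,
                           end = as.double(unclass(truth$spike)),
                           intensity = truth$spike_rate * truth$spike_ratio,
                           genome = "spike", stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, segs), spike_segs)
  rownames(out) <- NULL
  out
}

#' Expected spike-in fragment fraction of a truth model
#' @param truth A `truth_model`.
#' @return Scalar in (0, 1): the probability a simulated fragment maps to
#'   the spike genome.
#' @export
spike_share <- function(truth) {
  segs <- truth_intensity(truth)
  w <- segs$intensity * (segs$end - segs$start)
  sum(w[segs$genome == "spike"]) / sum(w)
}

#' Simulate one CUT&RUN sample from a truth model
#'
#' Fragment start positions are drawn from the piecewise-constant
#' intensity implied by the truth model (background times planted
#' multipliers on the primary genome; uniform spike-in intensity at the
#' configured cell-ratio share). Fragment lengths follow a normal
#' distribution truncated at 50 bp; fragments are shifted to fit inside
#' their chromosome. All draws are seeded: the same seed reproduces the
#' sample byte-for-byte.
#'
#' @param truth A [make_truth()] model.
#' @param n_fragments Total fragments to draw (primary + spike).
#' @param seed Integer seed.
#' @param sample_id,target Labels for the returned [fragment_set()].
#' @return A [fragment_set()].
#' @export
simulate_sample <- function(truth, n_fragments, seed,
                            sample_id = paste0(truth$profile, "_s", seed),
                            target = truth$profile) {
  if (n_fragments <= 0) stop("simulate_sample: n_fragments must be positive")
  segs <- truth_intensity(truth)
  w <- segs$intensity * (segs$end - segs$start)
  set.seed(seed)
  idx <- sample.int(nrow(segs), n_fragments, replace = TRUE, prob = w)
  u <- runif(n_fragments)
  start <- floor(segs$start[idx] + u * (segs$end[idx] - segs$start[idx]))
  len <- rnorm_trunc(n_fragments, truth$frag_len_mean, truth$frag_len_sd,
                     lower = 50)
  sizes_all <- c(setNames(as.double(unclass(truth$primary)),
                          names(truth$primary)),
                 setNames(as.double(unclass(truth$spike)),
                          names(truth$spike)))
  chrom <- segs$chrom[idx]
  chrom_len <- sizes_all[chrom]
  end <- start + len
  over <- end > chrom_len
  start[over] <- pmax(chrom_len[over] - len[over], 0)
  end <- pmin(start + len, chrom_len)
  is_spike <- segs$genome[idx] == "spike"
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  fragment_set(sample_id, target,
               primary = df[!is_spike, , drop = FALSE],
               spike = df[is_spike, , drop = FALSE],
               primary_sizes = truth$primary, spike_sizes = truth$spike)
}

# normal truncated below at `lower`, via inverse-CDF (vectorized, seeded)
rnorm_trunc <- function(n, mean, sd, lower) {
  p0 <- stats::pnorm(lower, mean, sd)
  round(stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd))
}

#' Plant a three-class differential-domain design
#'
#' Builds the ground truth for a two-condition comparison: `n_per_class`
#' domains each of class `shared` (present in both conditions), `A_only`
#' and `B_only`. Domains are laid out on a jittered grid with `slot` bp
#' slots so no two planted domains come closer than `slot` minus the
#' maximum width, then assigned to classes at random. Returns the per-class
#' region sets, a combined class map, and ready-to-simulate truth models
#' for condition A, condition B and an IgG-like control.
#'
#' @param genome List with `primary` and `spike` [chrom_sizes()].
#' @param n_per_class Domains per class (default 250).
#' @param width Domain width range in bp (default 12-25 kb, comfortably
#'   above the dominant-segment thresholds).
#' @param slot Grid slot size in bp (default 50 kb).
#' @param multiplier Enrichment of planted domains over background.
#' @param spike_rate Spike-genome intensity per bp (default 50, emulating
#'   an antibody whose epitope is abundant on the spike chromatin while
#'   primary background is non-specific).
#' @param seed Integer seed.
#' @return List with `shared`, `a_only`, `b_only` (region sets), `classes`
#'   (data.frame chrom/start/end/class), and truth models `truth_a`,
#'   `truth_b`, `truth_igg`.
#' @export
plant_differential_domains <- function(genome, n_per_class = 250,
                                       width = c(12000, 25000), slot = 50000,
                                       multiplier = 20, spike_rate = 50,
                                       seed = 1) {
  primary <- genome$primary
  set.seed(seed)
  slots <- do.call(rbind, lapply(names(primary), function(chrom) {
    starts <- seq(0, unclass(primary)[[chrom]] - slot, by = slot)
    data.frame(chrom = chrom, slot_start = starts, stringsAsFactors = FALSE)
  }))
  n_total <- 3L * n_per_class
  if (nrow(slots) < n_total)
    stop("plant_differential_domains: genome too small for ", n_total,
         " domains at slot size ", slot)
  pick <- slots[sort(sample.int(nrow(slots), n_total)), , drop = FALSE]
  w <- round(runif(n_total, width[1L], width[2L]))
  jitter <- floor(runif(n_total, 0, slot - w))
  dom <- data.frame(chrom = pick$chrom, start = pick$slot_start + jitter,
                    stringsAsFactors = FALSE)
  dom$end <- dom$start + w
  dom$class <- sample(rep(c("shared", "A_only", "B_only"), n_per_class))
  dom <- dom[order(dom$chrom, dom$start), , drop = FALSE]
  rownames(dom) <- NULL
  pick_class <- function(cls) {
    d <- dom[dom$class %in% cls, , drop = FALSE]
    region_set(d$chrom, d$start, d$end, label = paste(cls, collapse = "+"))
  }
  shared <- pick_class("shared")
  a_only <- pick_class("A_only")
  b_only <- pick_class("B_only")
  truth_a <- make_truth("domain_mark", genome = genome, seed = seed,
                        domains = pick_class(c("shared", "A_only")),
                        domain_multiplier = multiplier,
                        spike_rate = spike_rate)
  truth_b <- make_truth("domain_mark", genome = genome, seed = seed,
                        domains = pick_class(c("shared", "B_only")),
                        domain_multiplier = multiplier,
                        spike_rate = spike_rate)
  truth_igg <- make_truth("flat_background", genome = genome, seed = seed,
                          spike_rate = spike_rate)
  list(shared = shared, a_only = a_only, b_only = b_only, classes = dom,
       truth_a = truth_a, truth_b = truth_b, truth_igg = truth_igg)
}

#' Serialize a truth model's ground truth
#'
#' Writes the planted domains as BED (with multipliers in column 4 when
#' present), the planted peaks as BED, and every model parameter as JSON,
#' so test harnesses can evaluate pipeline output against the truth.
#'
#' @param truth A `truth_model`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
truth_report <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dom_path <- file.path(dir, "truth_domains.bed")
  peak_path <- file.path(dir, "truth_peaks.bed")
  json_path <- file.path(dir, "truth_params.json")
  dom <- truth$domains
  if (nrow(dom)) {
    writeLines(sprintf("%s\t%d\t%d\t%.6g", dom$chrom, as.integer(dom$start),
                       as.integer(dom$end), truth$domain_multiplier),
               dom_path)
  } else writeLines(character(), dom_path)
  if (nrow(truth$peaks)) {
    writeLines(sprintf("%s\t%d\t%d\t%.6g", truth$peaks$chrom,
                       as.integer(truth$peaks$start),
                       as.integer(truth$peaks$end), truth$peaks$multiplier),
               peak_path)
  } else writeLines(character(), peak_path)
  obj <- list(profile = truth$profile,
              primary = as.list(unclass(truth$primary)),
              spike = as.list(unclass(truth$spike)),
              background_rate = truth$background_rate,
              domains = as.data.frame(truth$domains)[, c("chrom", "start", "end")],
              domain_multiplier = truth$domain_multiplier,
              peaks = truth$peaks,
              spike_ratio = truth$spike_ratio, spike_rate = truth$spike_rate,
              frag_len_mean = truth$frag_len_mean,
              frag_len_sd = truth$frag_len_sd, seed = truth$seed)
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(domains = dom_path, peaks = peak_path, params = json_path))
}

#' Rebuild a truth model from a serialized parameter JSON
#' @param path Path to `truth_params.json` written by [truth_report()].
#' @return A `truth_model` equal to the one serialized.
#' @export
read_truth_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dom <- if (length(obj$domains) && NROW(obj$domains))
    region_set(obj$domains$chrom, obj$domains$start, obj$domains$end,
               label = "planted_domains")
  else region_set(label = "planted_domains")
  peaks <- if (length(obj$peaks) && NROW(obj$peaks))
    as.data.frame(obj$peaks, stringsAsFactors = FALSE)
  else data.frame(chrom = character(), start = double(), end = double(),
                  multiplier = double(), stringsAsFactors = FALSE)
  structure(list(profile = obj$profile,
                 primary = chrom_sizes(unlist(obj$primary), "primary"),
                 spike = chrom_sizes(unlist(obj$spike), "spike"),
                 background_rate = obj$background_rate,
                 domains = dom,
                 domain_multiplier = as.double(obj$domain_multiplier),
                 peaks = peaks,
                 spike_ratio = obj$spike_ratio, spike_rate = obj$spike_rate,
                 frag_len_mean = obj$frag_len_mean,
                 frag_len_sd = obj$frag_len_sd, seed = obj$seed),
            class = "truth_model")
}
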