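# Independent brute-force oracles and small fixture builders used across
# the suite. Everything here is deliberately naive O(n * m) / per-bp code:
# it checks the package's interval arithmetic without sharing any of it.

# random region set on a single toy chromosome of length `len`
random_region_set <- function(n, len, label, min_w = 1, max_w = len %/% 4) {
  if (n == 0L) return(region_set(label = label))
  # sample disjoint intervals by picking 2n distinct breakpoints
  repeat {
    starts <- sort(sample.int(len, n))
    widths <- pmin(sample.int(max_w, n, replace = TRUE) + min_w - 1L,
                   len - starts)
    ends <- starts + widths
    ok <- widths > 0 & c(ends[-n] <= starts[-1L], TRUE)
    if (all(ok)) break
  }
  region_set(rep("toy", n), starts, ends, label = label)
}

# per-bp membership oracle: for each bp of a toy chromosome, which labeled
# sets cover it (matrix bp x labels)
bp_membership <- function(sets, len) {
  m <- sapply(names(sets), function(l) {
    v <- logical(len)
    df <- as.data.frame(sets[[l]])
    for (i in seq_len(nrow(df))) {
      if (df$start[i] < len)
        v[(df$start[i] + 1):min(df$end[i], len)] <- TRUE
    }
    v
  })
  matrix(m, nrow = len, dimnames = list(NULL, names(sets)))
}

# reconstruct per-bp membership from partitioned segments
bp_membership_from_parts <- function(parts, labels, len) {
  m <- matrix(FALSE, len, length(labels), dimnames = list(NULL, labels))
  df <- as.data.frame(parts)
  for (i in seq_len(nrow(df))) {
    who <- strsplit(df$membership[i], ",", fixed = TRUE)[[1L]]
    m[(df$start[i] + 1):min(df$end[i], len), who] <- TRUE
  }
  m
}

# O(n * m) fragment-in-region overlap counter
brute_overlap_counts <- function(regions, frags, min_overlap = 1) {
  r <- as.data.frame(regions)
  vapply(seq_len(nrow(r)), function(i) {
    ov <- pmin(r$end[i], frags$end) - pmax(r$start[i], frags$start)
    sum(frags$chrom == r$chrom[i] & ov >= min_overlap)
  }, 0)
}

# matrix of `k` well-separated Gaussian row clusters in `d` dimensions;
# fixed simplex-like centers so separation does not depend on the seed
planted_matrix <- function(n_per, k, d = 3, sep = 12, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- rbind(rep(0, d),
                   diag(sep, nrow = k - 1, ncol = d))
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(stats::rnorm(n_per * d, sd = sd), n_per, d) +
      matrix(centers[i, ], n_per, d, byrow = TRUE)))
  list(x = x, truth = rep(seq_len(k), each = n_per))
}

# temporary file helper
tmpfile <- function(ext = "") withr::local_tempfile(fileext = ext,
                                                    .local_envir = parent.frame())
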