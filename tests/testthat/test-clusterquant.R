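toy_frags <- function(df, id = "s") {
  fragment_set(id, "test", primary = df)
}

test_that("signal matrix counts fragment overlaps like a brute-force scan", {
  regions <- region_set("chr1", c(0, 200), c(100, 300))
  frags <- data.frame(chrom = "chr1", start = c(50, 200), end = c(150, 300))
  m <- signal_matrix(regions, list(s1 = toy_frags(frags)))
  expect_equal(unname(unclass(m)[, "s1"]), c(1, 1))
  # empty region list -> 0-row matrix
  m0 <- signal_matrix(region_set(), list(s1 = toy_frags(frags)))
  expect_equal(nrow(m0), 0L)
  # random toy data vs O(n*m) oracle
  for (seed in 1:10) {
    set.seed(seed)
    rs <- random_region_set(6, 2000, "r", max_w = 400)
    rs_chr1 <- region_set(rep("chr1", nrow(rs)), rs$start, rs$end)
    fr <- data.frame(chrom = "chr1",
                     start = s <- sample.int(1900, 80),
                     end = pmin(s + sample(20:200, 80, replace = TRUE), 2000))
    m <- signal_matrix(rs_chr1, list(x = toy_frags(fr)))
    expect_equal(unname(unclass(m)[, "x"]), brute_overlap_counts(rs_chr1, fr))
  }
})

test_that("spike scaling of the matrix multiplies each column by its factor", {
  regions <- region_set("chr1", 0, 1000)
  fr <- data.frame(chrom = "chr1", start = c(10, 20, 30), end = c(110, 120, 130))
  m <- signal_matrix(regions, list(a = toy_frags(fr), b = toy_frags(fr)),
                     scales = list(a = spike_scale_factor(20000),
                                   b = spike_scale_factor(10000)))
  expect_equal(unname(unclass(m)[1, ]), c(1.5, 3))
})

test_that("FPK scaling follows count x 1000/length x constant", {
  regions <- region_set("chr1", c(0, 5000), c(2000, 6000))
  fr <- data.frame(chrom = "chr1",
                   start = c(rep(100, 8), rep(5100, 2)),
                   end = c(rep(300, 8), rep(5300, 2)))
  m <- signal_matrix(regions, list(a = toy_frags(fr)))
  out <- fpk_scale(m, constants = list(a = 0.5))
  # 8 fragments in a 2,000 bp region, constant 0.5 -> 8 * 0.5 * 0.5 = 2
  expect_equal(unname(unclass(out)[, "a"]), c(2, 1))
  # constant 1, 1,000 bp region: FPK == raw count
  r2 <- region_set("chr1", 0, 1000)
  m2 <- signal_matrix(r2, list(a = toy_frags(fr[1:8, ])))
  expect_equal(unname(unclass(fpk_scale(m2, list(a = 1)))[, "a"]), 8)
  expect_error(fpk_scale(out, list(a = 1)), "already scaled")
  expect_error(fpk_scale(signal_matrix(regions, list(a = toy_frags(fr)),
                                       scales = list(a = spike_scale_factor(1))),
                         list(a = 1)), "already scaled")
})

test_that("under uniform coverage FPK is independent of region length", {
  truth <- make_truth("flat_background", seed = 2)
  fs <- simulate_sample(truth, 400000, seed = 3)
  set.seed(4)
  widths <- sample(seq(2000, 50000, by = 2000))
  starts <- cumsum(c(0, head(widths, -1) + 5000))
  rs <- region_set(rep("chr1", length(widths)), starts, starts + widths)
  m <- fpk_scale(signal_matrix(rs, list(s = fs)), list(s = 1))
  fit <- stats::lm(unclass(m)[, "s"] ~ widths)
  # slope indistinguishable from zero relative to the mean FPK level
  rel_slope <- abs(coef(fit)[["widths"]]) * mean(widths) / mean(unclass(m))
  expect_lt(rel_slope, 0.05)
})

test_that("k-means separates planted clouds and is seed-deterministic", {
  pm <- planted_matrix(50, 2, d = 2, sep = 10, seed = 11)
  a <- kmeans_cluster(pm$x, 2, seed = 1, transform = "none")
  expect_equal(length(unique(a$cluster[pm$truth == 1])), 1L)
  expect_equal(length(unique(a$cluster[pm$truth == 2])), 1L)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(a$cluster, pm$truth), 1.0)
  b <- kmeans_cluster(pm$x, 2, seed = 1, transform = "none")
  expect_identical(a$cluster, b$cluster)
  # degenerate k = number of rows: every row its own cluster, WSS 0
  x <- matrix(c(0, 5, 10, 20), 4, 1)
  d <- kmeans_cluster(x, 4, seed = 1, transform = "none")
  expect_equal(sort(d$cluster), 1:4)
  expect_equal(d$tot_withinss, 0)
  expect_error(kmeans_cluster(x, 5, seed = 1), "fewer rows")
})

test_that("the knee of the within-cluster curve picks the planted k", {
  pm <- planted_matrix(40, 4, d = 3, sep = 15, seed = 21)
  sel <- select_k_knee(pm$x, k_min = 2, k_max = 8, seed = 5,
                       transform = "none")
  expect_equal(sel$k, 4)
  expect_equal(sel$selected$k, 4)
  # within-cluster distance is non-increasing over the scan
  expect_true(all(diff(sel$withinss) <= 1e-8))
  # a single Gaussian blob has no knee beyond noise: k_min wins
  set.seed(31)
  blob <- matrix(rnorm(300), 100, 3)
  expect_equal(select_k_knee(blob, k_min = 2, k_max = 8, seed = 6,
                             transform = "none")$k, 2)
})

test_that("an obvious elbow in the curve maps to k = 2", {
  # curve over k = 1..5; maximum curvature at k = 2
  w <- c(100, 40, 39, 38.5, 38.2)
  ks <- 2:4
  d2 <- w[ks - 1] - 2 * w[ks] + w[ks + 1]
  expect_equal(ks[which.max(d2)], 2)
})

test_that("overlap percentages reproduce printed-count arithmetic", {
  expect_equal(overlap_summary(5259, 24733, 1)$percent, 21.3)
  expect_equal(overlap_summary(375, 1401, 1)$percent, 26.8)
  expect_equal(overlap_summary(1287, 24733, 2)$percent, 5.20)
  # interval route: one of two query intervals overlaps the reference
  q <- region_set("chr1", c(0, 200), c(100, 300))
  r <- region_set("chr1", 250, 260)
  expect_equal(overlap_fraction(q, r)$percent, 50.0)
  expect_error(overlap_fraction(region_set(), r), "empty query")
  # self-overlap is always 100%; growing the reference is monotone
  expect_equal(overlap_fraction(q, q)$percent, 100)
  r2 <- region_set("chr1", c(50, 250), c(60, 260))
  expect_gte(overlap_fraction(q, r2)$percent, overlap_fraction(q, r)$percent)
})

test_that("TSS matrices order rows by core signal and pad edges", {
  g <- chrom_sizes(c(chr1 = 100000), "primary")
  tss <- data.frame(chrom = "chr1", pos = c(10000, 50000, 90000))
  # fragment piles: 3 at TSS2, 1 at TSS1, 2 at TSS3
  fr <- data.frame(chrom = "chr1",
                   start = c(49900, 49950, 50000, 9950, 89900, 89950),
                   end = c(50100, 50150, 50200, 10150, 90100, 90150))
  m <- tss_matrix(toy_frags(fr), g, tss, window = 1000)
  expect_equal(attr(m, "order"), c(2, 3, 1))
  # a single centered fragment gives a symmetric profile
  fr1 <- data.frame(chrom = "chr1", start = 49900, end = 50100)
  m1 <- tss_matrix(toy_frags(fr1), g, tss[2, , drop = FALSE], window = 1000,
                   bin_width = 100)
  expect_equal(m1[1, ], rev(m1[1, ]))
  # explicit ordering scores win over signal
  m2 <- tss_matrix(toy_frags(fr), g, tss, window = 1000,
                   order_by = c(3, 1, 2))
  expect_equal(attr(m2, "order"), c(1, 3, 2))
  # TSS near the chromosome edge: padded with zeros, with a message
  tss_edge <- data.frame(chrom = "chr1", pos = 300)
  expect_message(me <- tss_matrix(toy_frags(fr), g, tss_edge, window = 1000),
                 "truncated")
  expect_equal(unname(me[1, 1:7]), rep(0, 7))
})

test_that("turnover profiles concentrate TSS signal; uniform ones do not", {
  g <- toy_genome()
  set.seed(12)
  tss <- sample_positions(g$primary, 200, margin = 2000)
  names(tss) <- c("chrom", "pos")
  peaky <- make_truth("turnover_peaky", seed = 12, tss = tss)
  unif <- make_truth("replication_coupled_uniform", seed = 12)
  decile_ratio <- function(truth) {
    fs <- simulate_sample(truth, 300000, seed = 13)
    m <- tss_matrix(fs, truth$primary, tss, window = 1000)
    rowmean <- rowMeans(m)
    n <- length(rowmean)
    top <- mean(rowmean[1:(n %/% 10)])
    bot <- mean(rowmean[(n - n %/% 10 + 1):n])
    top / bot
  }
  expect_gt(decile_ratio(peaky), 5)
  expect_lt(decile_ratio(unif), 1.5)
})

test_that("promoter/expression correlation behaves across regimes", {
  x <- c(3, 8, 1, 40, 12, 0, 7)
  expect_equal(tss_window_correlation(x, x), 1.0)
  set.seed(8)
  a <- rpois(1000, 20)
  b <- rpois(1000, 20)
  expect_lt(tss_window_correlation(a, b), 0.01)
  expect_error(tss_window_correlation(rep(2, 10), rpois(10, 5)),
               "zero-variance")
  # planted coupling with noise tuned to R^2 ~= 0.3 is recovered
  set.seed(9)
  n <- 2000
  z <- rnorm(n)
  # on the log2 scale: y = z + noise with var ratio giving R^2 = 0.3
  noise <- rnorm(n, sd = sqrt(var(z) * (1 - 0.3) / 0.3))
  counts_x <- pmax(2^(z + 4) - 1, 0)
  counts_y <- pmax(2^(z + noise + 4) - 1, 0)
  r2 <- tss_window_correlation(counts_x, counts_y)
  expect_equal(r2, 0.3, tolerance = 0.05 / 0.3)
})

test_that("cluster summaries match reference quantiles", {
  m <- matrix(c(1, 2, 3, 4, 5, 7, 7, 7, 7, 7), 5, 2,
              dimnames = list(NULL, c("a", "b")))
  m <- structure(m, regions = NULL, scaling = NULL)
  st <- cluster_region_stats(m, rep(1L, 5))
  a_row <- st[st$sample == "a", ]
  expect_equal(a_row$q1, 2)
  expect_equal(a_row$median, 3)
  expect_equal(a_row$q3, 4)
  b_row <- st[st$sample == "b", ]
  expect_equal(b_row$q3 - b_row$q1, 0)  # constant values: zero IQR
  # random data vs stats::quantile directly
  set.seed(14)
  x <- matrix(rgamma(300, 2), 100, 3, dimnames = list(NULL, c("p", "q", "r")))
  cl <- sample(1:2, 100, replace = TRUE)
  st2 <- cluster_region_stats(x, cl)
  for (i in seq_len(nrow(st2))) {
    v <- x[cl == st2$cluster[i], st2$sample[i]]
    expect_equal(unlist(st2[i, c("min", "q1", "median", "q3", "max")],
                        use.names = FALSE),
                 unname(quantile(v, c(0, .25, .5, .75, 1))))
  }
})
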