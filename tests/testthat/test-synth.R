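test_that("truth profiles have the promised structure and are seed-stable", {
  u <- make_truth("replication_coupled_uniform", seed = 3)
  expect_equal(nrow(u$domains), 0L)
  expect_equal(nrow(u$peaks), 0L)
  g <- toy_genome()
  set.seed(1)
  tss <- sample_positions(g$primary, 100, margin = 1000)
  pk <- make_truth("turnover_peaky", seed = 3, tss = tss)
  expect_equal(nrow(pk$peaks), 100L)
  expect_true(all(pk$peaks$multiplier >= 1))
  dm <- make_truth("domain_mark", seed = 3)
  expect_equal(nrow(dm$domains), 15L)
  # planted domains are a valid region set: sorted, disjoint
  d <- as.data.frame(dm$domains)
  same <- d$chrom[-1L] == d$chrom[-nrow(d)]
  expect_true(all(d$start[-1L][same] >= d$end[-nrow(d)][same]))
  expect_identical(make_truth("domain_mark", seed = 3)$domains, dm$domains)
  expect_error(make_truth("domain_mark", spike_ratio = 2), "spike_ratio")
  expect_error(make_truth("domain_mark",
                          genome = list(primary = chrom_sizes(c(c1 = 5e4), "primary"),
                                        spike = g$spike)),
               "exceeds chromosome")
})

test_that("same seed reproduces a sample byte-for-byte", {
  truth <- make_truth("domain_mark", seed = 4)
  a <- simulate_sample(truth, 5000, seed = 9)
  b <- simulate_sample(truth, 5000, seed = 9)
  expect_identical(a$primary, b$primary)
  expect_identical(a$spike, b$spike)
  c_ <- simulate_sample(truth, 5000, seed = 10)
  expect_false(identical(a$primary, c_$primary))
})

test_that("flat background is uniform across windows", {
  truth <- make_truth("flat_background", seed = 6)
  rejected <- 0L
  n_runs <- 40L
  for (s in seq_len(n_runs)) {
    fs <- simulate_sample(truth, 10000, seed = 1000 + s)
    # chr1 fragment starts across 20 equal windows
    x <- fs$primary$start[fs$primary$chrom == "chr1"]
    ct <- tabulate(findInterval(x, seq(0, 5e6, length.out = 21),
                                rightmost.closed = TRUE), 20)
    p <- stats::chisq.test(ct)$p.value
    if (p < 0.01) rejected <- rejected + 1L
  }
  expect_lte(rejected / n_runs, 0.05)
})

test_that("planted enrichment matches its closed-form fragment share", {
  # one domain covering 10% of the primary genome at multiplier 20:
  # expected primary share = 20*0.1 / (20*0.1 + 0.9)
  g <- toy_genome()
  dom <- region_set("chr1", 0, 1e6, label = "d")
  truth <- make_truth("domain_mark", genome = g, seed = 2, domains = dom,
                      domain_multiplier = 20)
  fs <- simulate_sample(truth, 1e5, seed = 3)
  inside <- fs$primary$chrom == "chr1" & fs$primary$start < 1e6
  expected <- 20 * 0.1 / (20 * 0.1 + 0.9)
  expect_equal(mean(inside), expected, tolerance = 0.03 / expected)
})

test_that("spike fragment fraction follows the configured share", {
  truth <- make_truth("flat_background", seed = 5)
  p <- spike_share(truth)
  n <- 2e5
  fs <- simulate_sample(truth, n, seed = 6)
  expect_equal(fs$spike_reads / n, p, tolerance = 4 * sqrt(p * (1 - p) / n) / p)
  # share rises with the spike cell ratio
  t2 <- make_truth("flat_background", seed = 5, spike_ratio = 1 / 5)
  expect_gt(spike_share(t2), p)
})

test_that("fragment lengths are nucleosome-sized and never below 50 bp", {
  truth <- make_truth("flat_background", seed = 7)
  fs <- simulate_sample(truth, 20000, seed = 8)
  len <- fs$primary$end - fs$primary$start
  expect_gte(min(len), 50)
  expect_equal(mean(len), 170, tolerance = 0.02)
  expect_equal(sd(len), 25, tolerance = 0.1)
})

test_that("empirical intensity converges to the truth intensity", {
  truth <- make_truth("domain_mark", seed = 9)
  fs <- simulate_sample(truth, 1e6, seed = 10)
  segs <- spikedomains:::truth_intensity(truth)
  segs <- segs[segs$genome == "primary", ]
  w <- segs$intensity * (segs$end - segs$start)
  expected_cdf <- cumsum(w) / sum(w)
  # empirical fraction of primary fragments per segment, in segment order
  counts <- double(nrow(segs))
  for (ch in unique(segs$chrom)) {
    sel <- segs$chrom == ch
    x <- fs$primary$start[fs$primary$chrom == ch]
    counts[sel] <- tabulate(findInterval(x, segs$start[sel]), sum(sel))
  }
  emp_cdf <- cumsum(counts) / sum(counts)
  expect_lt(max(abs(emp_cdf - expected_cdf)), 0.02)
})

test_that("replicate simulations call highly concordant merged domains", {
  truth <- make_truth("domain_mark", seed = 11, domain_multiplier = 20)
  igg <- make_truth("flat_background", seed = 11)
  # control depth matched to the signal's background density, as the
  # max-control-block threshold assumes
  ctl <- binned_coverage(simulate_sample(igg, 1.3e5, seed = 30), truth$primary, 1)
  call_one <- function(seed) {
    fs <- simulate_sample(truth, 5e5, seed = seed)
    call_domains(binned_coverage(fs, truth$primary, 1), control = ctl)
  }
  r1 <- call_one(31)
  r2 <- call_one(32)
  gr1 <- GenomicRanges::GRanges(r1$chrom, IRanges::IRanges(r1$start + 1, r1$end))
  gr2 <- GenomicRanges::GRanges(r2$chrom, IRanges::IRanges(r2$start + 1, r2$end))
  jac <- sum(IRanges::width(GenomicRanges::intersect(gr1, gr2))) /
    sum(IRanges::width(GenomicRanges::union(gr1, gr2)))
  expect_gt(jac, 0.8)
})

test_that("truth reports round-trip through BED + JSON", {
  dir <- withr::local_tempdir()
  truth <- make_truth("domain_mark", seed = 12)
  paths <- truth_report(truth, dir)
  back <- read_truth_report(paths$params)
  expect_equal(back$profile, truth$profile)
  expect_equal(as.data.frame(back$domains)[c("chrom", "start", "end")],
               as.data.frame(truth$domains)[c("chrom", "start", "end")])
  expect_equal(back$spike_ratio, truth$spike_ratio)
  expect_equal(unclass(back$primary), unclass(truth$primary),
               ignore_attr = TRUE)
  # domain BED is sorted/non-overlapping and matches the model
  bed <- read.table(paths$domains, sep = "\t")
  expect_equal(nrow(bed), nrow(truth$domains))
  expect_true(all(diff(order(bed$V1, bed$V2)) == 1))
  set.seed(1)
  tss <- sample_positions(toy_genome()$primary, 25, margin = 1000)
  pk <- make_truth("turnover_peaky", seed = 13, tss = tss)
  paths2 <- truth_report(pk, dir)
  expect_equal(nrow(read.table(paths2$peaks, sep = "\t")), 25L)
})
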