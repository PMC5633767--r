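test_that("bin medians match the sort-and-middle oracle", {
  # constant depth
  d <- data.frame(chrom = "A01", start = 0, end = 5000, depth = 20)
  tr <- bin_median(d)
  expect_true(all(tr$values == 20))
  expect_equal(length(tr$values), 5)

  # bin covering depths 1..4 in equal parts -> median 2.5
  d <- data.frame(chrom = "A01", start = c(0, 250, 500, 750),
                  end = c(250, 500, 750, 1000), depth = 1:4)
  expect_equal(bin_median(d)$values, 2.5)

  # random per-bp track vs brute-force oracle
  set.seed(77)
  pos <- 0:9999
  dep <- rpois(10000, 15)
  d <- data.frame(chrom = "A01", start = pos, end = pos + 1, depth = dep)
  tr <- bin_median(d, 1000)
  expect_equal(tr$values,
               oracle_bin_medians(data.frame(pos = pos, depth = dep), 1000, 10))

  # gap bins and a partial final bin
  d <- data.frame(chrom = "A01", start = c(0, 2500), end = c(1000, 2600),
                  depth = c(7, 9))
  tr <- bin_median(d, 1000)
  expect_equal(tr$values, c(7, NA, 9))
  expect_equal(tr$gap, c(FALSE, TRUE, FALSE))

  expect_error(bin_median(data.frame(chrom = "A", start = c(10, 0),
                                     end = c(20, 10), depth = 1)), "sorted")
})

test_that("chromosome stats use the population SD over non-gap bins", {
  expect_equal(chrom_stats(coverage_track("c", rep(20, 10))),
               list(chrom = "c", mean_cov = 20, sd_cov = 0, n_bins = 10L))
  st <- chrom_stats(coverage_track("c", c(10, 20, 30)))
  expect_equal(st$mean_cov, 20)
  expect_equal(st$sd_cov, sqrt(200 / 3))  # closed form, divisor n
  set.seed(1)
  v <- rnorm(500, 50, 9)
  v[sample(500, 20)] <- NA
  st <- chrom_stats(coverage_track("c", v))
  expect_equal(st$mean_cov, mean(v, na.rm = TRUE))
  expect_equal(st$sd_cov,
               sqrt(sum((v[!is.na(v)] - mean(v, na.rm = TRUE))^2) / sum(!is.na(v))))
  expect_error(chrom_stats(coverage_track("c", NA_real_)), "non-gap")

  # robust mode: median/MAD resists contamination by rearranged bins
  v <- c(rep(100, 90), rep(1000, 10))
  st <- chrom_stats(coverage_track("c", v), robust = TRUE)
  expect_equal(st$mean_cov, 100)
  expect_equal(st$sd_cov, 0)
})

test_that("segmentation handles flat, step and noise-only tracks", {
  expect_equal(nrow(segment_track(coverage_track("c", rep(20, 300)), seed = 1)), 1)

  # clean step: boundary exactly at bin 200, matching the exhaustive oracle
  x <- c(rep(20, 200), rep(40, 200))
  segs <- segment_track(coverage_track("c", x), seed = 1)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$bin_start, c(1L, 201L))
  expect_equal(oracle_changepoints(x, 1), 200L)

  # pure noise: a single segment in the clear majority of replicates
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    nrow(segment_track(coverage_track("c", rnorm(500, 20, 2)), alpha = 0.01,
                       seed = s)) == 1
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("segmentation is idempotent on piecewise-constant tracks", {
  x <- rep(c(12, 30, 18), times = c(120, 80, 150))
  s1 <- segment_track(coverage_track("c", x), seed = 1)
  # rebuild the noiseless track from the fitted segments and re-segment
  x2 <- rep(s1$mean_cov, s1$n_bins)
  s2 <- segment_track(coverage_track("c", x2), seed = 2)
  expect_equal(s1$bin_start, s2$bin_start)
  expect_equal(s1$mean_cov, s2$mean_cov)
})

test_that("gap bins break segments and are excluded from statistics", {
  x <- c(rep(10, 100), rep(NA, 60), rep(30, 100))
  segs <- segment_track(coverage_track("c", x), seed = 1)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$mean_cov, c(10, 30))
  expect_equal(segs$start, c(0, 160000))
  expect_warning(segment_track(coverage_track("c", rep(NA_real_, 10))), "gap")
})

test_that("merge rules follow the 50-kb / same-mean / gap conventions", {
  seg <- function(start, end, mean) data.frame(chrom = "c", start = start,
                                               end = end, mean_cov = mean,
                                               n_bins = (end - start) / 1000)
  # identical means, 10-kb gap -> merged
  m <- merge_filter_segments(rbind(seg(0, 60000, 30), seg(70000, 130000, 30)),
                             ref_mean = 30)
  expect_equal(nrow(m), 1)
  expect_equal(m$end, 130000)

  # identical means, 60-kb gap -> not merged
  m <- merge_filter_segments(rbind(seg(0, 60000, 30), seg(120000, 180000, 30)),
                             ref_mean = 30)
  expect_equal(nrow(m), 2)

  # short deviant segment between long normal ones -> removed from output
  m <- merge_filter_segments(rbind(seg(0, 100000, 30), seg(100000, 130000, 80),
                                   seg(130000, 230000, 30)), ref_mean = 30)
  expect_true(all(m$end - m$start >= 5e4))
  expect_true(all(abs(m$mean_cov - 30) < 80 - 30))

  # different means are never merged
  m <- merge_filter_segments(rbind(seg(0, 60000, 30), seg(60000, 120000, 60)),
                             ref_mean = 30)
  expect_equal(nrow(m), 2)
})

test_that("classification applies the +/- k SD rule around the chromosome mean", {
  st <- list(chrom = "c", mean_cov = 30, sd_cov = 5, n_bins = 100L)
  seg <- data.frame(chrom = "c", start = c(0, 1e5, 2e5), end = c(1e5, 2e5, 3e5),
                    mean_cov = c(30, 40, 22), n_bins = 100)
  cl <- classify_segments(seg, st)
  expect_equal(cl$class, c("normal", "duplication", "deletion"))
  # boundary values are not called (strict inequality)
  seg$mean_cov <- c(35, 25, 30)
  expect_equal(classify_segments(seg, st)$class, rep("normal", 3))
  # degenerate SD warns but still classifies
  st0 <- list(chrom = "c", mean_cov = 30, sd_cov = 0, n_bins = 10L)
  seg$mean_cov <- c(31, 29, 30)
  expect_warning(cl <- classify_segments(seg, st0), "degenerate")
  expect_equal(cl$class, c("duplication", "deletion", "normal"))
})

test_that("breakpoints match the exhaustive-search oracle on small tracks", {
  set.seed(101)
  for (rep in 1:25) {
    k <- sample(0:2, 1)
    n <- sample(40:100, 1)
    cuts <- integer(0)
    if (k > 0) {
      repeat {
        cuts <- sort(sample(5:(n - 5), k))
        if (k < 2 || diff(cuts) >= 5) break
      }
    }
    levels <- sample(seq(10, 100, by = 10), k + 1)
    x <- rep(levels, diff(c(0, cuts, n)))
    segs <- segment_track(coverage_track("c", x), seed = rep)
    expect_equal(as.integer(segs$bin_start[-1] - 1L),
                 oracle_changepoints(x, 2),
                 info = sprintf("rep %d", rep))
  }
})
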