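make_group_bins <- function(scored, cM, group = "A01") {
  list(group = group, chrom = group, bins = colnames(scored), cM = cM,
       scored = scored)
}

test_that("expected dosage matches the four-flank Haldane enumeration", {
  sc <- cbind(a = c(1L, 1L, 2L, 2L), b = c(1L, 2L, 1L, 2L))
  gb <- make_group_bins(sc, c(0, 20))
  # at an informative marker the dosage equals the marker origin
  D <- expected_genotype(gb, c(0, 20))
  expect_equal(D[, 1], c(0, 0, 1, 1))
  expect_equal(D[, 2], c(0, 1, 0, 1))
  # midpoint between discordant flanks: exactly 0.5 by symmetry
  D <- expected_genotype(gb, 10)
  expect_equal(D[2, 1], 0.5)
  expect_equal(D[3, 1], 0.5)
  # closed-form check of all four flank configurations
  r10 <- 0.5 * (1 - exp(-10 / 50)); r20 <- 0.5 * (1 - exp(-20 / 50))
  expect_equal(D[1, 1], r10 * r10 / (1 - r20))          # 1,1 flanks
  expect_equal(D[4, 1], (1 - r10)^2 / (1 - r20))        # 2,2 flanks
  # missing flank: one-sided Haldane probability
  sc_na <- cbind(a = c(1L, NA), b = c(NA, 2L))
  gb <- make_group_bins(sc_na, c(0, 20))
  D <- expected_genotype(gb, 5)
  expect_equal(D[1, 1], 0.5 * (1 - exp(-5 / 50)))
  expect_equal(D[2, 1], 1 - 0.5 * (1 - exp(-15 / 50)))
  # no informative flank at all: 0.5
  expect_equal(expected_genotype(make_group_bins(cbind(a = c(NA_integer_, NA_integer_)), 0), 0)[1, 1], 0.5)
})

test_that("a noise-free marker phenotype gives a perfect peak at the marker", {
  set.seed(3)
  sc <- matrix(sample(1:2, 100 * 21, replace = TRUE), 100, 21)
  # make an ordered chain: cumulative recombination along columns
  for (j in 2:21) {
    flip <- runif(100) < 0.1
    sc[, j] <- ifelse(flip, 3L - sc[, j - 1], sc[, j - 1])
  }
  colnames(sc) <- sprintf("b%02d", 1:21)
  gb <- make_group_bins(sc, (0:20) * 5)
  y <- as.numeric(sc[, 11] - 1)
  prof <- hexamap:::scan_group(gb, y, cofactors = NULL, step = 1)
  peak <- prof[which.max(prof$LOD), ]
  expect_equal(peak$cM, gb$cM[11])
  expect_equal(peak$R2, 1)
  expect_true(is.infinite(peak$LOD) || peak$LOD > 50)
})

test_that("constant phenotypes yield a zero profile with a warning", {
  sc <- cbind(a = rep(1:2, 10), b = rep(1:2, 10))
  gb <- make_group_bins(sc, c(0, 10))
  expect_warning(prof <- hexamap:::scan_group(gb, rep(1, 20)), "constant")
  expect_true(all(prof$LOD == 0))
})

test_that("QTL reporting applies threshold, support interval and peak splitting", {
  prof <- data.frame(
    group = "A01",
    cM = 0:100,
    LOD = c(seq(0, 4.9, length.out = 51), seq(4.8, 0, length.out = 50)),
    R2 = 0.1
  )
  expect_equal(nrow(report_qtl(prof, threshold = 5)), 0)  # 4.9 max: no QTL

  # two peaks separated by a deep valley and > min_distance: two QTL
  lod <- c(dnorm(0:100, 25, 4), dnorm(0:100, 75, 4)) * 0
  lod <- 8 * exp(-(0:100 - 25)^2 / 50) + 9 * exp(-(0:100 - 75)^2 / 50)
  prof <- data.frame(group = "A01", cM = 0:100, LOD = lod, R2 = 0.2)
  q <- report_qtl(prof, threshold = 5)
  expect_equal(nrow(q), 2)
  expect_equal(q$peak_cM, c(25, 75))
  expect_true(all(q$ci_lo <= q$peak_cM & q$ci_hi >= q$peak_cM))

  # shallow valley (< 2 LOD below the lower peak): merged into one QTL
  lod2 <- pmax(8 * exp(-(0:100 - 40)^2 / 800), 8.5 * exp(-(0:100 - 60)^2 / 800))
  prof <- data.frame(group = "A01", cM = 0:100, LOD = lod2, R2 = 0.2)
  expect_equal(nrow(report_qtl(prof, threshold = 5)), 1)

  # peak inside an HE block's cM span is annotated with the event id
  prof <- data.frame(group = "A01", cM = 0:100,
                     LOD = 10 * exp(-(0:100 - 50)^2 / 50), R2 = 0.3)
  ev <- data.frame(event_id = "RE1", class = "HE", group = "A01",
                   cm_start = 45, cm_end = 55, stringsAsFactors = FALSE)
  q <- report_qtl(prof, events = ev, threshold = 5)
  expect_equal(q$event_id, "RE1")
})

test_that("a simulated carrier QTL is detected, localized and colocalized", {
  sim <- toy_sim(81, n_events = 3, kind_mix = c(HE = 1),
                 size_range = c(8e5, 1.5e6),
                 qtl = list(event = 1, a = 2, sigma = 1))
  r <- classify_markers(sim$calls$parents, sim$calls$lines)
  map <- build_linkage_map(r$records, r$scored, sim$calls$anchors)
  segs <- do.call(rbind, lapply(sim$coverage$P2, segment_coverage, seed = 3))
  ev <- call_rearrangements(map, segs, sim$genome)
  prof <- scan_qtl(map, as.numeric(sim$phenotype))
  q <- report_qtl(prof, ev, map)
  expect_gte(nrow(q), 1)
  top <- q[which.max(q$LOD), ]
  expect_gt(top$LOD, 5)
  expect_gt(top$R2, 0.3)
  # the QTL colocalizes with the causal HE's called event
  causal <- sim$events[1, ]
  hit <- ev[!is.na(ev$lost_chrom) & ev$lost_chrom == causal$lost_chrom &
              abs(ev$lost_start - causal$lost_start) < 2e5, ]
  expect_equal(top$event_id, hit$event_id)
})

test_that("monotonicity: larger effects never reduce expected peak LOD", {
  sim <- toy_sim(91, n_pairs = 1, chrom_length = 1e7, n_events = 1,
                 kind_mix = c(HE = 1), size_range = c(8e5, 1e6))
  r <- classify_markers(sim$calls$parents, sim$calls$lines)
  map <- build_linkage_map(r$records, r$scored, sim$calls$anchors)
  peak <- sapply(c(0.5, 1, 2), function(a) {
    m <- sapply(1:5, function(s) {
      y <- simulate_phenotype(sim$pop, event = 1, a = a, sigma = 1, seed = 100 + s)
      max(scan_qtl(map, as.numeric(y), cim = FALSE)$LOD)
    })
    mean(m)
  })
  expect_true(all(diff(peak) > 0))
})
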