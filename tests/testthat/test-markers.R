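test_that("anchor filtering enforces overlap, identity, gaps and uniqueness", {
  anc <- data.frame(
    marker = c("m1", "m2", "m3", "m4", "m5"),
    chrom = "A01", pos = 1:5 * 1000,
    overlap_length = c(60, 49, 60, 60, 50),
    identity = c(96, 96, 94.9, 96, 95),
    has_gaps = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    n_hits = c(1L, 1L, 1L, 1L, 2L),
    stringsAsFactors = FALSE
  )
  kept <- filter_anchors(anc)
  expect_equal(kept$marker, "m1")  # only the clean unique hit survives
  expect_equal(filter_anchors(anc, require_unique = FALSE)$marker,
               c("m1", "m5"))
})

test_that("chi-square 1:1 test matches the closed form", {
  s <- segregation_test(82, 82)
  expect_equal(s$chi2, 0)
  expect_equal(s$p, 1)
  expect_true(s$pass)

  s <- segregation_test(100, 64)
  expect_equal(s$chi2, 36^2 / 164)
  expect_equal(round(s$chi2, 2), 7.9)
  expect_equal(s$p, pchisq(36^2 / 164, 1, lower.tail = FALSE))
  expect_lt(s$p, 0.005)
  expect_false(s$pass)

  expect_false(segregation_test(0, 164)$pass)
})

make_calls <- function(p1, p2, line_calls) {
  m <- matrix(line_calls, ncol = 1, dimnames = list(NULL, "M"))
  list(parents = matrix(c(p1, p2), 2, 1, dimnames = list(c("P1", "P2"), "M")),
       lines = m)
}

test_that("marker classes follow the simple/het/PA decision rules", {
  # simple: AA x BB parents, codominant 1:1 lines
  cc <- make_calls("AA", "BB", rep(c("AA", "BB"), each = 82))
  r <- classify_markers(cc$parents, cc$lines)
  expect_equal(r$records$class, "simple")
  expect_equal(r$records$count_p1, 82)
  expect_equal(r$records$count_p2, 82)
  expect_true(r$records$pass_1to1)
  expect_equal(r$records$name, "M")

  # het: AA x AB parents, AB scored as the hemi-SNP parent's allele
  cc <- make_calls("AA", "AB", c(rep("AA", 80), rep("AB", 78), rep("NC", 6)))
  r <- classify_markers(cc$parents, cc$lines)
  expect_equal(r$records$class, "het")
  expect_equal(r$records$suffix, "-het")
  expect_equal(r$records$count_p2, 78)  # AB -> P2
  expect_equal(sum(is.na(r$scored)), 6)

  # PA: null parent NC, NC scored as the null-allele parent
  cc <- make_calls("AA", "NC", c(rep("AA", 81), rep("NC", 79),
                                 rep("BB", 4)))  # 4 stray calls tolerated
  r <- classify_markers(cc$parents, cc$lines, max_violation = 0.05)
  expect_equal(r$records$class, "PA")
  expect_equal(r$records$suffix, "-PA")
  expect_equal(r$records$count_p1, 81)
  expect_equal(r$records$count_p2, 79)  # NC -> P2

  # monomorphic and rejected patterns
  cc <- make_calls("AA", "AA", rep("AA", 100))
  expect_equal(classify_markers(cc$parents, cc$lines)$records$class,
               "monomorphic")
  cc <- make_calls("NC", "NC", rep("AA", 100))
  r <- classify_markers(cc$parents, cc$lines)$records
  expect_equal(r$class, "rejected")
  expect_equal(r$reason, "parents_nc")
  cc <- make_calls("AA", "BB", rep("AB", 100))
  expect_equal(classify_markers(cc$parents, cc$lines)$records$class,
               "rejected")
})

test_that("class recovery is exact on noise-free simulated markers", {
  sim <- toy_sim(21, chrom_length = 5e6, n_events = 3,
                 size_range = c(5e5, 1e6), missing_rate = 0, error_rate = 0)
  r <- classify_markers(sim$calls$parents, sim$calls$lines)
  got <- r$records$class[match(sim$calls$truth$marker, r$records$marker)]
  expect_equal(mean(got == sim$calls$truth$class), 1)
})

test_that("scored vectors preserve the carrier indicator of rearranged haplotypes", {
  sim <- toy_sim(22, chrom_length = 5e6, n_events = 2,
                 kind_mix = c(HE = 1), size_range = c(8e5, 1.5e6),
                 missing_rate = 0, error_rate = 0)
  r <- classify_markers(sim$calls$parents, sim$calls$lines)
  tr <- sim$calls$truth
  for (e in seq_len(nrow(sim$events))) {
    for (cls in c("PA", "het")) {
      mks <- tr$marker[tr$event_id == sim$events$event_id[e] & tr$class == cls]
      for (mk in head(mks, 3)) {
        sc <- r$scored[, mk]
        expect_identical(unname(sc == 2), unname(sim$pop$carriers[, e]),
                         info = paste(cls, mk))
      }
    }
  }
})

test_that("cosegregation binning equals brute-force equality clustering", {
  v1 <- c(1L, 2L, 1L, 2L, NA)
  sc <- cbind(M1 = v1, M2 = v1, M3 = c(1L, 2L, 2L, 2L, NA), M4 = v1)
  anc <- data.frame(marker = colnames(sc), chrom = "A01", pos = 1:4 * 1e4)
  b <- bin_cosegregating(sc, anc)
  expect_equal(b$bin, c(1L, 1L, 2L, 1L))
  expect_equal(b$representative, c(TRUE, FALSE, TRUE, FALSE))

  set.seed(9)
  sc <- matrix(sample(c(1L, 2L, NA), 50 * 200, replace = TRUE,
                      prob = c(0.48, 0.48, 0.04)), 50, 200,
               dimnames = list(NULL, sprintf("m%03d", 1:200)))
  # duplicate some columns to create real bins
  sc[, 151:200] <- sc[, 1:50]
  anc <- data.frame(marker = colnames(sc), chrom = "A01", pos = 1:200 * 1e4)
  b <- bin_cosegregating(sc, anc)
  expect_equal(as.integer(factor(b$bin, levels = unique(b$bin))),
               as.integer(factor(oracle_equality_bins(sc),
                                 levels = unique(oracle_equality_bins(sc)))))
})

test_that("segregation-test calibration: type-I error close to alpha", {
  set.seed(123)
  c1 <- rbinom(2000, 164, 0.5)
  s <- segregation_test(c1, 164 - c1, alpha = 0.05)
  rate <- mean(!s$pass)
  # discrete null at n = 164 rejects at ~0.051
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000) + 0.002)
})
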