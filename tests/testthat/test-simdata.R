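test_that("genome models tile the A subgenome with homoeology blocks", {
  g <- simulate_genome(1, 1e7)
  expect_equal(nrow(g$chromosomes), 2)
  expect_equal(nrow(g$homoeology), 1)
  expect_equal(g$homoeology$end_a - g$homoeology$start_a, 1e7)

  g2 <- simulate_genome(2, 2e7, blocks_per_pair = 4)
  for (p in 1:2) {
    blk <- g2$homoeology[g2$homoeology$chrom_a == sprintf("A%02d", p), ]
    expect_equal(sum(blk$end_a - blk$start_a), 2e7)  # full tiling
    expect_true(all(blk$start_a[-1] == blk$end_a[-nrow(blk)]))
  }
  expect_identical(simulate_genome(2, 2e7), simulate_genome(2, 2e7))
  expect_error(simulate_genome(1, 5e3, bin_size = 1e4), "block size")
})

test_that("parent events are disjoint, HE images homoeologous, and seeded", {
  g <- simulate_genome(2, 2e7)
  expect_equal(nrow(simulate_parent_events(g, 0)), 0)

  ev1 <- simulate_parent_events(g, 1, kind_mix = c(HE = 1), size_range = c(1e6, 1e6),
                                seed = 3)
  img <- homoeologous_image(g, ev1$lost_chrom, ev1$lost_start, ev1$lost_end)
  expect_equal(img$chrom, ev1$gained_chrom)
  expect_equal(img$start, ev1$gained_start)
  expect_equal(img$end, ev1$gained_end)

  ev <- simulate_parent_events(g, 50, size_range = c(5e4, 5e4), seed = 7)
  iv <- rbind(
    data.frame(chrom = ev$lost_chrom, start = ev$lost_start, end = ev$lost_end),
    data.frame(chrom = ev$gained_chrom, start = ev$gained_start, end = ev$gained_end)
  )
  iv <- iv[!is.na(iv$chrom), ]
  expect_false(oracle_any_overlap(iv))
  expect_identical(simulate_parent_events(g, 10, seed = 5),
                   simulate_parent_events(g, 10, seed = 5))
})

test_that("DH meiosis gives 1:1 carrier segregation and seeded reproducibility", {
  g <- simulate_genome(1, 1e7)
  ev <- simulate_parent_events(g, 1, kind_mix = c(deletion = 1), seed = 1)

  pop0 <- simulate_dh_population(g, ev, n_lines = 20, crossovers_mean = 0, seed = 2)
  org <- parental_origin(pop0, "A01", c(1e5, 5e6, 9.9e6))
  expect_true(all(org == org[, 1]))  # whole chromosome from one parent

  pop <- simulate_dh_population(g, ev, n_lines = 10000, seed = 3)
  f <- mean(pop$carriers[, 1])
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(f - 0.5), 3 * se)

  expect_identical(simulate_dh_population(g, ev, 50, seed = 9),
                   simulate_dh_population(g, ev, 50, seed = 9))
})

test_that("array calls follow PA/het/simple semantics exactly without noise", {
  g <- simulate_genome(2, 1e7)
  ev <- simulate_parent_events(g, 3, kind_mix = c(HE = 1), size_range = c(1e6, 2e6),
                               seed = 4)
  pop <- simulate_dh_population(g, ev, n_lines = 80, seed = 5)
  calls <- simulate_array_calls(g, ev, pop, missing_rate = 0, error_rate = 0,
                                seed = 6)
  tr <- calls$truth
  for (e in seq_len(nrow(ev))) {
    pa <- tr$marker[tr$class == "PA" & tr$event_id == ev$event_id[e]]
    for (mk in pa)  # NC if-and-only-if carrier
      expect_identical(unname(calls$lines[, mk] == "NC"),
                       unname(pop$carriers[, e]))
    het <- tr$marker[tr$class == "het" & tr$event_id == ev$event_id[e]]
    for (mk in het)
      expect_identical(unname(calls$lines[, mk] == "AB"),
                       unname(pop$carriers[, e]))
  }
  # no events -> no PA or het truth labels
  calls0 <- simulate_array_calls(g, simulate_parent_events(g, 0),
                                 simulate_dh_population(g, NULL, 30, seed = 7),
                                 seed = 8)
  expect_true(all(calls0$truth$class == "simple"))
})

test_that("missingness rate outside events matches the nominal rate", {
  g <- simulate_genome(1, 1e7)
  pop <- simulate_dh_population(g, NULL, n_lines = 100, seed = 1)
  calls <- simulate_array_calls(g, simulate_parent_events(g, 0), pop,
                                marker_spacing = 1e4, missing_rate = 0.02,
                                error_rate = 0, seed = 2)
  ncalls <- length(calls$lines)
  frac <- mean(calls$lines == "NC")
  se <- sqrt(0.02 * 0.98 / ncalls)
  expect_lt(abs(frac - 0.02), 3 * se)
})

test_that("coverage scales with copy number and is Poisson in the dispersion limit", {
  g <- simulate_genome(1, 1e7, bin_size = 1000)
  ev <- data.frame(event_id = "EV1", kind = "duplication", carrier_parent = "P2",
                   lost_chrom = NA, lost_start = NA, lost_end = NA,
                   gained_chrom = "A01", gained_start = 0, gained_end = 5e6,
                   stringsAsFactors = FALSE)
  cov <- simulate_coverage(g, ev, carrier = "P2", mean_depth = 100,
                           dispersion = 50, seed = 3)
  v <- cov[["A01"]]$values
  ratio <- mean(v[1:5000]) / mean(v[5001:10000])
  expect_lt(abs(ratio - 1.5), 0.05)  # 10000 bins, LLN

  # homozygous deletion bins are exactly zero
  del <- data.frame(event_id = "EV1", kind = "deletion", carrier_parent = "P2",
                    lost_chrom = "A01", lost_start = 0, lost_end = 1e6,
                    gained_chrom = NA, gained_start = NA, gained_end = NA,
                    stringsAsFactors = FALSE)
  cov0 <- simulate_coverage(g, del, carrier = "P2", zygosity = "homozygous",
                            mean_depth = 100, seed = 4)
  expect_true(all(cov0[["A01"]]$values[1:1000] == 0))

  # Poisson limit: variance ~ mean
  covp <- simulate_coverage(g, NULL, mean_depth = 100, dispersion = Inf, seed = 5)
  v <- covp[["A01"]]$values
  expect_lt(abs(var(v) / mean(v) - 1), 0.1)
})

test_that("phenotypes follow the additive carrier model", {
  g <- simulate_genome(1, 1e7)
  ev <- simulate_parent_events(g, 1, kind_mix = c(HE = 1), seed = 1)
  pop <- simulate_dh_population(g, ev, n_lines = 200, seed = 2)

  y0 <- simulate_phenotype(pop, a = 3, sigma = 0, seed = 3)
  expect_equal(sort(unique(as.numeric(y0))), c(0, 3))
  expect_equal(attr(y0, "h2"), 1)

  y <- simulate_phenotype(pop, a = 0, sigma = 1, seed = 4)
  carr <- pop$carriers[, 1]
  dm <- mean(y[carr]) - mean(y[!carr])
  se <- sqrt(1 / sum(carr) + 1 / sum(!carr))
  expect_lt(abs(dm), 3 * se)

  expect_identical(simulate_phenotype(pop, seed = 5),
                   simulate_phenotype(pop, seed = 5))
  expect_error(simulate_phenotype(pop, sigma = -1), "sigma")
})

test_that("HE lost and gained intervals cosegregate perfectly", {
  g <- simulate_genome(2, 1e7)
  ev <- simulate_parent_events(g, 2, kind_mix = c(HE = 1), seed = 11)
  pop <- simulate_dh_population(g, ev, n_lines = 120, seed = 12)
  calls <- simulate_array_calls(g, ev, pop, missing_rate = 0, error_rate = 0,
                                seed = 13)
  tr <- calls$truth
  for (e in seq_len(nrow(ev))) {
    pa <- tr$marker[tr$class == "PA" & tr$event_id == ev$event_id[e]]
    het <- tr$marker[tr$class == "het" & tr$event_id == ev$event_id[e]]
    if (length(pa) && length(het)) {
      lost_carrier <- calls$lines[, pa[1]] == "NC"
      gain_carrier <- calls$lines[, het[1]] == "AB"
      expect_identical(lost_carrier, gain_carrier)
    }
  }
})
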