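# End-to-end recovery study shared by the HE-caller and QTL acceptance
# checks: a 164-line DH cross segregating for 3 homoeologous exchanges and
# 2 segmental deletions (0.5-1.5 Mb) carried by the synthetic parent P2,
# with an additive QTL (a = 2, sigma = 1, R2 ~ 0.5) on the first HE.
run_he_qtl_study <- function(seed) {
  s <- seed * 50L
  g <- simulate_genome(2, 2e7)
  ev <- simulate_parent_events(g, 5, kinds = c("HE", "HE", "HE",
                                               "deletion", "deletion"),
                               size_range = c(5e5, 1.5e6), seed = s + 1L)
  pop <- simulate_dh_population(g, ev, n_lines = 164, crossovers_mean = 2,
                                seed = s + 2L)
  calls <- simulate_array_calls(g, ev, pop, marker_spacing = 5e4,
                                missing_rate = 0.02, error_rate = 0.005,
                                seed = s + 3L)
  y <- simulate_phenotype(pop, event = 1, a = 2, sigma = 1, seed = s + 4L)
  segs <- do.call(rbind, c(
    lapply(simulate_coverage(g, ev, "P2", 200, 50, seed = s + 5L),
           segment_coverage, seed = s + 7L),
    lapply(simulate_coverage(g, ev, "P1", 200, 50, seed = s + 6L),
           segment_coverage, seed = s + 8L)
  ))
  mk <- classify_markers(calls$parents, calls$lines)
  map <- build_linkage_map(mk$records, mk$scored, calls$anchors)
  called <- call_rearrangements(map, segs, g)

  # per-truth-event recovery: class, tier, physical boundaries
  ev_ok <- vapply(seq_len(nrow(ev)), function(e) {
    want_class <- if (ev$kind[e] == "HE") "HE" else "deletion"
    hit <- called[called$class == want_class &
                    !is.na(called$lost_chrom) &
                    called$lost_chrom == ev$lost_chrom[e] &
                    abs(called$lost_start - ev$lost_start[e]) <= 1e5 &
                    abs(called$lost_end - ev$lost_end[e]) <= 1e5, ]
    if (nrow(hit) != 1 || hit$tier != "validated") return(FALSE)
    if (want_class == "HE") {
      if (hit$gained_chrom != ev$gained_chrom[e] ||
          abs(hit$gained_start - ev$gained_start[e]) > 1e5 ||
          abs(hit$gained_end - ev$gained_end[e]) > 1e5) return(FALSE)
    }
    TRUE
  }, logical(1))

  # QTL on the causal HE: genome scan, reporting, colocalization
  prof <- scan_qtl(map, as.numeric(y))
  q <- report_qtl(prof, called, map)
  qtl_ok <- FALSE
  peak_err <- NA_real_
  if (nrow(q)) {
    top <- q[which.max(q$LOD), ]
    causal_mk <- map$marker %in%
      calls$truth$marker[!is.na(calls$truth$event_id) &
                           calls$truth$event_id == "EV1"]
    if (any(causal_mk) && top$LOD > 5) {
      true_cm <- range(map$cM[causal_mk & map$group == top$group])
      if (all(is.finite(true_cm))) {
        peak_err <- max(0, true_cm[1] - top$peak_cM, top$peak_cM - true_cm[2])
        causal_called <- called$event_id[called$class == "HE" &
          !is.na(called$lost_chrom) & called$lost_chrom == ev$lost_chrom[1] &
          abs(called$lost_start - ev$lost_start[1]) <= 1e5]
        qtl_ok <- peak_err <= 5 && length(causal_called) == 1 &&
          identical(top$event_id, causal_called)
      }
    }
  }
  list(events_ok = all(ev_ok), n_events_ok = sum(ev_ok), qtl_ok = qtl_ok,
       peak_err = peak_err, map = map, phen = as.numeric(y))
}

.study_cache <- new.env(parent = emptyenv())
get_he_qtl_study <- function(n_seeds = 20) {
  key <- as.character(n_seeds)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- lapply(seq_len(n_seeds), run_he_qtl_study)
  .study_cache[[key]]
}
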