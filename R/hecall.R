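#' Find rearrangement-indicative marker blocks on a genetic map
#'
#' Scans each linkage group in map order for runs of markers pointing at a
#' rearrangement:
#' * **PA-run** — adjacent presence-absence markers (deleted segment);
#' * **het-run** — adjacent hemi-SNP markers anchored on the group's own
#'   chromosome (in-place duplication);
#' * **translocated-run** — adjacent polymorphic markers whose anchor
#'   chromosome differs from the group's chromosome (a duplicated fragment
#'   mapping to its homoeologous position).
#' Runs of three or more markers are validation-grade evidence; shorter runs
#' are retained but flagged (`tier_seed = "single-marker"`), since isolated
#' PA/het markers can still be useful rearrangement markers.
#'
#' @param map a [build_linkage_map()] result.
#' @param min_run minimum run length for full confidence (default 3).
#' @return data frame of blocks: block_id, group, class, chrom (anchor
#'   chromosome), start, end (bp footprint), cm_start, cm_end, run_length,
#'   members (comma-separated marker names), tier_seed.
#' @export
find_blocks <- function(map, min_run = 3) {
  out <- list()
  for (g in unique(map$group)) {
    mg <- map[map$group == g, ]
    bc <- ifelse(mg$anchor_chrom != mg$group_chrom, "translocated-run",
                 ifelse(mg$class == "PA", "PA-run",
                        ifelse(mg$class == "het", "het-run", NA_character_)))
    key <- paste(bc, mg$anchor_chrom)
    key[is.na(bc)] <- NA
    r <- rle(key)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (k in which(!is.na(r$values))) {
      i <- idx_start[k]:idx_end[k]
      out[[length(out) + 1L]] <- data.frame(
        group = g, class = bc[i[1]], chrom = mg$anchor_chrom[i[1]],
        start = min(mg$anchor_pos[i]), end = max(mg$anchor_pos[i]) + 1,
        cm_start = min(mg$cM[i]), cm_end = max(mg$cM[i]),
        run_length = length(i),
        members = paste(mg$name[i], collapse = ","),
        tier_seed = if (length(i) >= min_run) "run" else "single-marker",
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out))
    return(data.frame(block_id = character(), group = character(),
                      class = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      cm_start = numeric(), cm_end = numeric(),
                      run_length = integer(), members = character(),
                      tier_seed = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- cbind(block_id = sprintf("B%d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  res
}

interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  uni <- max(e1, e2) - min(s1, s2)
  if (uni <= 0) 0 else inter / uni
}

# Cluster evidence items (same side) by physical overlap on each chromosome.
cluster_items <- function(items) {
  if (!nrow(items)) return(items)
  items$cluster <- NA_integer_
  nxt <- 0L
  for (ch in unique(items$chrom)) {
    idx <- which(items$chrom == ch)
    idx <- idx[order(items$start[idx])]
    cur_end <- -Inf
    for (i in idx) {
      if (items$start[i] >= cur_end) nxt <- nxt + 1L
      items$cluster[i] <- nxt
      cur_end <- max(cur_end, items$end[i])
    }
  }
  items
}

summarise_cluster <- function(it) {
  cov <- it[it$source == "coverage", ]
  span <- if (nrow(cov)) c(min(cov$start), max(cov$end))
          else c(min(it$start), max(it$end))
  mk <- it[it$source == "marker", ]
  list(
    chrom = it$chrom[1], start = span[1], end = span[2],
    full_start = min(it$start), full_end = max(it$end),
    n_marker_blocks = nrow(mk), n_segments = nrow(cov),
    max_run = if (nrow(mk)) max(mk$run_length) else 0L,
    max_seg_len = if (nrow(cov)) max(cov$end - cov$start) else 0,
    group = if (nrow(mk)) mk$group[which.max(mk$run_length)] else NA_character_,
    cm_start = if (nrow(mk)) min(mk$cm_start) else NA_real_,
    cm_end = if (nrow(mk)) max(mk$cm_end) else NA_real_,
    evidence = paste(it$id, collapse = ";")
  )
}

#' Pair homoeologous deletion and duplication evidence into events
#'
#' The central inference: a deleted segment (PA-run and/or deletion coverage
#' segment) whose homoeologous image overlaps duplication evidence (het-run,
#' translocated-run and/or duplication segment) with interval Jaccard at
#' least `min_jaccard` is called a homoeologous exchange (HE); unpaired loss
#' evidence becomes a deletion event and unpaired gain evidence a
#' duplication event. Physical extents prefer coverage-segment boundaries
#' over marker footprints when both exist. Contradictory evidence (loss and
#' gain overlapping on the same chromosome) is surfaced via the `conflict`
#' flag, never silently resolved.
#'
#' @param blocks marker blocks from [find_blocks()].
#' @param segments classified coverage segments (rbind over chromosomes;
#'   needs chrom, start, end, mean_cov, class). May be NULL.
#' @param homoeology homoeology table (chrom_a, start_a, end_a, chrom_c,
#'   start_c, end_c) or a `genome_model`.
#' @param min_jaccard reciprocal-overlap threshold after projection through
#'   the homoeology table (default 0.25).
#' @return data frame of events: event_id, class, lost_chrom/lost_start/
#'   lost_end, gained_chrom/gained_start/gained_end, group, cm_start,
#'   cm_end, n_marker_blocks, n_segments, max_run, max_seg_len, evidence,
#'   conflict.
#' @export
pair_homoeologues <- function(blocks, segments = NULL, homoeology,
                              min_jaccard = 0.25) {
  hom <- if (inherits(homoeology, "genome_model")) homoeology$homoeology
         else homoeology
  item <- function(side, source, id, chrom, start, end, group = NA,
                   cm_start = NA, cm_end = NA, run_length = 0L) {
    data.frame(side = side, source = source, id = id, chrom = chrom,
               start = start, end = end, group = group,
               cm_start = cm_start, cm_end = cm_end,
               run_length = run_length, stringsAsFactors = FALSE)
  }
  items <- list()
  for (k in seq_len(nrow(blocks))) {
    b <- blocks[k, ]
    side <- if (b$class == "PA-run") "loss" else "gain"
    items[[length(items) + 1L]] <-
      item(side, "marker", b$block_id, b$chrom, b$start, b$end, b$group,
           b$cm_start, b$cm_end, b$run_length)
  }
  if (!is.null(segments) && nrow(segments)) {
    seg <- segments[segments$class %in% c("deletion", "duplication"), ,
                    drop = FALSE]
    for (k in seq_len(nrow(seg))) {
      s <- seg[k, ]
      items[[length(items) + 1L]] <-
        item(if (s$class == "deletion") "loss" else "gain", "coverage",
             sprintf("S:%s:%d-%d:%s", s$chrom, s$start, s$end, s$class),
             s$chrom, s$start, s$end)
    }
  }
  if (!length(items)) return(empty_events())
  items <- do.call(rbind, items)
  loss <- cluster_items(items[items$side == "loss", , drop = FALSE])
  gain <- cluster_items(items[items$side == "gain", , drop = FALSE])
  loss_cl <- lapply(split(loss, loss$cluster), summarise_cluster)
  gain_cl <- lapply(split(gain, gain$cluster), summarise_cluster)
  conflict_loss <- rep(FALSE, length(loss_cl))
  conflict_gain <- rep(FALSE, length(gain_cl))
  for (i in seq_along(loss_cl)) for (j in seq_along(gain_cl)) {
    l <- loss_cl[[i]]; g <- gain_cl[[j]]
    if (l$chrom == g$chrom &&
        interval_jaccard(l$full_start, l$full_end, g$full_start, g$full_end) >=
          min_jaccard) {
      conflict_loss[i] <- TRUE
      conflict_gain[j] <- TRUE
    }
  }
  used_gain <- rep(FALSE, length(gain_cl))
  events <- list()
  for (i in seq_along(loss_cl)) {
    l <- loss_cl[[i]]
    img <- homoeologous_image(hom, l$chrom, l$start, l$end)
    best_j <- 0L; best_jac <- 0
    for (j in seq_along(gain_cl)) {
      if (used_gain[j]) next
      g <- gain_cl[[j]]
      for (p in seq_len(nrow(img))) {
        if (img$chrom[p] != g$chrom) next
        jac <- interval_jaccard(img$start[p], img$end[p], g$start, g$end)
        if (jac > best_jac) { best_jac <- jac; best_j <- j }
      }
    }
    if (best_j > 0 && best_jac >= min_jaccard) {
      used_gain[best_j] <- TRUE
      g <- gain_cl[[best_j]]
      cms <- suppressWarnings(min(l$cm_start, g$cm_start, na.rm = TRUE))
      cme <- suppressWarnings(max(l$cm_end, g$cm_end, na.rm = TRUE))
      events[[length(events) + 1L]] <- data.frame(
        class = "HE", lost_chrom = l$chrom, lost_start = l$start,
        lost_end = l$end, gained_chrom = g$chrom, gained_start = g$start,
        gained_end = g$end,
        group = if (!is.na(l$group)) l$group else g$group,
        cm_start = if (is.finite(cms)) cms else NA_real_,
        cm_end = if (is.finite(cme)) cme else NA_real_,
        n_marker_blocks = l$n_marker_blocks + g$n_marker_blocks,
        n_segments = l$n_segments + g$n_segments,
        max_run = max(l$max_run, g$max_run),
        max_seg_len = max(l$max_seg_len, g$max_seg_len),
        evidence = paste(l$evidence, g$evidence, sep = ";"),
        conflict = conflict_loss[i] || conflict_gain[best_j],
        stringsAsFactors = FALSE
      )
    } else {
      events[[length(events) + 1L]] <- data.frame(
        class = "deletion", lost_chrom = l$chrom, lost_start = l$start,
        lost_end = l$end, gained_chrom = NA_character_,
        gained_start = NA_real_, gained_end = NA_real_,
        group = l$group, cm_start = l$cm_start, cm_end = l$cm_end,
        n_marker_blocks = l$n_marker_blocks, n_segments = l$n_segments,
        max_run = l$max_run, max_seg_len = l$max_seg_len,
        evidence = l$evidence, conflict = conflict_loss[i],
        stringsAsFactors = FALSE
      )
    }
  }
  for (j in which(!used_gain)) {
    g <- gain_cl[[j]]
    events[[length(events) + 1L]] <- data.frame(
      class = "duplication", lost_chrom = NA_character_,
      lost_start = NA_real_, lost_end = NA_real_,
      gained_chrom = g$chrom, gained_start = g$start, gained_end = g$end,
      group = g$group, cm_start = g$cm_start, cm_end = g$cm_end,
      n_marker_blocks = g$n_marker_blocks, n_segments = g$n_segments,
      max_run = g$max_run, max_seg_len = g$max_seg_len,
      evidence = g$evidence, conflict = conflict_gain[j],
      stringsAsFactors = FALSE
    )
  }
  ev <- do.call(rbind, events)
  ev <- ev[order(match(ev$class, c("HE", "deletion", "duplication"))), ]
  cbind(event_id = sprintf("RE%d", seq_len(nrow(ev))), ev,
        stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(event_id = character(), class = character(),
             lost_chrom = character(), lost_start = numeric(),
             lost_end = numeric(), gained_chrom = character(),
             gained_start = numeric(), gained_end = numeric(),
             group = character(), cm_start = numeric(), cm_end = numeric(),
             n_marker_blocks = integer(), n_segments = integer(),
             max_run = numeric(), max_seg_len = numeric(),
             evidence = character(), conflict = logical(),
             tier = character(), stringsAsFactors = FALSE)
}

#' Assign confidence tiers to called events
#'
#' `validated`: supported by at least one marker block *and* one coverage
#' segment (genetic mapping confirmed by read densities). `putative`:
#' a single evidence kind, but a marker run of at least `min_run` or a
#' segment of at least `min_seg_length`. `single-marker`: anything weaker.
#'
#' @param events events from [pair_homoeologues()].
#' @param min_run,min_seg_length thresholds (defaults 3 and 50 kb).
#' @return `events` with a `tier` column.
#' @export
reconcile_evidence <- function(events, min_run = 3, min_seg_length = 5e4) {
  if (!nrow(events)) { events$tier <- character(0); return(events) }
  events$tier <- ifelse(
    events$n_marker_blocks >= 1 & events$n_segments >= 1, "validated",
    ifelse(events$max_run >= min_run | events$max_seg_len >= min_seg_length,
           "putative", "single-marker"))
  events
}

#' Call rearrangement events from a map and coverage segments
#'
#' Convenience wrapper: [find_blocks()], [pair_homoeologues()],
#' [reconcile_evidence()]. Deterministic given its inputs.
#'
#' @param map a [build_linkage_map()] result.
#' @param segments classified coverage segments (rbind over chromosomes).
#' @param homoeology homoeology table or `genome_model`.
#' @param min_run,min_jaccard,min_seg_length see the component functions.
#' @return tiered event data frame.
#' @export
call_rearrangements <- function(map, segments, homoeology, min_run = 3,
                                min_jaccard = 0.25, min_seg_length = 5e4) {
  blocks <- find_blocks(map, min_run)
  ev <- pair_homoeologues(blocks, segments, homoeology, min_jaccard)
  reconcile_evidence(ev, min_run, min_seg_length)
}
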