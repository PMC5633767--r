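#' Pairwise recombination fractions between scored markers
#'
#' DH estimator: `discordant / informative` over lines where both
#' markers are scored, truncated at 0.5. Pairs with fewer informative lines
#' than `min_informative` are flagged uninformative (NA).
#'
#' @param scored n x m matrix of parental-origin scores (1/2/NA).
#' @param min_informative minimum jointly scored lines (default 20).
#' @return list with `r` (m x m symmetric matrix, diagonal 0) and `n`
#'   (informative-line counts).
#' @export
pairwise_rf <- function(scored, min_informative = 20) {
  A <- (scored == 1L); A[is.na(A)] <- FALSE
  B <- (scored == 2L); B[is.na(B)] <- FALSE
  storage.mode(A) <- "double"; storage.mode(B) <- "double"
  disc <- crossprod(A, B)
  disc <- disc + t(disc)
  ninf <- crossprod(A + B)
  r <- ifelse(ninf > 0, pmin(disc / ninf, 0.5), NA_real_)
  r[ninf < min_informative] <- NA_real_
  diag(r) <- 0
  list(r = r, n = ninf)
}

#' Group markers into linkage groups
#'
#' Linkage groups are the connected components of the graph whose edges join
#' marker pairs with recombination fraction below the cut-off (default 0.2,
#' the standard DH grouping threshold); uninformative pairs contribute no
#' edge.
#'
#' @param rf result of [pairwise_rf()].
#' @param cutoff recombination-fraction cut-off (default 0.2).
#' @return integer vector of group memberships (1-based, ordered by group
#'   size, largest first).
#' @export
group_markers <- function(rf, cutoff = 0.2) {
  r <- rf$r
  m <- nrow(r)
  adj <- !is.na(r) & r < cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  as.integer(factor(comp, levels = names(sort(sizes, decreasing = TRUE))))
}

order_exhaustive <- function(d) {
  k <- nrow(d)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(k))) {
    if (p[1] > p[k]) next  # each path once (reversal-symmetric)
    cost <- path_cost(d, p)
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  best
}

#' Order markers within a linkage group
#'
#' Minimises the sum of adjacent recombination fractions (a
#' travelling-salesman-path objective) by greedy nearest-neighbour seriation
#' refined with 2-opt; groups of up to 8 bins are solved exhaustively, so
#' small orders are globally optimal. The returned order is one of the two
#' score-equivalent orientations; orient with [build_linkage_map()].
#'
#' @param rf result of [pairwise_rf()] (or a submatrix list) for the bins.
#' @param members indices of the group's bins within `rf$r`.
#' @return `members` permuted into map order.
#' @export
order_group <- function(rf, members = seq_len(nrow(rf$r))) {
  d <- rf$r[members, members, drop = FALSE]
  d[is.na(d)] <- 0.5
  k <- length(members)
  if (k <= 2) return(members)
  if (k <= 8) return(members[order_exhaustive(d)])
  cand_orders <- list()
  # classical MDS on Haldane distances: the first principal coordinate gives
  # a globally coherent seed order that 2-opt then polishes locally
  dm <- -50 * log(1 - 2 * pmin(d, 0.49))
  mds <- try(stats::cmdscale(dm, k = 1), silent = TRUE)
  if (!inherits(mds, "try-error")) cand_orders$mds <- order(mds[, 1])
  # greedy nearest-neighbour from several starts
  for (s in unique(c(which.min(rowSums(d)), which.max(rowSums(d)), 1L, k))) {
    ord <- integer(k); used <- logical(k)
    ord[1] <- s; used[s] <- TRUE
    for (i in 2:k) {
      cand <- which(!used)
      nxt <- cand[which.min(d[ord[i - 1], cand])]
      ord[i] <- nxt; used[nxt] <- TRUE
    }
    cand_orders[[length(cand_orders) + 1L]] <- ord
  }
  best <- NULL; best_cost <- Inf
  for (ord in cand_orders) {
    # alternate 2-opt (reversals) and or-opt (relocations) to convergence
    repeat {
      c0 <- path_cost(d, ord)
      ord <- two_opt_path(d, ord, 200L)
      ord <- or_opt_path(d, ord, 50L)
      if (path_cost(d, ord) >= c0 - 1e-12) break
    }
    cost <- path_cost(d, ord)
    if (cost < best_cost) { best_cost <- cost; best <- ord }
  }
  members[best]
}

#' Haldane map distances along an ordered group
#'
#' Cumulative centiMorgan positions from adjacent recombination fractions
#' via the Haldane mapping function `d = -50 ln(1 - 2r)` (no crossover
#' interference, matching the Poisson meiosis model).
#'
#' @param r_adjacent recombination fractions between consecutive bins.
#' @return cumulative cM positions (first bin at 0).
#' @export
map_distances <- function(r_adjacent) {
  if (any(r_adjacent >= 0.5, na.rm = TRUE))
    stop_config("adjacent recombination fraction >= 0.5: split the group")
  r_adjacent[is.na(r_adjacent)] <- 0
  c(0, cumsum(-50 * log(1 - 2 * r_adjacent)))
}

# Mask apparent tight double crossovers: a non-missing bin score that
# differs from both flanking non-missing scores of the same line (which
# agree) is set to NA. Two genuine crossovers within one bin interval are
# vanishingly rare; genotyping errors are not.
mask_singletons <- function(sc) {
  for (i in seq_len(nrow(sc))) {
    obs <- which(!is.na(sc[i, ]))
    if (length(obs) < 3) next
    v <- sc[i, obs]
    k <- length(v)
    bad <- v[-c(1, k)] != v[-c(k - 1, k)] & v[-c(1, k)] != v[-c(1, 2)] &
      v[-c(k - 1, k)] == v[-c(1, 2)]
    if (any(bad)) sc[i, obs[-c(1, k)][bad]] <- NA_integer_
  }
  sc
}

# Recombination fraction between consecutive columns of a scored matrix.
adjacent_rf <- function(sc) {
  k <- ncol(sc)
  if (k < 2) return(numeric(0))
  a <- sc[, -k, drop = FALSE]
  b <- sc[, -1, drop = FALSE]
  both <- !is.na(a) & !is.na(b)
  disc <- colSums(both & a != b)
  n <- colSums(both)
  ifelse(n > 0, pmin(disc / n, 0.5), 0.49)
}

#' Build a DH linkage map
#'
#' End-to-end map construction: markers passing the anchor filter and the
#' 1:1 segregation test are binned ([bin_cosegregating()]), pairwise
#' recombination fractions are estimated, bins are grouped at the rf
#' cut-off, ordered by seriation and placed on a Haldane cM scale. Groups
#' are named after the majority anchor chromosome of their markers (ties:
#' smallest anchor position; several groups on one chromosome get `_1`,
#' `_2`, ... by anchor position), and each group is oriented so that cM
#' increases with the majority chromosome's physical position.
#'
#' @param records,scored output of [classify_markers()].
#' @param anchors anchor table (already quality-filtered or not; pass
#'   through [filter_anchors()] first if needed).
#' @param cutoff rf grouping cut-off (default 0.2).
#' @param min_informative minimum jointly scored lines for rf (default 20).
#' @param min_group_size groups with fewer bins are dropped from the map
#'   (default 2).
#' @param distortion_alpha segregation p-value below which a marker is
#'   excluded from mapping (default 0.001). Markers are *reported* against
#'   1:1 at the conventional alpha = 0.05 ([classify_markers()]), but
#'   admission to the map uses this stricter level: pure sampling drift
#'   pushes whole chromosomal regions past a marginal 5% test in a 164-line
#'   DH population, and discarding them fragments linkage groups, so only
#'   strongly distorted markers are excluded (the usual practice in map
#'   construction).
#' @param clean_singletons mask apparent tight double crossovers before
#'   computing map distances (default TRUE). A single bin whose parental
#'   origin differs from both flanking bins of a line would require two
#'   crossovers within one bin interval - overwhelmingly a genotyping
#'   error, whose retention inflates Haldane map length; the call is set to
#'   missing, the standard DH map curation step.
#' @return object of class `linkage_map`: a data frame with one row per
#'   mapped marker (group, group_chrom, marker, name, class, bin, cM,
#'   anchor_chrom, anchor_pos), plus attribute `bins` (per-bin scored
#'   matrix, lines x bins, with bin cM and group).
#' @export
build_linkage_map <- function(records, scored, anchors, cutoff = 0.2,
                              min_informative = 20, min_group_size = 2,
                              distortion_alpha = 0.001,
                              clean_singletons = TRUE) {
  keep <- records$class %in% c("simple", "het", "PA") &
    !is.na(records$p) & records$p >= distortion_alpha &
    (records$count_p1 + records$count_p2) >= min_informative &
    records$marker %in% anchors$marker
  if (!any(keep)) stop_config("no mappable markers")
  rec <- records[keep, ]
  sc <- scored[, rec$marker, drop = FALSE]
  anc <- anchors[match(rec$marker, anchors$marker), ]
  bins <- bin_cosegregating(sc, anc)
  reps <- bins$marker[bins$representative]
  reps <- reps[order(bins$bin[bins$representative])]
  bsc <- sc[, reps, drop = FALSE]
  rf <- pairwise_rf(bsc, min_informative)
  grp <- group_markers(rf, cutoff)
  rows <- list()
  bin_meta <- list()
  for (g in sort(unique(grp))) {
    members <- which(grp == g)
    if (length(members) < min_group_size) next
    ord <- order_group(rf, members)
    osc <- bsc[, ord, drop = FALSE]
    if (clean_singletons && ncol(osc) >= 3) osc <- mask_singletons(osc)
    radj <- adjacent_rf(osc)
    cm <- map_distances(pmin(radj, 0.49))
    bin_markers <- bins$bin %in% bins$bin[match(reps[ord], bins$marker)]
    mk <- rec$marker[bin_markers]
    anc_mk <- anc[match(mk, rec$marker), ]
    chrom_tab <- sort(table(anc_mk$chrom), decreasing = TRUE)
    top <- names(chrom_tab)[chrom_tab == max(chrom_tab)]
    gchrom <- if (length(top) == 1) top else
      top[which.min(vapply(top, function(cc)
        min(anc_mk$pos[anc_mk$chrom == cc]), numeric(1)))]
    # orient by majority-chromosome anchors
    bin_of <- bins$bin[match(mk, bins$marker)]
    bin_order <- match(bin_of, bins$bin[match(reps[ord], bins$marker)])
    onchrom <- anc_mk$chrom == gchrom
    if (sum(onchrom) >= 2 &&
        cor(bin_order[onchrom], anc_mk$pos[onchrom],
            method = "spearman") < 0) {
      ord <- rev(ord)
      osc <- osc[, rev(seq_len(ncol(osc))), drop = FALSE]
      cm <- max(cm) - rev(cm)
      bin_order <- length(ord) + 1L - bin_order
    }
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, group_chrom = gchrom,
      marker = mk, name = rec$name[match(mk, rec$marker)],
      class = rec$class[match(mk, rec$marker)],
      bin = bin_order, cM = cm[bin_order],
      anchor_chrom = anc_mk$chrom, anchor_pos = anc_mk$pos,
      stringsAsFactors = FALSE
    )
    bin_meta[[length(bin_meta) + 1L]] <- list(
      group = g, chrom = gchrom, bins = reps[ord], cM = cm,
      scored = osc
    )
  }
  map <- do.call(rbind, rows)
  # rename groups by chromosome
  nm <- vapply(bin_meta, function(b) b$chrom, character(1))
  pos0 <- vapply(seq_along(bin_meta), function(i) {
    mkg <- map$anchor_pos[map$group == bin_meta[[i]]$group &
                            map$anchor_chrom == nm[i]]
    if (length(mkg)) min(mkg) else Inf
  }, numeric(1))
  label <- nm
  for (cc in unique(nm)) {
    idx <- which(nm == cc)
    if (length(idx) > 1) {
      idx <- idx[order(pos0[idx])]
      label[idx] <- paste0(cc, "_", seq_along(idx))
    }
  }
  old_group <- vapply(bin_meta, function(b) b$group, numeric(1))
  map$group <- label[match(map$group, old_group)]
  for (i in seq_along(bin_meta)) bin_meta[[i]]$group <- label[i]
  names(bin_meta) <- label
  map <- map[order(match(map$group, label), map$cM, map$class,
                   map$anchor_chrom, map$anchor_pos), ]
  rownames(map) <- NULL
  structure(map, bins = bin_meta, class = c("linkage_map", "data.frame"))
}

#' @export
print.linkage_map <- function(x, ...) {
  b <- attr(x, "bins")
  cat(sprintf("linkage_map: %d markers in %d groups\n", nrow(x), length(b)))
  for (g in b)
    cat(sprintf("  %s: %d bins, %.1f cM\n", g$group, length(g$bins), max(g$cM)))
  invisible(x)
}
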