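#' Coverage track constructor
#'
#' A coverage track is one chromosome's ordered per-bin median read depth.
#' Bins are contiguous 0-based half-open intervals of `bin_size` bp starting
#' at 0; bins with no aligned data are gap bins (value NA).
#'
#' @param chrom chromosome name.
#' @param values per-bin depth values (NA = gap bin); must be >= 0.
#' @param bin_size bin width in bp (default 1000).
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(chrom, values, bin_size = 1000) {
  values <- as.numeric(values)
  if (any(values < 0, na.rm = TRUE)) stop_config("depth values must be >= 0")
  structure(list(chrom = chrom, values = values, bin_size = bin_size,
                 gap = is.na(values)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track %s: %d bins of %d bp (%d gap), mean %.1f\n",
              x$chrom, length(x$values), x$bin_size, sum(x$gap),
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

weighted_median <- function(v, w) {
  o <- order(v)
  v <- v[o]; w <- w[o]
  cw <- cumsum(w)
  half <- sum(w) / 2
  k <- which(cw >= half)[1]
  # even split exactly at a value boundary: average the two middle values
  if (abs(cw[k] - half) < 1e-9 && k < length(v)) (v[k] + v[k + 1]) / 2 else v[k]
}

#' Median coverage over fixed-size bins
#'
#' Collapses a base-pair-resolution (or finer-bin) depth track to the median
#' depth of each `bin_size` window, the classic "median coverage over
#' 1000-bp blocks" reduction. Positions with no data make gap bins; a final
#' partial bin keeps its own median.
#'
#' @param depth data frame with columns chrom, start, end, depth (bedGraph
#'   semantics: 0-based half-open, sorted, non-overlapping) for a single
#'   chromosome, e.g. one element of [read_bedgraph()].
#' @param bin_size bin width in bp (default 1000).
#' @param chrom_length optional chromosome length; defaults to the last
#'   covered position.
#' @return a [coverage_track()].
#' @export
bin_median <- function(depth, bin_size = 1000, chrom_length = NULL) {
  if (!nrow(depth)) stop_config("empty depth track")
  if (length(unique(depth$chrom)) != 1)
    stop_config("bin_median() expects a single chromosome")
  if (any(depth$depth < 0)) stop_config("negative depth values")
  if (is.unsorted(depth$start)) stop_config("depth intervals must be sorted")
  if (any(depth$start[-1] < depth$end[-nrow(depth)]))
    stop_config("depth intervals must not overlap")
  L <- chrom_length %||% max(depth$end)
  nbins <- ceiling(L / bin_size)
  # split intervals at bin boundaries, then weighted median per bin
  first_bin <- floor(depth$start / bin_size)
  last_bin <- floor((depth$end - 1) / bin_size)
  nspan <- last_bin - first_bin + 1L
  row <- rep(seq_len(nrow(depth)), nspan)
  bin <- first_bin[row] + sequence(nspan) - 1L
  lo <- pmax(depth$start[row], bin * bin_size)
  hi <- pmin(depth$end[row], (bin + 1) * bin_size)
  vals <- rep(NA_real_, nbins)
  pieces <- split(data.frame(v = depth$depth[row], w = hi - lo), bin)
  med <- vapply(pieces, function(p) weighted_median(p$v, p$w), numeric(1))
  vals[as.integer(names(pieces)) + 1L] <- med
  coverage_track(depth$chrom[1], vals, bin_size)
}

#' Per-chromosome coverage mean and standard deviation
#'
#' Arithmetic mean and population SD (divisor n) over the non-gap bins of a
#' track; these are the classification reference for the +/- 1 SD rule.
#' `robust = TRUE` substitutes median and scaled MAD, which resists the
#' bias of the mean/SD normalisation on heavily rearranged chromosomes; it
#' is off by default for fidelity to the standard protocol.
#'
#' @param track a [coverage_track()].
#' @param robust use median/MAD instead of mean/SD (default FALSE).
#' @return list with chrom, mean_cov, sd_cov, n_bins.
#' @export
chrom_stats <- function(track, robust = FALSE) {
  v <- track$values[!track$gap]
  if (!length(v)) stop_config("track %s has no non-gap bins", track$chrom)
  if (robust)
    return(list(chrom = track$chrom, mean_cov = median(v),
                sd_cov = stats::mad(v), n_bins = length(v)))
  m <- mean(v)
  list(chrom = track$chrom, mean_cov = m,
       sd_cov = sqrt(mean((v - m)^2)), n_bins = length(v))
}

# Single-changepoint refinement: best split of x (by between-group sum of
# squares) restricted to cuts in [lo, hi]; returns the 0-based cut position.
refine_breakpoint <- function(x, lo, hi) {
  n <- length(x)
  lo <- max(1L, lo); hi <- min(n - 1L, hi)
  P <- cumsum(x)
  Tt <- P[n]
  cuts <- lo:hi
  bss <- (P[cuts] - cuts * Tt / n)^2 * n / (cuts * (n - cuts))
  cuts[which.max(bss)]
}

cbs_recurse <- function(x, alpha, min_width, n_perm) {
  n <- length(x)
  bps <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    a <- seg[1]; b <- seg[2]
    m <- b - a + 1L
    if (m < 2L * min_width) next
    xs <- x[a:b]
    arc <- cbs_best_arc(xs, min_width)
    if (arc$t <= 0) next
    accept <- if (is.infinite(arc$t)) {
      TRUE
    } else {
      # Bonferroni-style screen over the ~m(m-1)/2 arcs: overwhelming |t|
      # is accepted without permutations
      p_bound <- m * (m - 1) * pt(-arc$t, df = m - 2)
      if (p_bound < alpha / 10) TRUE
      else cbs_perm_test(xs, min_width, arc$u, n_perm, alpha)$p <= alpha
    }
    if (!accept) next
    cuts <- c(arc$i, arc$j)
    cuts <- cuts[cuts > 0 & cuts < m]
    if (!length(cuts)) next
    bps <- c(bps, a - 1L + cuts)
    edges <- c(a - 1L, a - 1L + cuts, b)
    for (k in seq_len(length(edges) - 1L))
      stack[[length(stack) + 1L]] <- c(edges[k] + 1L, edges[k + 1L])
  }
  sort(unique(bps))
}

#' Segment a coverage track by circular binary segmentation
#'
#' Recursive maximal-|t| search over circular arcs with permutation
#' p-values: within each current segment the arc (i, j] most different in
#' mean from its complement is split off if its permutation p-value is at
#' most `alpha`. Gap bins are excluded from all statistics and break the
#' track into independently segmented runs. Long runs (over
#' `coarsen_above` bins) are first segmented on averaged coarse bins and
#' every breakpoint is then refined at full resolution in a local window.
#'
#' @param track a [coverage_track()].
#' @param alpha permutation significance level per split (default 0.01).
#' @param min_width_bins minimum arc/segment width in bins (default 2).
#' @param n_perm permutations per test (default 1000; sequential early
#'   stopping makes the typical cost much smaller).
#' @param coarsen_above run length (bins) above which the multiscale pass is
#'   used (default 6000).
#' @param seed seed for the permutation RNG.
#' @return data frame of raw segments: chrom, start, end (bp, half-open),
#'   mean_cov, n_bins, bin_start, bin_end (1-based bin indices).
#' @export
segment_track <- function(track, alpha = 0.01, min_width_bins = 2,
                          n_perm = 1000, coarsen_above = 6000, seed = NULL) {
  gap <- track$gap
  if (all(gap)) {
    warning(sprintf("track %s is all gaps; no segments", track$chrom))
    return(empty_segments())
  }
  if (sum(!gap) < 2) stop_config("need >= 2 non-gap bins")
  with_seed(seed, {
    runs <- rle(gap)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    out <- list()
    for (r in which(!runs$values)) {
      a <- starts[r]; b <- ends[r]
      x <- track$values[a:b]
      n <- length(x)
      if (n > coarsen_above) {
        f <- ceiling(n / 3000)
        nc <- floor(n / f)
        xc <- colMeans(matrix(x[seq_len(nc * f)], nrow = f))
        tail_vals <- x[-seq_len(nc * f)]
        if (length(tail_vals)) xc <- c(xc, mean(tail_vals))
        bps_c <- cbs_recurse(xc, alpha, min_width_bins, n_perm)
        bps <- vapply(bps_c, function(bc)
          refine_breakpoint(x, (bc - 1L) * f - f, bc * f + f), integer(1))
        bps <- sort(unique(bps))
      } else {
        bps <- cbs_recurse(x, alpha, min_width_bins, n_perm)
      }
      edges <- c(0L, bps, n)
      for (k in seq_len(length(edges) - 1L)) {
        i1 <- a + edges[k]; i2 <- a - 1L + edges[k + 1L]  # 1-based bin range
        out[[length(out) + 1L]] <- data.frame(
          chrom = track$chrom,
          start = (i1 - 1) * track$bin_size,
          end = i2 * track$bin_size,
          mean_cov = mean(track$values[i1:i2]),
          n_bins = i2 - i1 + 1L,
          bin_start = i1, bin_end = i2,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, out)
  })
}

empty_segments <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             mean_cov = numeric(), n_bins = integer(),
             bin_start = integer(), bin_end = integer(),
             stringsAsFactors = FALSE)
}

#' Merge and length-filter raw coverage segments
#'
#' Applies the 50-kb post-processing rules: adjacent segments with the same
#' mean coverage (relative difference at most `mean_tol` of the reference
#' mean) are merged unless separated by a gap larger than `gap_limit`;
#' segments shorter than `min_length` are dissolved into an adjacent
#' compatible segment, or dropped, and merging is re-applied, so every
#' output segment is at least `min_length` long.
#'
#' @param segments raw segments from [segment_track()], one chromosome,
#'   sorted.
#' @param min_length minimum output segment length in bp (default 50 kb).
#' @param gap_limit maximum intervening gap for merging in bp (default 50 kb).
#' @param mean_tol relative mean-equality tolerance (default 0.10). The
#'   literal rule is exact mean equality, unattainable for noisy means;
#'   tolerance is expressed relative to `ref_mean`.
#' @param ref_mean reference mean (the chromosome mean); defaults to the
#'   bin-weighted mean of the input segments.
#' @return data frame of merged segments (chrom, start, end, mean_cov,
#'   n_bins).
#' @export
merge_filter_segments <- function(segments, min_length = 5e4, gap_limit = 5e4,
                                  mean_tol = 0.10, ref_mean = NULL) {
  if (!nrow(segments)) return(segments)
  if (length(unique(segments$chrom)) != 1)
    stop_config("merge_filter_segments() expects a single chromosome")
  s <- segments[order(segments$start), , drop = FALSE]
  ref <- ref_mean %||% (sum(s$mean_cov * s$n_bins) / sum(s$n_bins))
  tol <- mean_tol * ref
  merge_pass <- function(s) {
    repeat {
      if (nrow(s) < 2) return(s)
      gap <- s$start[-1] - s$end[-nrow(s)]
      close_means <- abs(s$mean_cov[-1] - s$mean_cov[-nrow(s)]) <= tol
      k <- which(close_means & gap <= gap_limit)[1]
      if (is.na(k)) return(s)
      nb <- s$n_bins[k] + s$n_bins[k + 1]
      s$mean_cov[k] <- (s$mean_cov[k] * s$n_bins[k] +
                          s$mean_cov[k + 1] * s$n_bins[k + 1]) / nb
      s$end[k] <- s$end[k + 1]
      s$n_bins[k] <- nb
      s <- s[-(k + 1), , drop = FALSE]
    }
  }
  s <- merge_pass(s)
  # dissolve sub-minimum segments into the nearest-mean adjacent neighbour
  # within gap_limit, else drop them
  repeat {
    short <- which(s$end - s$start < min_length)
    if (!length(short)) break
    k <- short[1]
    cand <- c()
    if (k > 1 && s$start[k] - s$end[k - 1] <= gap_limit) cand <- c(cand, k - 1)
    if (k < nrow(s) && s$start[k + 1] - s$end[k] <= gap_limit) cand <- c(cand, k + 1)
    cand <- cand[s$end[cand] - s$start[cand] >= min_length]
    if (length(cand)) {
      j <- cand[which.min(abs(s$mean_cov[cand] - s$mean_cov[k]))]
      nb <- s$n_bins[k] + s$n_bins[j]
      s$mean_cov[j] <- (s$mean_cov[k] * s$n_bins[k] +
                          s$mean_cov[j] * s$n_bins[j]) / nb
      s$n_bins[j] <- nb
      s$start[j] <- min(s$start[j], s$start[k])
      s$end[j] <- max(s$end[j], s$end[k])
    }
    s <- s[-k, , drop = FALSE]
    s <- merge_pass(s)
  }
  rownames(s) <- NULL
  s[, c("chrom", "start", "end", "mean_cov", "n_bins")]
}

# Re-estimate each boundary between adjacent merged segments by maximum
# likelihood in a local window, modelling each side as Gaussian with its own
# mean and variance (read-count variance grows with copy number, so a plain
# least-squares cut systematically misassigns edge bins of the
# higher-coverage side). Dissolving sub-minimum micro-segments can also drag
# a boundary off the ML position; this polish restores it.
refine_boundaries <- function(segments, track, window_bins = 15) {
  if (nrow(segments) < 2) return(segments)
  s <- segments[order(segments$start), , drop = FALSE]
  bs <- track$bin_size
  x <- track$values
  for (i in seq_len(nrow(s) - 1)) {
    if (s$start[i + 1] != s$end[i]) next  # only touching segments
    b <- s$end[i] / bs                    # boundary bin count
    lo <- max(s$start[i] / bs + 1, b - window_bins)
    hi <- min(s$end[i + 1] / bs - 1, b + window_bins)
    if (lo >= hi) next
    # side parameters from bins safely outside the refinement window
    core1 <- x[(s$start[i] / bs + 1):max(s$start[i] / bs + 1, lo - 1)]
    core2 <- x[min(s$end[i + 1] / bs, hi + 1):(s$end[i + 1] / bs)]
    if (anyNA(core1) || anyNA(core2) || length(core1) < 5 || length(core2) < 5)
      next
    m1 <- mean(core1); v1 <- max(var(core1), 1e-8)
    m2 <- mean(core2); v2 <- max(var(core2), 1e-8)
    win <- x[lo:hi]
    if (anyNA(win)) next
    ll1 <- dnorm(win, m1, sqrt(v1), log = TRUE)
    ll2 <- dnorm(win, m2, sqrt(v2), log = TRUE)
    # cut after position c (0 = all window bins on side 2)
    tot <- c(0, cumsum(ll1 - ll2))
    cut <- which.max(tot) - 1L
    new_end <- (lo - 1 + cut) * bs
    if (new_end != s$end[i]) {
      s$end[i] <- new_end
      s$start[i + 1] <- new_end
    }
  }
  s$n_bins <- as.integer((s$end - s$start) / bs)
  for (i in seq_len(nrow(s)))
    s$mean_cov[i] <- mean(x[(s$start[i] / bs + 1):(s$end[i] / bs)])
  s
}

#' Classify segments as deletion / normal / duplication
#'
#' A segment whose mean coverage exceeds the chromosome mean by more than
#' `k` standard deviations is a segmental duplication; more than `k` SDs
#' below it, a deletion; anything else is normal. Default `k = 1`.
#'
#' @param segments merged segments for one chromosome.
#' @param stats [chrom_stats()] of the same chromosome.
#' @param k SD multiplier (default 1; must be > 0 for the deletion and
#'   duplication bands not to overlap).
#' @return `segments` with an added `class` column.
#' @export
classify_segments <- function(segments, stats, k = 1) {
  if (!nrow(segments)) {
    segments$class <- character(0)
    return(segments)
  }
  if (stats$sd_cov == 0 && any(segments$mean_cov != stats$mean_cov))
    warning("degenerate chromosome SD of 0; classifying by strict inequality")
  up <- stats$mean_cov + k * stats$sd_cov
  dn <- stats$mean_cov - k * stats$sd_cov
  segments$class <- ifelse(segments$mean_cov > up, "duplication",
                           ifelse(segments$mean_cov < dn, "deletion", "normal"))
  segments
}

#' Full per-chromosome coverage segmentation pipeline
#'
#' Chains [chrom_stats()], [segment_track()], [merge_filter_segments()] and
#' [classify_segments()] for one track.
#'
#' @param track a [coverage_track()].
#' @param min_length,gap_limit,mean_tol see [merge_filter_segments()].
#' @param k see [classify_segments()].
#' @param alpha,min_width_bins,n_perm,coarsen_above,seed see
#'   [segment_track()].
#' @param robust classify against median/MAD chromosome statistics (see
#'   [chrom_stats()]; default FALSE).
#' @return classified segment data frame.
#' @export
segment_coverage <- function(track, min_length = 5e4, gap_limit = 5e4,
                             mean_tol = 0.10, k = 1, alpha = 0.01,
                             min_width_bins = 2, n_perm = 1000,
                             coarsen_above = 6000, seed = NULL,
                             robust = FALSE) {
  st <- chrom_stats(track, robust = robust)
  raw <- segment_track(track, alpha, min_width_bins, n_perm, coarsen_above,
                       seed = seed)
  mrg <- merge_filter_segments(raw, min_length, gap_limit, mean_tol,
                               ref_mean = st$mean_cov)
  mrg <- refine_boundaries(mrg, track)
  classify_segments(mrg, st, k)
}
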