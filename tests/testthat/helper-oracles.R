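# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Exhaustive least-squares segmentation with at most `max_k` changepoints:
# returns the 0-based cut positions of the smallest k whose best RSS is
# within `tol` of the overall best (for noiseless tracks: the true cuts).
oracle_changepoints <- function(x, max_k = 2, tol = 1e-9) {
  n <- length(x)
  rss <- function(v) sum((v - mean(v))^2)
  seg_rss <- function(cuts) {
    edges <- c(0, cuts, n)
    sum(vapply(seq_len(length(edges) - 1),
               function(i) rss(x[(edges[i] + 1):edges[i + 1]]), numeric(1)))
  }
  best <- list()
  best[["0"]] <- list(cuts = integer(0), rss = rss(x))
  if (max_k >= 1) {
    r1 <- vapply(1:(n - 1), function(c) seg_rss(c), numeric(1))
    best[["1"]] <- list(cuts = which.min(r1), rss = min(r1))
  }
  if (max_k >= 2 && n >= 3) {
    b <- Inf; bc <- NULL
    for (c1 in 1:(n - 2)) for (c2 in (c1 + 1):(n - 1)) {
      r <- seg_rss(c(c1, c2))
      if (r < b) { b <- r; bc <- c(c1, c2) }
    }
    best[["2"]] <- list(cuts = bc, rss = b)
  }
  overall <- min(vapply(best, function(b) b$rss, numeric(1)))
  for (k in names(best))
    if (best[[k]]$rss <= overall + tol) return(as.integer(best[[k]]$cuts))
  integer(0)
}

# Plain sort-and-middle median of the values covering one bin.
oracle_bin_medians <- function(pos_depth, bin_size, nbins) {
  vapply(seq_len(nbins), function(b) {
    v <- pos_depth$depth[pos_depth$pos >= (b - 1) * bin_size &
                           pos_depth$pos < b * bin_size]
    if (!length(v)) return(NA_real_)
    v <- sort(v)
    m <- length(v)
    if (m %% 2 == 1) v[(m + 1) / 2] else (v[m / 2] + v[m / 2 + 1]) / 2
  }, numeric(1))
}

# Pairwise interval-overlap checker (half-open intervals).
oracle_any_overlap <- function(iv) {
  if (nrow(iv) < 2) return(FALSE)
  for (i in 1:(nrow(iv) - 1)) for (j in (i + 1):nrow(iv)) {
    if (iv$chrom[i] == iv$chrom[j] &&
        max(iv$start[i], iv$start[j]) < min(iv$end[i], iv$end[j]))
      return(TRUE)
  }
  FALSE
}

# Brute-force cosegregation clustering by pairwise vector equality.
oracle_equality_bins <- function(scored) {
  m <- ncol(scored)
  bin <- integer(m)
  nxt <- 0L
  for (j in seq_len(m)) {
    hit <- 0L
    if (j > 1) for (i in 1:(j - 1)) {
      if (identical(scored[, i], scored[, j])) { hit <- bin[i]; break }
    }
    if (hit == 0L) { nxt <- nxt + 1L; hit <- nxt }
    bin[j] <- hit
  }
  bin
}

# Exhaustive minimum-adjacent-distance path over all orders (k <= 8).
oracle_best_order <- function(d) {
  k <- nrow(d)
  best <- NULL; best_cost <- Inf
  for (p in combinat_perms(seq_len(k))) {
    if (p[1] > p[k]) next
    cost <- sum(d[cbind(p[-k], p[-1])])
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  list(order = best, cost = best_cost)
}

combinat_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in combinat_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# Small default simulation used by several tests.
toy_sim <- function(seed, n_pairs = 2, chrom_length = 2e7, n_events = 5,
                    ...) {
  simulate_cross(n_pairs = n_pairs, chrom_length = chrom_length,
                 n_events = n_events, seed = seed, ...)
}
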