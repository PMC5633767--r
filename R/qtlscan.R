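haldane_r <- function(d_cm) 0.5 * (1 - exp(-d_cm / 50))

#' Expected parental dosage at arbitrary map positions
#'
#' Flanking-marker imputation for DH lines under the Haldane (no
#' interference) model: at each grid position the probability that a line's
#' genome derives from parent P2, given the nearest informative flanking
#' marker origins. At a fully informative marker the dosage is exactly 0 or
#' 1; with discordant flanks the dosage interpolates and equals 0.5 at the
#' midpoint; lines with no informative flank get 0.5.
#'
#' @param group_bins one element of `attr(map, "bins")`: list with `cM`
#'   (bin positions) and `scored` (lines x bins, 1/2/NA).
#' @param positions cM positions to impute.
#' @return lines x positions matrix of P(origin = P2).
#' @export
expected_genotype <- function(group_bins, positions) {
  cm <- group_bins$cM
  sc <- group_bins$scored
  n <- nrow(sc)
  out <- matrix(0.5, n, length(positions))
  for (i in seq_len(n)) {
    inf <- which(!is.na(sc[i, ]))
    if (!length(inf)) next
    mcm <- cm[inf]
    g <- sc[i, inf]  # 1/2
    li <- findInterval(positions, mcm)  # index of left informative marker
    for (k in seq_along(positions)) {
      pos <- positions[k]
      L <- li[k]
      R <- if (L < length(mcm)) L + 1L else 0L
      if (L >= 1 && pos == mcm[L]) { out[i, k] <- g[L] - 1; next }
      if (L >= 1 && R >= 1) {
        dL <- pos - mcm[L]; dR <- mcm[R] - pos
        rL <- haldane_r(dL); rR <- haldane_r(dR); rLR <- haldane_r(dL + dR)
        pL <- if (g[L] == 2) 1 - rL else rL
        pR <- if (g[R] == 2) 1 - rR else rR
        den <- if (g[L] == g[R]) 1 - rLR else rLR
        out[i, k] <- pL * pR / den
      } else if (L >= 1) {
        rL <- haldane_r(pos - mcm[L])
        out[i, k] <- if (g[L] == 2) 1 - rL else rL
      } else if (R >= 1) {
        rR <- haldane_r(mcm[R] - pos)
        out[i, k] <- if (g[R] == 2) 1 - rR else rR
      }
    }
  }
  out
}

rss_fit <- function(X, y) {
  fit <- .lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Forward selection of cofactor markers
#'
#' Greedy forward selection of bin-representative markers as background
#' cofactors for composite-style interval mapping: at each step the marker
#' with the smallest partial F-test p-value enters if `p < p_enter`, up to
#' `max_cofactors` markers. Missing scores are mean-imputed.
#'
#' @param map a [build_linkage_map()] result.
#' @param phen phenotype vector.
#' @param max_cofactors maximum cofactors (default 5).
#' @param p_enter entry p-value (default 0.001).
#' @return data frame with group, cM, bin marker id of the selected
#'   cofactors, plus attribute `dosage` (lines x k matrix).
#' @export
select_cofactors <- function(map, phen, max_cofactors = 5, p_enter = 0.001) {
  bins <- attr(map, "bins")
  cols <- list(); meta <- list()
  for (b in bins) {
    d <- b$scored - 1
    for (j in seq_len(ncol(d))) {
      v <- d[, j]
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      cols[[length(cols) + 1L]] <- v
      meta[[length(meta) + 1L]] <- data.frame(group = b$group, cM = b$cM[j],
                                              marker = b$bins[j],
                                              stringsAsFactors = FALSE)
    }
  }
  D <- do.call(cbind, cols)
  meta <- do.call(rbind, meta)
  ok <- !is.na(phen)
  y <- phen[ok]; D <- D[ok, , drop = FALSE]
  n <- length(y)
  sel <- integer(0)
  while (length(sel) < max_cofactors) {
    X0 <- cbind(1, D[, sel, drop = FALSE])
    rss0 <- rss_fit(X0, y)
    df_full <- n - ncol(X0) - 1
    best_p <- Inf; best_j <- 0L
    for (j in setdiff(seq_len(ncol(D)), sel)) {
      rss1 <- rss_fit(cbind(X0, D[, j]), y)
      if (rss1 >= rss0) next
      f <- (rss0 - rss1) / (rss1 / df_full)
      p <- pf(f, 1, df_full, lower.tail = FALSE)
      if (p < best_p) { best_p <- p; best_j <- j }
    }
    if (best_j == 0L || best_p >= p_enter) break
    sel <- c(sel, best_j)
  }
  res <- meta[sel, , drop = FALSE]
  attr(res, "dosage") <- {
    full <- do.call(cbind, cols)[, sel, drop = FALSE]
    full
  }
  res
}

scan_group <- function(group_bins, phen, cofactors = NULL, step = 1,
                       window = 10) {
  ok <- !is.na(phen)
  y <- phen[ok]
  n <- length(y)
  grid <- seq(0, max(group_bins$cM), by = step)
  if (max(grid) < max(group_bins$cM)) grid <- c(grid, max(group_bins$cM))
  if (sd(y) == 0) {
    warning("constant phenotype; zero LOD profile")
    return(data.frame(group = group_bins$group, cM = grid, LOD = 0, R2 = 0))
  }
  D <- expected_genotype(group_bins, grid)[ok, , drop = FALSE]
  if (is.null(cofactors) || !nrow(cofactors)) {
    sdD <- apply(D, 2, sd)
    r <- rep(0, length(grid))
    usable <- sdD > 0
    r[usable] <- suppressWarnings(as.vector(cor(y, D[, usable, drop = FALSE])))
    r[is.na(r)] <- 0
    r2 <- r^2
    lod <- -(n / 2) * log10(1 - r2)
    return(data.frame(group = group_bins$group, cM = grid, LOD = lod, R2 = r2))
  }
  cof_d <- attr(cofactors, "dosage")[ok, , drop = FALSE]
  lod <- r2 <- numeric(length(grid))
  for (k in seq_along(grid)) {
    excl <- cofactors$group == group_bins$group &
      abs(cofactors$cM - grid[k]) <= window
    X0 <- cbind(1, cof_d[, !excl, drop = FALSE])
    rss0 <- rss_fit(X0, y)
    x <- D[, k]
    if (sd(x) == 0) { lod[k] <- 0; r2[k] <- 0; next }
    rss1 <- rss_fit(cbind(X0, x), y)
    lod[k] <- (n / 2) * log10(rss0 / rss1)
    r2[k] <- 1 - rss1 / rss0
  }
  data.frame(group = group_bins$group, cM = grid, LOD = pmax(lod, 0),
             R2 = pmax(r2, 0))
}

#' Genome scan for QTL by regression interval mapping
#'
#' Haley-Knott regression of the (standardized) phenotype on expected
#' parental dosage at a cM grid, per linkage group, with optional
#' forward-selected marker cofactors excluded within a +/- `window` cM
#' guard around the test position (a composite-interval-mapping
#' approximation). `LOD = (n/2) log10(RSS_null / RSS_full)`; `R2` is the
#' variance fraction explained relative to the cofactors-only model.
#'
#' @param map a [build_linkage_map()] result.
#' @param phen phenotype vector (one per line, NA allowed).
#' @param step grid step in cM (default 1).
#' @param cim use cofactors (default TRUE).
#' @param max_cofactors,p_enter see [select_cofactors()].
#' @param window cofactor exclusion window in cM (default 10).
#' @param standardize scale the phenotype to unit variance first (default
#'   TRUE; LOD and R2 are unaffected, effect sizes become comparable).
#' @return object of class `lod_profiles`: data frame (group, cM, LOD, R2)
#'   with the cofactor table as attribute `cofactors`.
#' @export
scan_qtl <- function(map, phen, step = 1, cim = TRUE, max_cofactors = 5,
                     p_enter = 0.001, window = 10, standardize = TRUE) {
  if (standardize && sd(phen, na.rm = TRUE) > 0)
    phen <- as.vector(scale(phen))
  cof <- if (cim) select_cofactors(map, phen, max_cofactors, p_enter) else NULL
  bins <- attr(map, "bins")
  prof <- do.call(rbind, lapply(bins, function(b)
    scan_group(b, phen, cof, step, window)))
  rownames(prof) <- NULL
  structure(prof, cofactors = cof, class = c("lod_profiles", "data.frame"))
}

#' Genome-wide null distribution of the maximum LOD
#'
#' Permutes the phenotype across lines and records the genome-wide maximum
#' LOD of a simple interval-mapping scan for each permutation (the standard
#' permutation null for declaring QTL).
#'
#' @param map a [build_linkage_map()] result.
#' @param phen phenotype vector.
#' @param n_perm number of permutations (default 200).
#' @param step grid step in cM (default 2).
#' @param seed RNG seed.
#' @return numeric vector of per-permutation genome-wide max LOD.
#' @export
scan_permutations <- function(map, phen, n_perm = 200, step = 2, seed = NULL) {
  ok <- !is.na(phen)
  y <- phen[ok]
  n <- length(y)
  bins <- attr(map, "bins")
  D <- do.call(cbind, lapply(bins, function(b) {
    grid <- seq(0, max(b$cM), by = step)
    expected_genotype(b, grid)[ok, , drop = FALSE]
  }))
  keep <- apply(D, 2, sd) > 0
  D <- D[, keep, drop = FALSE]
  with_seed(seed, {
    Yp <- sapply(seq_len(n_perm), function(b) sample(y))
    r <- cor(Yp, D)
    maxr2 <- apply(r^2, 1, max)
    -(n / 2) * log10(1 - maxr2)
  })
}

#' Report QTL above a LOD threshold, with event colocalization
#'
#' Local profile maxima above `threshold` (default LOD 5) become QTL; peaks
#' within one group are kept distinct only when separated by a valley
#' deeper than `valley` LOD below the lower peak. Each QTL gets a 1-LOD
#' support interval, the inferred physical interval from the anchors of the
#' markers inside it, and, when an event table is supplied, the
#' rearrangement event whose cM span overlaps the support interval (the
#' colocalization call).
#'
#' @param profiles a [scan_qtl()] result.
#' @param events optional events from [call_rearrangements()].
#' @param map optional map for physical-interval inference.
#' @param threshold LOD threshold (default 5).
#' @param drop support-interval LOD drop (default 1).
#' @param valley LOD valley depth separating peaks (default 2).
#' @param min_distance minimum cM separation between distinct peaks
#'   (default 10, matching the cofactor exclusion window: a plateau carved
#'   by cofactor switching is one QTL, not several).
#' @param trait trait name to report.
#' @return data frame: trait, group, peak_cM, ci_lo, ci_hi, LOD, R2,
#'   phys_chrom, phys_lo, phys_hi, event_id.
#' @export
report_qtl <- function(profiles, events = NULL, map = NULL, threshold = 5,
                       drop = 1, valley = 2, min_distance = 10,
                       trait = "trait") {
  out <- list()
  for (g in unique(profiles$group)) {
    pg <- profiles[profiles$group == g, ]
    v <- pg$LOD
    nv <- length(v)
    is_max <- v > threshold &
      v >= c(-Inf, v[-nv]) & v >= c(v[-1], -Inf)
    peaks <- which(is_max)
    if (!length(peaks)) next
    # merge peaks not separated by a deep enough valley
    repeat {
      if (length(peaks) < 2) break
      merged <- FALSE
      for (k in seq_len(length(peaks) - 1)) {
        lo <- min(v[peaks[k]:peaks[k + 1]])
        if (pg$cM[peaks[k + 1]] - pg$cM[peaks[k]] < min_distance ||
            lo > min(v[peaks[k]], v[peaks[k + 1]]) - valley) {
          peaks <- peaks[-(k + if (v[peaks[k]] < v[peaks[k + 1]]) 0 else 1)]
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
    for (p in peaks) {
      lim <- v[p] - drop
      l <- p; while (l > 1 && v[l - 1] >= lim) l <- l - 1
      r <- p; while (r < nv && v[r + 1] >= lim) r <- r + 1
      ci <- c(pg$cM[l], pg$cM[r])
      if (!is.null(map)) {
        # expand the support interval to the nearest flanking map markers
        # (the usual convention; grid-resolution intervals are artificially
        # narrow for strong QTL)
        mcm <- sort(unique(map$cM[map$group == g]))
        below <- mcm[mcm <= ci[1]]
        above <- mcm[mcm >= ci[2]]
        if (length(below)) ci[1] <- max(below)
        if (length(above)) ci[2] <- min(above)
      }
      phys <- c(NA_character_, NA_real_, NA_real_)
      if (!is.null(map)) {
        mk <- map[map$group == g & map$cM >= ci[1] & map$cM <= ci[2] &
                    map$anchor_chrom == map$group_chrom, ]
        if (nrow(mk))
          phys <- c(mk$anchor_chrom[1], min(mk$anchor_pos), max(mk$anchor_pos))
      }
      eid <- NA_character_
      if (!is.null(events) && nrow(events)) {
        cand <- which(!is.na(events$group) & events$group == g &
                        !is.na(events$cm_start) &
                        events$cm_start <= ci[2] & events$cm_end >= ci[1])
        if (length(cand)) {
          ovl <- pmin(events$cm_end[cand], ci[2]) -
            pmax(events$cm_start[cand], ci[1])
          eid <- events$event_id[cand[which.max(ovl)]]
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        trait = trait, group = g, peak_cM = pg$cM[p], ci_lo = ci[1],
        ci_hi = ci[2], LOD = v[p], R2 = pg$R2[p],
        phys_chrom = phys[1], phys_lo = as.numeric(phys[2]),
        phys_hi = as.numeric(phys[3]), event_id = eid,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out))
    return(data.frame(trait = character(), group = character(),
                      peak_cM = numeric(), ci_lo = numeric(),
                      ci_hi = numeric(), LOD = numeric(), R2 = numeric(),
                      phys_chrom = character(), phys_lo = numeric(),
                      phys_hi = numeric(), event_id = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
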