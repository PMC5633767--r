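#' Simulate a toy allopolyploid genome with homoeologous blocks
#'
#' Builds a two-subgenome genome model (subgenomes A and C, as in *Brassica
#' napus*) in which every A chromosome is fully tiled by co-linear homoeology
#' blocks pairing it with its C partner. Coordinates are 0-based half-open.
#'
#' @param n_pairs number of homoeologous chromosome pairs (>= 1).
#' @param chrom_length chromosome length in bp; either a single value or one
#'   per pair.
#' @param bin_size coverage bin size in bp (default 1000).
#' @param blocks_per_pair number of co-linear homoeology blocks tiling each
#'   pair (default 1, i.e. whole-chromosome homoeology).
#' @param seed optional RNG seed (the model is deterministic; kept for
#'   interface symmetry with the other generators).
#' @return an object of class `genome_model`: a list with `chromosomes`
#'   (data frame: name, length, subgenome, pair), `homoeology` (data frame:
#'   chrom_a, start_a, end_a, chrom_c, start_c, end_c) and `bin_size`.
#' @export
simulate_genome <- function(n_pairs = 2, chrom_length = 2e7, bin_size = 1000,
                            blocks_per_pair = 1, seed = NULL) {
  if (n_pairs < 1) stop_config("n_pairs must be >= 1")
  len <- rep_len(as.numeric(chrom_length), n_pairs)
  if (any(len <= 0)) stop_config("chromosome lengths must be > 0")
  if (any(len / blocks_per_pair < bin_size))
    stop_config("homoeology block size smaller than one bin: reduce blocks_per_pair")
  chroms <- data.frame(
    name = c(sprintf("A%02d", seq_len(n_pairs)), sprintf("C%02d", seq_len(n_pairs))),
    length = c(len, len),
    subgenome = rep(c("A", "C"), each = n_pairs),
    pair = rep(seq_len(n_pairs), 2),
    stringsAsFactors = FALSE
  )
  hom <- do.call(rbind, lapply(seq_len(n_pairs), function(p) {
    edges <- round(seq(0, len[p], length.out = blocks_per_pair + 1))
    data.frame(
      chrom_a = sprintf("A%02d", p), start_a = edges[-length(edges)], end_a = edges[-1],
      chrom_c = sprintf("C%02d", p), start_c = edges[-length(edges)], end_c = edges[-1],
      stringsAsFactors = FALSE
    )
  }))
  structure(list(chromosomes = chroms, homoeology = hom, bin_size = bin_size),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes (%d homoeologous pairs), %d blocks, bin %d bp\n",
              nrow(x$chromosomes), nrow(x$chromosomes) / 2L, nrow(x$homoeology),
              x$bin_size))
  invisible(x)
}

chrom_length_of <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$name)
  if (anyNA(i)) stop_config("unknown chromosome: %s", chrom[which(is.na(i))[1]])
  genome$chromosomes$length[i]
}

#' Project an interval onto its homoeologous image
#'
#' Maps an interval through the genome's homoeology table using
#' piecewise-linear (proportional) coordinates within each block. Intervals
#' spanning several blocks are projected block-wise.
#'
#' @param genome a `genome_model` or a homoeology data frame.
#' @param chrom,start,end interval to project (0-based half-open).
#' @return data frame with columns chrom, start, end of the projected pieces
#'   (one row per homoeology block touched), sorted by position.
#' @export
homoeologous_image <- function(genome, chrom, start, end) {
  hom <- if (inherits(genome, "genome_model")) genome$homoeology else genome
  out <- list()
  for (k in seq_len(nrow(hom))) {
    b <- hom[k, ]
    for (side in 1:2) {
      if (side == 1) {
        sc <- b$chrom_a; ss <- b$start_a; se <- b$end_a
        tc <- b$chrom_c; ts <- b$start_c; te <- b$end_c
      } else {
        sc <- b$chrom_c; ss <- b$start_c; se <- b$end_c
        tc <- b$chrom_a; ts <- b$start_a; te <- b$end_a
      }
      if (chrom != sc) next
      lo <- max(start, ss); hi <- min(end, se)
      if (hi <= lo) next
      scale <- (te - ts) / (se - ss)
      out[[length(out) + 1]] <- data.frame(
        chrom = tc,
        start = round(ts + (lo - ss) * scale),
        end = round(ts + (hi - ss) * scale),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Simulate parental rearrangement events
#'
#' Places non-overlapping deletions, duplications and homoeologous exchanges
#' (HE) on a parent's genome. An HE has a lost interval and a gained interval
#' that is the homoeologous image of the lost one; a deletion has only a lost
#' interval and a duplication only a gained (in-place duplicated) interval.
#' All intervals are aligned to bin boundaries, and gained images are
#' reserved so that no two events (including their images) overlap.
#'
#' @param genome a `genome_model`.
#' @param n_events number of events to place.
#' @param kind_mix named proportions over c("HE", "deletion", "duplication").
#' @param kinds optional explicit kind per event (overrides `kind_mix`
#'   sampling; recycled to `n_events`).
#' @param size_range bp, c(min, max) event size; min must be >= one bin.
#' @param carrier_parent parent carrying the events ("P1" or "P2"); may be a
#'   vector recycled over events.
#' @param seed RNG seed.
#' @param max_tries placement retries before giving up with an error.
#' @return data frame with one row per event: event_id, kind, carrier_parent,
#'   lost_chrom/lost_start/lost_end and gained_chrom/gained_start/gained_end
#'   (NA where the event has no such interval).
#' @export
simulate_parent_events <- function(genome, n_events,
                                   kind_mix = c(HE = 0.5, deletion = 0.3, duplication = 0.2),
                                   size_range = c(5e5, 2e6),
                                   carrier_parent = "P2", seed = NULL,
                                   kinds = NULL,
                                   max_tries = 200 * max(1, n_events)) {
  empty <- data.frame(event_id = character(), kind = character(),
                      carrier_parent = character(),
                      lost_chrom = character(), lost_start = numeric(), lost_end = numeric(),
                      gained_chrom = character(), gained_start = numeric(), gained_end = numeric(),
                      stringsAsFactors = FALSE)
  if (n_events == 0) return(empty)
  bs <- genome$bin_size
  if (size_range[1] < bs) stop_config("minimum event size must be >= one bin (%d bp)", bs)
  kinds_all <- c("HE", "deletion", "duplication")
  mix <- kind_mix[kinds_all]
  mix[is.na(mix)] <- 0
  if (sum(mix) <= 0) stop_config("kind_mix must have positive mass")
  if (!is.null(kinds) && !all(kinds %in% kinds_all))
    stop_config("kinds must be among %s", paste(kinds_all, collapse = "/"))
  with_seed(seed, {
    kinds <- if (is.null(kinds)) sample(kinds_all, n_events, replace = TRUE, prob = mix)
             else rep_len(kinds, n_events)
    carrier <- rep_len(carrier_parent, n_events)
    occupied <- list()  # per chromosome: matrix of (start, end)
    overlaps_any <- function(chrom, s, e) {
      occ <- occupied[[chrom]]
      !is.null(occ) && any(pmax(occ[, 1], s) < pmin(occ[, 2], e))
    }
    reserve <- function(chrom, s, e) {
      occupied[[chrom]] <<- rbind(occupied[[chrom]], c(s, e))
    }
    rows <- vector("list", n_events)
    for (ev in seq_len(n_events)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        size <- round(runif(1, size_range[1], size_range[2]) / bs) * bs
        size <- max(size, bs)
        if (kinds[ev] == "HE") {
          # lost interval must sit inside a single homoeology block
          k <- sample(nrow(genome$homoeology), 1)
          side <- sample(1:2, 1)
          b <- genome$homoeology[k, ]
          if (side == 1) { chrom <- b$chrom_a; bs0 <- b$start_a; be0 <- b$end_a }
          else { chrom <- b$chrom_c; bs0 <- b$start_c; be0 <- b$end_c }
          if (be0 - bs0 < size) next
          s <- bs0 + floor(runif(1, 0, (be0 - bs0 - size) / bs + 1)) * bs
          e <- s + size
          img <- homoeologous_image(genome, chrom, s, e)
          if (nrow(img) != 1) next
          if (overlaps_any(chrom, s, e) ||
              overlaps_any(img$chrom, img$start, img$end)) next
          reserve(chrom, s, e); reserve(img$chrom, img$start, img$end)
          rows[[ev]] <- data.frame(event_id = sprintf("EV%d", ev), kind = "HE",
                                   carrier_parent = carrier[ev],
                                   lost_chrom = chrom, lost_start = s, lost_end = e,
                                   gained_chrom = img$chrom, gained_start = img$start,
                                   gained_end = img$end, stringsAsFactors = FALSE)
        } else {
          chrom <- sample(genome$chromosomes$name, 1)
          L <- chrom_length_of(genome, chrom)
          if (L < size) next
          s <- floor(runif(1, 0, (L - size) / bs + 1)) * bs
          e <- s + size
          if (overlaps_any(chrom, s, e)) next
          reserve(chrom, s, e)
          rows[[ev]] <- if (kinds[ev] == "deletion") {
            data.frame(event_id = sprintf("EV%d", ev), kind = "deletion",
                       carrier_parent = carrier[ev],
                       lost_chrom = chrom, lost_start = s, lost_end = e,
                       gained_chrom = NA_character_, gained_start = NA_real_,
                       gained_end = NA_real_, stringsAsFactors = FALSE)
          } else {
            data.frame(event_id = sprintf("EV%d", ev), kind = "duplication",
                       carrier_parent = carrier[ev],
                       lost_chrom = NA_character_, lost_start = NA_real_,
                       lost_end = NA_real_,
                       gained_chrom = chrom, gained_start = s, gained_end = e,
                       stringsAsFactors = FALSE)
          }
        }
        placed <- TRUE
        break
      }
      if (!placed)
        stop_config("could not place event %d without overlap after %d tries",
                    ev, max_tries)
    }
    do.call(rbind, rows)
  })
}

# Focal position whose parental origin decides whether a DH line carries the
# rearranged haplotype: the lost interval's midpoint (the physical residence
# of an HE's translocated copy), or the gained midpoint for pure duplications.
event_focal <- function(events) {
  has_lost <- !is.na(events$lost_chrom)
  data.frame(
    chrom = ifelse(has_lost, events$lost_chrom, events$gained_chrom),
    pos = ifelse(has_lost, (events$lost_start + events$lost_end) / 2,
                 (events$gained_start + events$gained_end) / 2),
    stringsAsFactors = FALSE
  )
}

#' Simulate a doubled-haploid population
#'
#' Each DH line is a single recombinant gamete from the F1 of parents P1 and
#' P2, rendered fully homozygous. Crossovers per chromosome are Poisson with
#' the given mean (no interference) and uniform in position, so downstream
#' Haldane map distances are exactly consistent with the meiosis model.
#'
#' @param genome a `genome_model`.
#' @param events event table from [simulate_parent_events()] (may be empty);
#'   used to derive the per-line carrier matrix.
#' @param n_lines number of DH lines (>= 2; default 164).
#' @param crossovers_mean mean crossovers per chromosome per meiosis.
#' @param seed RNG seed.
#' @return an object of class `dh_population`: list with `n_lines`,
#'   `inheritance` (per chromosome: list of per-line crossover positions and
#'   the parental origin, 1 or 2, at position 0) and `carriers`, an
#'   n_lines x n_events logical matrix (TRUE = line inherited the rearranged
#'   haplotype).
#' @export
simulate_dh_population <- function(genome, events = NULL, n_lines = 164,
                                   crossovers_mean = 2, seed = NULL) {
  if (n_lines < 2) stop_config("n_lines must be >= 2")
  with_seed(seed, {
    inh <- lapply(seq_len(nrow(genome$chromosomes)), function(ci) {
      L <- genome$chromosomes$length[ci]
      k <- rpois(n_lines, crossovers_mean)
      list(
        breaks = lapply(seq_len(n_lines), function(i) sort(runif(k[i], 0, L))),
        start = sample(1:2, n_lines, replace = TRUE)
      )
    })
    names(inh) <- genome$chromosomes$name
    pop <- structure(list(n_lines = n_lines, inheritance = inh,
                          chromosomes = genome$chromosomes$name),
                     class = "dh_population")
    if (!is.null(events) && nrow(events)) {
      foc <- event_focal(events)
      carriers <- sapply(seq_len(nrow(events)), function(e) {
        org <- parental_origin(pop, foc$chrom[e], foc$pos[e])[, 1]
        org == match(events$carrier_parent[e], c("P1", "P2"))
      })
      carriers <- matrix(carriers, nrow = n_lines,
                         dimnames = list(NULL, events$event_id))
    } else {
      carriers <- matrix(logical(0), nrow = n_lines, ncol = 0)
    }
    pop$carriers <- carriers
    pop
  })
}

#' @export
print.dh_population <- function(x, ...) {
  cat(sprintf("dh_population: %d lines, %d chromosomes, %d tracked events\n",
              x$n_lines, length(x$inheritance), ncol(x$carriers)))
  invisible(x)
}

#' Parental origin of DH lines at given positions
#'
#' @param pop a `dh_population`.
#' @param chrom chromosome name.
#' @param positions bp positions on that chromosome.
#' @return integer matrix (lines x positions) of parental origins (1 = P1,
#'   2 = P2).
#' @export
parental_origin <- function(pop, chrom, positions) {
  ch <- pop$inheritance[[chrom]]
  if (is.null(ch)) stop_config("unknown chromosome: %s", chrom)
  m <- vapply(seq_len(pop$n_lines), function(i) {
    n_cross <- findInterval(positions, ch$breaks[[i]])
    ifelse(n_cross %% 2 == 0, ch$start[i], 3L - ch$start[i])
  }, integer(length(positions)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)  # single position
  t(m)
}

#' Simulate Infinium-style SNP array calls for a DH population
#'
#' Markers are placed at regular spacing on every chromosome and emitted with
#' the call semantics of a two-subgenome Infinium array:
#' * markers inside a lost (deleted) interval are no-calls (NC) in carrier
#'   lines and in the carrier parent, and show the other parent's homozygous
#'   call elsewhere (truth class **PA**, dominant presence-absence scoring);
#' * markers inside a gained (duplicated) interval give heterozygous-looking
#'   AB calls in carrier lines and in the carrier parent (truth class
#'   **het**, the hemi-SNP pattern: the duplicated copy contributes the
#'   alternative allele while the resident locus is monomorphic);
#' * all other markers are simple codominant SNPs segregating AA/BB 1:1 by
#'   parental origin at the marker position (truth class **simple**).
#' Calls inside event intervals follow the event's carrier status, never a
#' within-event crossover: hemizygous rearranged regions do not recombine.
#' Technical noise is sprinkled on line calls only: miscalls at `error_rate`
#' (a random different genotype) and missing NC at `missing_rate`.
#'
#' @param genome a `genome_model`.
#' @param events event table (may be empty).
#' @param pop a `dh_population` (its `carriers` matrix must match `events`).
#' @param marker_spacing bp between adjacent markers (>= 1).
#' @param missing_rate,error_rate technical noise rates in \[0, 1\].
#' @param seed RNG seed.
#' @return list with `parents` (2 x m character matrix, rows P1/P2), `lines`
#'   (n_lines x m), `anchors` (data frame marker/chrom/pos/overlap_length/
#'   identity/has_gaps/n_hits) and `truth` (marker, chrom, pos, class,
#'   event_id).
#' @export
simulate_array_calls <- function(genome, events, pop, marker_spacing = 5e4,
                                 missing_rate = 0.02, error_rate = 0.005,
                                 seed = NULL) {
  if (marker_spacing < 1) stop_config("marker_spacing must be >= 1 bp")
  if (missing_rate < 0 || missing_rate > 1 || error_rate < 0 || error_rate > 1)
    stop_config("rates must be in [0, 1]")
  if (is.null(events)) events <- simulate_parent_events(genome, 0)
  with_seed(seed, {
    mk <- do.call(rbind, lapply(seq_len(nrow(genome$chromosomes)), function(ci) {
      L <- genome$chromosomes$length[ci]
      pos <- seq(floor(marker_spacing / 2), L - 1, by = marker_spacing)
      data.frame(chrom = genome$chromosomes$name[ci], pos = pos,
                 stringsAsFactors = FALSE)
    }))
    mk$marker <- paste0(mk$chrom, "_", mk$pos)
    m <- nrow(mk)
    mk$class <- "simple"
    mk$event_id <- NA_character_
    for (e in seq_len(nrow(events))) {
      ev <- events[e, ]
      if (!is.na(ev$lost_chrom)) {
        inlost <- mk$chrom == ev$lost_chrom & mk$pos >= ev$lost_start &
          mk$pos < ev$lost_end
        mk$class[inlost] <- "PA"
        mk$event_id[inlost] <- ev$event_id
      }
      if (!is.na(ev$gained_chrom)) {
        ingain <- mk$chrom == ev$gained_chrom & mk$pos >= ev$gained_start &
          mk$pos < ev$gained_end
        mk$class[ingain] <- "het"
        mk$event_id[ingain] <- ev$event_id
      }
    }
    n <- pop$n_lines
    parents <- matrix(NA_character_, 2, m, dimnames = list(c("P1", "P2"), mk$marker))
    lines <- matrix(NA_character_, n, m,
                    dimnames = list(sprintf("DH%03d", seq_len(n)), mk$marker))
    hom_allele <- sample(c("AA", "BB"), m, replace = TRUE)  # allele of the non-carrier/P1 side
    for (j in seq_len(m)) {
      cls <- mk$class[j]
      if (cls == "simple") {
        a1 <- hom_allele[j]
        a2 <- if (a1 == "AA") "BB" else "AA"
        parents[, j] <- c(a1, a2)
        org <- parental_origin(pop, mk$chrom[j], mk$pos[j])[, 1]
        lines[, j] <- ifelse(org == 1, a1, a2)
      } else {
        ev <- match(mk$event_id[j], events$event_id)
        cp <- match(events$carrier_parent[ev], c("P1", "P2"))
        carrier <- pop$carriers[, ev]
        other <- hom_allele[j]
        if (cls == "PA") {
          parents[cp, j] <- "NC"
          parents[3 - cp, j] <- other
          lines[, j] <- ifelse(carrier, "NC", other)
        } else {  # het
          parents[cp, j] <- "AB"
          parents[3 - cp, j] <- other
          lines[, j] <- ifelse(carrier, "AB", other)
        }
      }
    }
    if (error_rate > 0) {
      called <- lines != "NC"
      err <- called & matrix(runif(n * m) < error_rate, n, m)
      if (any(err)) {
        idx <- which(err)
        lines[idx] <- vapply(lines[idx], function(g)
          sample(setdiff(c("AA", "AB", "BB"), g), 1), character(1))
      }
    }
    if (missing_rate > 0) {
      miss <- matrix(runif(n * m) < missing_rate, n, m)
      lines[miss] <- "NC"
    }
    anchors <- data.frame(marker = mk$marker, chrom = mk$chrom, pos = mk$pos,
                          overlap_length = 60, identity = 99.5,
                          has_gaps = FALSE, n_hits = 1L, stringsAsFactors = FALSE)
    list(parents = parents, lines = lines, anchors = anchors,
         truth = mk[, c("marker", "chrom", "pos", "class", "event_id")])
  })
}

#' Simulate a read-depth coverage track
#'
#' Per-bin read counts are drawn from a negative binomial with mean
#' `mean_depth * copy_number / 2` and the given dispersion (`size`
#' parameter; `Inf` gives Poisson). The copy-number baseline is 2;
#' lost intervals drop to `2 - loss` and gained intervals rise to
#' `2 + gain`. Parents carry rearrangements hemizygously
#' (`zygosity = "hemizygous"`: loss/gain of 1 copy) whereas DH lines are
#' homozygous (loss/gain of 2).
#'
#' @param genome a `genome_model`.
#' @param events event table (may be NULL/empty).
#' @param carrier which parent's genome to emulate ("P1"/"P2"): events whose
#'   `carrier_parent` matches get their rearranged copy number. Alternatively
#'   pass `carried`, a logical vector over events, directly.
#' @param mean_depth mean reads per bin at copy number 2 (> 0). The toy
#'   default of 200 reads per 1000-bp bin corresponds to ~20x depth with
#'   100-bp reads.
#' @param dispersion negative-binomial size parameter (Inf = Poisson).
#' @param zygosity "hemizygous" (parent) or "homozygous" (DH line).
#' @param loss,gain copy-number change in lost/gained intervals; defaults
#'   follow `zygosity` (1 or 2).
#' @param carried optional logical vector over events overriding `carrier`.
#' @param seed RNG seed.
#' @return named list of `coverage_track` objects, one per chromosome.
#' @export
simulate_coverage <- function(genome, events = NULL, carrier = "P2",
                              mean_depth = 200, dispersion = 50,
                              zygosity = c("hemizygous", "homozygous"),
                              loss = NULL, gain = NULL, carried = NULL,
                              seed = NULL) {
  if (mean_depth <= 0) stop_config("mean_depth must be > 0")
  zygosity <- match.arg(zygosity)
  dz <- if (zygosity == "hemizygous") 1 else 2
  loss <- loss %||% dz
  gain <- gain %||% dz
  if (is.null(events)) events <- simulate_parent_events(simulate_genome(1), 0)
  if (is.null(carried)) carried <- events$carrier_parent == carrier
  bs <- genome$bin_size
  with_seed(seed, {
    tracks <- lapply(seq_len(nrow(genome$chromosomes)), function(ci) {
      chrom <- genome$chromosomes$name[ci]
      nbins <- ceiling(genome$chromosomes$length[ci] / bs)
      cn <- rep(2, nbins)
      for (e in which(carried)) {
        ev <- events[e, ]
        if (!is.na(ev$lost_chrom) && ev$lost_chrom == chrom) {
          b <- (floor(ev$lost_start / bs) + 1):ceiling(ev$lost_end / bs)
          cn[b] <- pmax(0, 2 - loss)
        }
        if (!is.na(ev$gained_chrom) && ev$gained_chrom == chrom) {
          b <- (floor(ev$gained_start / bs) + 1):ceiling(ev$gained_end / bs)
          cn[b] <- 2 + gain
        }
      }
      mu <- mean_depth * cn / 2
      vals <- if (is.infinite(dispersion)) rpois(nbins, mu)
              else rnbinom(nbins, mu = mu, size = dispersion)
      coverage_track(chrom, as.numeric(vals), bin_size = bs)
    })
    names(tracks) <- genome$chromosomes$name
    tracks
  })
}

#' Simulate an additive QTL phenotype from event carrier status
#'
#' `y_i = mu + a * carrier_i + eps_i`, `eps ~ N(0, sigma^2)`, where carrier
#' status refers to one simulated rearrangement event. The implied
#' narrow-sense heritability `a^2 / (a^2 + 4 sigma^2)` (carrier variance 1/4
#' in a 1:1 DH population) is attached as attribute `"h2"`.
#'
#' @param pop a `dh_population` with a carrier matrix, or a logical carrier
#'   vector.
#' @param event event column (index or id) in the carrier matrix.
#' @param mu,a,sigma intercept, additive effect and residual SD (trait units).
#' @param seed RNG seed.
#' @return numeric phenotype vector, one value per line.
#' @export
simulate_phenotype <- function(pop, event = 1, mu = 0, a = 2, sigma = 1,
                               seed = NULL) {
  if (sigma < 0) stop_config("sigma must be >= 0")
  carrier <- if (inherits(pop, "dh_population")) {
    if (!ncol(pop$carriers)) stop_config("population has no tracked events")
    pop$carriers[, event]
  } else as.logical(pop)
  with_seed(seed, {
    y <- mu + a * carrier + rnorm(length(carrier), 0, sigma)
    attr(y, "h2") <- a^2 / (a^2 + 4 * sigma^2)
    y
  })
}

#' Simulate a complete cross: genome, events, population, calls, coverage
#'
#' Convenience wrapper chaining all generators with a single seed. Defaults
#' mirror a desk-scale version of a natural x synthetic *B. napus* DH study:
#' 2 homoeologous pairs of 20 Mb, 164 DH lines, 50-kb marker spacing, 200
#' reads per 1000-bp bin (~20x), all rearrangements carried by parent P2
#' (the synthetic donor).
#'
#' @param n_pairs,chrom_length,bin_size genome layout.
#' @param n_events,kind_mix,size_range rearrangement events of parent P2.
#' @param n_lines,crossovers_mean DH population.
#' @param marker_spacing,missing_rate,error_rate array calls.
#' @param mean_depth,dispersion coverage tracks (both parents).
#' @param qtl NULL or list(event=, mu=, a=, sigma=) for a phenotype.
#' @param seed master seed; stage seeds are derived from it.
#' @return list with genome, events, pop, calls, coverage (list with P1 and
#'   P2 track lists), phenotype (or NULL).
#' @export
simulate_cross <- function(n_pairs = 2, chrom_length = 2e7, bin_size = 1000,
                           n_events = 5,
                           kind_mix = c(HE = 0.5, deletion = 0.3, duplication = 0.2),
                           size_range = c(5e5, 2e6), n_lines = 164,
                           crossovers_mean = 2, marker_spacing = 5e4,
                           missing_rate = 0.02, error_rate = 0.005,
                           mean_depth = 200, dispersion = 50, qtl = NULL,
                           seed = 1) {
  s <- (as.integer(seed) %% 199999L) * 10L
  genome <- simulate_genome(n_pairs, chrom_length, bin_size)
  events <- simulate_parent_events(genome, n_events, kind_mix, size_range,
                                   carrier_parent = "P2", seed = s + 1L)
  pop <- simulate_dh_population(genome, events, n_lines, crossovers_mean,
                                seed = s + 2L)
  calls <- simulate_array_calls(genome, events, pop, marker_spacing,
                                missing_rate, error_rate, seed = s + 3L)
  coverage <- list(
    P1 = simulate_coverage(genome, events, carrier = "P1", mean_depth,
                           dispersion, seed = s + 4L),
    P2 = simulate_coverage(genome, events, carrier = "P2", mean_depth,
                           dispersion, seed = s + 5L)
  )
  phenotype <- if (!is.null(qtl)) {
    do.call(simulate_phenotype,
            c(list(pop = pop, seed = s + 6L), qtl))
  }
  list(genome = genome, events = events, pop = pop, calls = calls,
       coverage = coverage, phenotype = phenotype)
}
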