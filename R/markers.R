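#' Filter marker anchors by BLAST-hit quality
#'
#' Keeps markers whose single physical anchor meets the standard criteria:
#' minimum overlap 50 bp, minimum identity 95%, no sequence gaps, exactly
#' one hit (only uniquely anchored SNPs are positionally informative).
#'
#' @param anchors data frame with columns marker, overlap_length, identity,
#'   has_gaps, n_hits (plus chrom/pos, carried through).
#' @param min_overlap minimum alignment overlap in bp (default 50).
#' @param min_identity minimum percent identity (default 95).
#' @param require_unique require n_hits == 1 (default TRUE).
#' @return the retained rows of `anchors`.
#' @export
filter_anchors <- function(anchors, min_overlap = 50, min_identity = 95,
                           require_unique = TRUE) {
  keep <- anchors$overlap_length >= min_overlap &
    anchors$identity >= min_identity &
    !anchors$has_gaps &
    (!require_unique | anchors$n_hits == 1)
  anchors[keep, , drop = FALSE]
}

#' Chi-square test for 1:1 DH segregation
#'
#' `chi2 = (c1 - c2)^2 / (c1 + c2)` on 1 df; a marker passes when
#' `p >= alpha` (DH lines must fit the expected 1:1 segregation).
#'
#' @param count_p1,count_p2 lines scored as each parental allele.
#' @param alpha significance level (default 0.05).
#' @return list with chi2, p, pass.
#' @export
segregation_test <- function(count_p1, count_p2, alpha = 0.05) {
  n <- count_p1 + count_p2
  chi2 <- ifelse(n > 0, (count_p1 - count_p2)^2 / n, NA_real_)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p = p, pass = !is.na(p) & p >= alpha)
}

#' Classify SNP-array markers in a two-parent DH population
#'
#' Assigns every marker one of the scoring patterns used for
#' rearrangement-aware DH mapping:
#'
#' * **simple** — parents opposite homozygotes (AA vs BB), lines segregate
#'   AA/BB (sporadic NC tolerated);
#' * **het** — one parent heterozygous-appearing (AB, the hemi-SNP pattern
#'   of a marker hybridizing a duplicated locus), the other homozygous;
#'   lines segregate AB vs that homozygous call, and AB is scored as the
#'   hemi-SNP parent's allele (codominant recoding);
#' * **PA** — one parent gives no call (probe site deleted), lines split
#'   called/NC near 1:1; NC is scored as the null-allele parent (dominant
#'   presence-absence recoding);
#' * **monomorphic** — parents identical and lines uniform;
#' * **rejected** — anything else, with a reason code.
#'
#' Class assignment is structural; the chi-square 1:1 segregation test is
#' recorded separately (`pass_1to1`) and gates admission to mapping. Marker
#' names get the class suffix (`-het`, `-PA`) used on the genetic map.
#'
#' @param parents 2 x m character matrix of parental calls (rows P1, P2) in
#'   AA/BB/AB/NC.
#' @param lines n x m character matrix of DH line calls.
#' @param alpha level for the 1:1 test (default 0.05).
#' @param min_informative minimum lines with non-missing scores for a marker
#'   to be considered scorable (default 20).
#' @param sporadic_nc maximum NC fraction treated as technical missingness
#'   in non-PA classes (default 0.10).
#' @param max_violation maximum fraction of lines with calls outside the
#'   expected pattern (treated as missing) before rejection (default 0.05).
#' @param pa_band NC-fraction band regarded as presence-absence segregation
#'   rather than missingness (default c(0.2, 0.8)).
#' @return list with `records` (data frame: marker, class, reason, suffix,
#'   name, count_p1, count_p2, n_missing, chi2, p, pass_1to1) and `scored`
#'   (n x m integer matrix: 1 = P1 allele, 2 = P2 allele, NA = missing).
#' @export
classify_markers <- function(parents, lines, alpha = 0.05,
                             min_informative = 20, sporadic_nc = 0.10,
                             max_violation = 0.05, pa_band = c(0.2, 0.8)) {
  m <- ncol(lines)
  n <- nrow(lines)
  stopifnot(ncol(parents) == m, nrow(parents) == 2)
  ids <- colnames(lines) %||% paste0("M", seq_len(m))
  scored <- matrix(NA_integer_, n, m, dimnames = list(rownames(lines), ids))
  cls <- character(m); reason <- rep(NA_character_, m)
  hom <- c("AA", "BB")
  for (j in seq_len(m)) {
    p1 <- parents[1, j]; p2 <- parents[2, j]
    g <- lines[, j]
    nc <- g == "NC"
    if (p1 == "NC" && p2 == "NC") {
      cls[j] <- "rejected"; reason[j] <- "parents_nc"
      next
    }
    if (xor(p1 == "NC", p2 == "NC")) {
      null_parent <- if (p1 == "NC") 1L else 2L
      called_parent <- 3L - null_parent
      pc <- parents[called_parent, j]
      nc_frac <- mean(nc)
      ok <- !nc & g == pc
      viol <- !nc & g != pc
      if (nc_frac >= pa_band[1] && nc_frac <= pa_band[2] &&
          mean(viol) <= max_violation) {
        cls[j] <- "PA"
        scored[nc, j] <- null_parent
        scored[ok, j] <- called_parent
      } else if (nc_frac <= sporadic_nc && all(g[!nc] == pc)) {
        cls[j] <- "monomorphic"
      } else {
        cls[j] <- "rejected"; reason[j] <- "pa_pattern"
      }
      next
    }
    if (p1 == p2) {
      uniform <- mean(!nc & g != p1) <= max_violation
      if (uniform) cls[j] <- "monomorphic"
      else { cls[j] <- "rejected"; reason[j] <- "identical_parents_segregating" }
      next
    }
    if (p1 %in% hom && p2 %in% hom) {
      viol <- !nc & !(g %in% c(p1, p2))
      if (mean(nc) <= sporadic_nc && mean(viol) <= max_violation) {
        cls[j] <- "simple"
        scored[g == p1 & !viol, j] <- 1L
        scored[g == p2 & !viol, j] <- 2L
      } else {
        cls[j] <- "rejected"
        reason[j] <- if (mean(nc) > sporadic_nc) "excess_nc" else "call_pattern"
      }
      next
    }
    if (xor(p1 == "AB", p2 == "AB") && (p1 %in% hom || p2 %in% hom)) {
      ab_parent <- if (p1 == "AB") 1L else 2L
      hom_parent <- 3L - ab_parent
      hc <- parents[hom_parent, j]
      viol <- !nc & !(g %in% c("AB", hc))
      if (mean(nc) <= sporadic_nc && mean(viol) <= max_violation) {
        cls[j] <- "het"
        scored[g == "AB", j] <- ab_parent
        scored[g == hc, j] <- hom_parent
      } else {
        cls[j] <- "rejected"
        reason[j] <- if (mean(nc) > sporadic_nc) "excess_nc" else "call_pattern"
      }
      next
    }
    cls[j] <- "rejected"; reason[j] <- "parent_pattern"
  }
  count_p1 <- colSums(scored == 1L, na.rm = TRUE)
  count_p2 <- colSums(scored == 2L, na.rm = TRUE)
  seg <- segregation_test(count_p1, count_p2, alpha)
  informative <- count_p1 + count_p2
  suffix <- ifelse(cls == "PA", "-PA", ifelse(cls == "het", "-het", ""))
  records <- data.frame(
    marker = ids, class = cls, reason = reason, suffix = suffix,
    name = paste0(ids, suffix),
    count_p1 = count_p1, count_p2 = count_p2,
    n_missing = n - informative,
    chi2 = seg$chi2, p = seg$p,
    pass_1to1 = seg$pass & informative >= min_informative &
      cls %in% c("simple", "het", "PA"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(records = records, scored = scored)
}

#' Bin cosegregating markers
#'
#' Markers with identical scored vectors share a bin; the bin representative
#' is the first member in genome order (anchor chromosome, then position).
#' By default missing values must match too (strict equality): treating
#' missing as a wildcard is not transitive and is therefore opt-in.
#'
#' @param scored n x m scored matrix from [classify_markers()].
#' @param anchors data frame with marker, chrom, pos for genome ordering.
#' @param wildcard_missing if TRUE, markers whose vectors agree on all
#'   jointly observed lines are merged greedily in genome order.
#' @return data frame: marker, bin (integer id), representative (logical).
#' @export
bin_cosegregating <- function(scored, anchors, wildcard_missing = FALSE) {
  ids <- colnames(scored)
  a <- anchors[match(ids, anchors$marker), ]
  ord <- order(a$chrom, a$pos)
  if (!wildcard_missing) {
    key <- apply(scored, 2, paste, collapse = ",")
    bin <- match(key, unique(key[ord]))
  } else {
    bin <- rep(NA_integer_, length(ids))
    reps <- list()
    for (j in ord) {
      placed <- FALSE
      for (b in seq_along(reps)) {
        v <- reps[[b]]; w <- scored[, j]
        obs <- !is.na(v) & !is.na(w)
        if (all(v[obs] == w[obs])) {
          bin[j] <- b
          v[is.na(v)] <- w[is.na(v)]
          reps[[b]] <- v
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        reps[[length(reps) + 1L]] <- scored[, j]
        bin[j] <- length(reps)
      }
    }
  }
  first <- !duplicated(bin[ord])
  representative <- logical(length(ids))
  representative[ord] <- first
  data.frame(marker = ids, bin = bin, representative = representative,
             stringsAsFactors = FALSE)
}
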