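stage_header <- function(stage, params = list(), seed = NULL) {
  ps <- if (length(params))
    paste(sprintf("%s=%s", names(params),
                  vapply(params, function(x) paste(format(x), collapse = ","),
                         character(1))), collapse = " ")
  else ""
  sprintf("# hexamap stage=%s %s%s", stage, ps,
          if (!is.null(seed)) sprintf(" seed=%s", seed) else "")
}

write_stage_tsv <- function(df, path, stage, params = list(), seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stage_header(stage, params, seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_stage_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a bedGraph coverage file
#'
#' Four whitespace-separated columns (chrom, start, end, depth), 0-based
#' half-open, sorted and non-overlapping within each chromosome; `track`,
#' `browser` and `#` lines are tolerated. Violations are reported with the
#' offending line number.
#'
#' @param path bedGraph file.
#' @return data frame chrom, start, end, depth.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines)))
  if (!length(keep)) stop_config("%s: no data lines", path)
  df <- read.table(text = lines[keep], col.names = c("chrom", "start", "end", "depth"),
                   colClasses = c("character", "numeric", "numeric", "numeric"))
  bad <- which(df$end <= df$start | df$depth < 0)
  if (length(bad))
    stop_config("%s: invalid interval at line %d", path, keep[bad[1]])
  for (ch in unique(df$chrom)) {
    i <- which(df$chrom == ch)
    if (is.unsorted(df$start[i]))
      stop_config("%s: unsorted intervals at line %d", path,
                  keep[i[which(diff(df$start[i]) < 0)[1] + 1L]])
    ovl <- which(df$start[i][-1] < df$end[i][-length(i)])
    if (length(ovl))
      stop_config("%s: overlapping intervals at line %d", path,
                  keep[i[ovl[1] + 1L]])
  }
  df
}

#' Write a bedGraph coverage file
#'
#' @param df data frame chrom, start, end, depth (canonical records), or a
#'   list of [coverage_track()]s (gap bins omitted).
#' @param path output file.
#' @param stage,params,seed provenance recorded in the header comment.
#' @export
write_bedgraph <- function(df, path, stage = "coverage", params = list(),
                           seed = NULL) {
  if (!is.data.frame(df)) df <- do.call(rbind, lapply(df, as_bedgraph))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stage_header(stage, params, seed), con)
  write.table(format(df, scientific = FALSE, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert a coverage track to bedGraph records
#' @param track a [coverage_track()].
#' @return data frame chrom, start, end, depth (gap bins omitted).
#' @export
as_bedgraph <- function(track) {
  i <- which(!track$gap)
  data.frame(chrom = track$chrom, start = (i - 1) * track$bin_size,
             end = i * track$bin_size, depth = track$values[i],
             stringsAsFactors = FALSE)
}

#' Write classified coverage segments (BED-style TSV)
#' @param segments classified segment data frame.
#' @param path output file.
#' @param params,seed provenance for the header.
#' @export
write_segments <- function(segments, path, params = list(), seed = NULL) {
  write_stage_tsv(segments, path, "segment", params, seed)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) read_stage_tsv(path)

#' Write / read a SNP call matrix
#'
#' TSV with one row per marker: marker, chrom, pos, P1, P2, then one column
#' per DH line, calls in AA/BB/AB/NC.
#'
#' @param calls list with `parents`, `lines`, `anchors` (as produced by
#'   [simulate_array_calls()]).
#' @param path file path.
#' @param params,seed provenance for the header.
#' @export
write_calls <- function(calls, path, params = list(), seed = NULL) {
  df <- data.frame(marker = calls$anchors$marker, chrom = calls$anchors$chrom,
                   pos = calls$anchors$pos,
                   P1 = calls$parents[1, ], P2 = calls$parents[2, ],
                   t(calls$lines), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_stage_tsv(df, path, "calls", params, seed)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  df <- read_stage_tsv(path)
  ids <- df$marker
  line_cols <- setdiff(colnames(df), c("marker", "chrom", "pos", "P1", "P2"))
  parents <- rbind(P1 = df$P1, P2 = df$P2)
  colnames(parents) <- ids
  lines <- t(as.matrix(df[, line_cols, drop = FALSE]))
  colnames(lines) <- ids
  rownames(lines) <- line_cols
  list(parents = parents, lines = lines,
       anchors = data.frame(marker = ids, chrom = df$chrom, pos = df$pos,
                            stringsAsFactors = FALSE))
}

#' Write / read a marker anchor table
#' @param anchors anchor data frame.
#' @param path file path.
#' @export
write_anchors <- function(anchors, path) write_stage_tsv(anchors, path, "anchors")

#' @rdname write_anchors
#' @export
read_anchors <- function(path) read_stage_tsv(path)

#' Write / read a homoeology block table
#' @param hom homoeology data frame (chrom_a, start_a, end_a, chrom_c,
#'   start_c, end_c) or `genome_model`.
#' @param path file path.
#' @export
write_homoeology <- function(hom, path) {
  if (inherits(hom, "genome_model")) hom <- hom$homoeology
  write_stage_tsv(hom, path, "homoeology")
}

#' @rdname write_homoeology
#' @export
read_homoeology <- function(path) read_stage_tsv(path)

#' Write / read phenotypes
#' @param phen named numeric vector or data frame (line, trait columns).
#' @param path file path.
#' @param trait trait name used when `phen` is a vector.
#' @export
write_phenotypes <- function(phen, path, trait = "trait") {
  if (!is.data.frame(phen))
    phen <- data.frame(line = names(phen) %||% seq_along(phen),
                       trait = as.numeric(phen), stringsAsFactors = FALSE,
                       check.names = FALSE)
  write_stage_tsv(phen, path, "phenotypes")
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) read_stage_tsv(path)

#' Write a BEDPE file of HE lost/gained interval pairs
#' @param events tiered event table.
#' @param path output file.
#' @export
write_bedpe <- function(events, path) {
  he <- events[events$class == "HE", , drop = FALSE]
  df <- data.frame(chrom1 = he$lost_chrom, start1 = he$lost_start,
                   end1 = he$lost_end, chrom2 = he$gained_chrom,
                   start2 = he$gained_start, end2 = he$gained_end,
                   name = he$event_id, score = 0, strand1 = ".", strand2 = ".",
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stage_header("call-he"), con)
  if (nrow(df))
    write.table(format(df, scientific = FALSE, trim = TRUE), con, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Parameter registry for every stage; defaults equal the published analysis
#' values where the protocol states them (1000-bp bins, 50-kb minimum
#' segment/merge gap, 1-SD classification, rf cut-off 0.2, marker run 3,
#' LOD threshold 5) and the toy-simulation defaults elsewhere.
#'
#' @param ... name = value overrides of top-level entries (nested lists are
#'   merged).
#' @return nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    simulate = list(n_pairs = 2, chrom_length = 2e7, bin_size = 1000,
                    n_events = 5,
                    kind_mix = c(HE = 0.5, deletion = 0.3, duplication = 0.2),
                    size_range = c(5e5, 2e6), n_lines = 164,
                    crossovers_mean = 2, marker_spacing = 5e4,
                    missing_rate = 0.02, error_rate = 0.005,
                    mean_depth = 200, dispersion = 50,
                    qtl = list(event = 1, mu = 0, a = 2, sigma = 1)),
    segment = list(bin_size = 1000, min_length = 5e4, gap_limit = 5e4,
                   mean_tol = 0.10, k_sd = 1, alpha = 0.01,
                   min_width_bins = 2, n_perm = 1000),
    classify = list(alpha = 0.05, min_informative = 20, sporadic_nc = 0.10,
                    max_violation = 0.05,
                    min_overlap = 50, min_identity = 95),
    map = list(rf_cutoff = 0.2, min_informative = 20, min_group_size = 2),
    hecall = list(min_run = 3, min_jaccard = 0.25, min_seg_length = 5e4),
    qtl = list(lod_threshold = 5, step = 1, cim = TRUE, max_cofactors = 5,
               p_enter = 0.001, window = 10)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      utils::modifyList(cfg[[nm]], dots[[nm]]) else dots[[nm]]
  }
  cfg
}

#' Read a YAML run configuration, merged onto the defaults
#' @param path YAML file.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  do.call(default_config, user)
}

#' Run the full pipeline: simulate, segment, classify, map, call-he, qtl
#'
#' Chains every stage on a simulated cross and writes all artifacts to
#' `out_dir`: coverage bedGraphs and truth for both parents, `segments.tsv`,
#' `calls.tsv`, `anchors.tsv`, `homoeology.tsv`, `markers.tsv`, `map.tsv`,
#' `events.tsv`, `events.bedpe`, `pheno.tsv`, `qtl.tsv` and a
#' `manifest.json` with the resolved configuration, seed and file
#' checksums. Deterministic given the seed. Any stage failure aborts with
#' the stage name; artifacts of completed stages are preserved.
#'
#' @param config configuration from [default_config()] /
#'   [read_run_config()].
#' @param out_dir output directory (created if needed).
#' @param seed overrides `config$seed`.
#' @return invisibly, a list with every in-memory stage result.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL) {
  seed <- seed %||% config$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config, seed = seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_config("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  res$sim <- stage("simulate", {
    sc <- config$simulate
    sim <- simulate_cross(
      n_pairs = sc$n_pairs, chrom_length = sc$chrom_length,
      bin_size = sc$bin_size, n_events = sc$n_events,
      kind_mix = unlist(sc$kind_mix), size_range = unlist(sc$size_range),
      n_lines = sc$n_lines, crossovers_mean = sc$crossovers_mean,
      marker_spacing = sc$marker_spacing, missing_rate = sc$missing_rate,
      error_rate = sc$error_rate, mean_depth = sc$mean_depth,
      dispersion = sc$dispersion, qtl = sc$qtl, seed = seed
    )
    write_calls(sim$calls, file.path(out_dir, "calls.tsv"),
                sc[c("marker_spacing", "missing_rate", "error_rate")], seed)
    write_anchors(sim$calls$anchors, file.path(out_dir, "anchors.tsv"))
    write_homoeology(sim$genome, file.path(out_dir, "homoeology.tsv"))
    for (p in names(sim$coverage))
      write_bedgraph(sim$coverage[[p]],
                     file.path(out_dir, sprintf("coverage_%s.bedgraph", p)),
                     params = list(sample = p, mean_depth = sc$mean_depth),
                     seed = seed)
    if (!is.null(sim$phenotype))
      write_phenotypes(setNames(as.numeric(sim$phenotype),
                                rownames(sim$calls$lines)),
                       file.path(out_dir, "pheno.tsv"))
    jsonlite::write_json(
      list(events = sim$events, truth = sim$calls$truth,
           carriers = sim$pop$carriers),
      file.path(out_dir, "truth.json"), dataframe = "columns", na = "null")
    sim
  })
  sim <- res$sim
  if (isTRUE(config$simulate_only)) {
    files <- list.files(out_dir, full.names = TRUE)
    jsonlite::write_json(
      list(package = "hexamap", seed = seed, config = config,
           files = data.frame(file = basename(files),
                              md5 = unname(tools::md5sum(files)),
                              stringsAsFactors = FALSE)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
    return(invisible(res))
  }
  res$segments <- stage("segment", {
    sg <- config$segment
    segs <- do.call(rbind, unlist(lapply(names(sim$coverage), function(p) {
      lapply(sim$coverage[[p]], function(tr) {
        s <- segment_coverage(tr, sg$min_length, sg$gap_limit, sg$mean_tol,
                              sg$k_sd, sg$alpha, sg$min_width_bins, sg$n_perm,
                              seed = seed + 7L)
        if (nrow(s)) s$sample <- p
        s
      })
    }), recursive = FALSE))
    rownames(segs) <- NULL
    write_segments(segs, file.path(out_dir, "segments.tsv"),
                   sg[c("min_length", "gap_limit", "k_sd", "alpha")], seed)
    segs
  })
  res$markers <- stage("classify", {
    cl <- config$classify
    anchors <- filter_anchors(sim$calls$anchors, cl$min_overlap,
                              cl$min_identity)
    mk <- classify_markers(sim$calls$parents, sim$calls$lines, cl$alpha,
                           cl$min_informative, cl$sporadic_nc,
                           cl$max_violation)
    write_stage_tsv(mk$records, file.path(out_dir, "markers.tsv"), "classify",
                    cl["alpha"], seed)
    c(mk, list(anchors = anchors))
  })
  res$map <- stage("map", {
    mp <- config$map
    map <- build_linkage_map(res$markers$records, res$markers$scored,
                             res$markers$anchors, mp$rf_cutoff,
                             mp$min_informative, mp$min_group_size)
    write_stage_tsv(as.data.frame(map), file.path(out_dir, "map.tsv"), "map",
                    mp["rf_cutoff"], seed)
    map
  })
  res$events <- stage("call-he", {
    if (is.null(sim$genome$homoeology))
      stop_config("homoeology table required to call HE events")
    hc <- config$hecall
    ev <- call_rearrangements(res$map, res$segments, sim$genome, hc$min_run,
                              hc$min_jaccard, hc$min_seg_length)
    write_stage_tsv(ev, file.path(out_dir, "events.tsv"), "call-he",
                    hc, seed)
    write_bedpe(ev, file.path(out_dir, "events.bedpe"))
    ev
  })
  if (!is.null(sim$phenotype)) {
    res$qtl <- stage("qtl", {
      q <- config$qtl
      prof <- scan_qtl(res$map, as.numeric(sim$phenotype), q$step, q$cim,
                       q$max_cofactors, q$p_enter, q$window)
      qtl <- report_qtl(prof, res$events, res$map, q$lod_threshold)
      write_stage_tsv(qtl, file.path(out_dir, "qtl.tsv"), "qtl",
                      q["lod_threshold"], seed)
      list(profiles = prof, qtl = qtl)
    })
  }
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "hexamap",
    version = as.character(utils::packageVersion("hexamap")),
    seed = seed, config = config,
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
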