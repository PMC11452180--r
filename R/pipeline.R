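#' Run the full PCCD pipeline on a cohort
#'
#' Orchestrates, for every TF of the panel: birth-order sequencing of each
#' staining specimen, the censoring-aware frequency profile, Savitzky-
#' Golay smoothing, peak detection, region partitioning and level-set
#' cluster placement; the cluster calls of all TFs are then assembled
#' into a single combinatorial code map.  Cohorts with fewer than
#' `min_specimens` specimens for a TF trigger a warning (profiles are
#' noisy below the usual N > 15 staining practice) but the run continues.
#'
#' @param input a [SpecimenSet-class], or a path to a cell table readable
#'   by [loadSpecimens()].
#' @param config configuration list from [pccdConfig()].
#' @param out_dir optional output directory; when given, writes per-TF
#'   profile TSVs, ordered-sequence TSVs, the code-map TSV + JSON report,
#'   a YAML echo of all parameters, and a plain-text run log.  Outputs
#'   are deterministic functions of (input, config).
#' @param condition condition label for the code map; default: the most
#'   frequent specimen genotype.
#' @return a [PCCDResult-class].
#' @export
runPCCD <- function(input, config = pccdConfig(), out_dir = NULL,
                    condition = NULL) {
  set <- if (is(input, "SpecimenSet")) input else loadSpecimens(input)
  panel <- stainedTFs(set)
  tfs <- config$tfs %||% panel
  missing_tfs <- setdiff(tfs, panel)
  if (length(missing_tfs)) {
    stop("requested TF(s) not stained in any specimen: ",
         paste(missing_tfs, collapse = ", "))
  }
  if (is.null(condition)) {
    gts <- vapply(specimens(set), genotype, character(1))
    condition <- names(sort(table(gts), decreasing = TRUE))[1L]
  }
  counts <- tfStainCounts(set)
  log <- c(sprintf("cohort: %d specimen(s), condition '%s'", length(set), condition),
           sprintf("parameters: window=%d polyorder=%d edge=%s | h_min=%g d_min=%g p_min=%g | mode=%s | max_birth_order=%d",
                   config$smoothing@window, config$smoothing@polyorder,
                   config$smoothing@edgeMode, config$peaks@hMin,
                   config$peaks@dMin, config$peaks@pMin, config$mode,
                   config$max_birth_order))
  profiles <- list()
  peaks <- list()
  clusters <- list()
  all_calls <- list()
  seq_tables <- list()
  for (tf in tfs) {
    if (counts[[tf]] < config$min_specimens) {
      warning(sprintf("only %d specimen(s) stain %s; cohorts of N > 15 are the usual practice for stable profiles",
                      counts[[tf]], tf))
    }
    seqs <- orderSequences(set, tf)
    seqs <- Filter(function(s) length(s@calls) > 0L, seqs)
    if (!length(seqs)) {
      log <- c(log, sprintf("%s: no non-empty sequences; skipped", tf))
      next
    }
    calls <- detectClusters(seqs, smoothing = config$smoothing,
                            peaks_cfg = config$peaks, mode = config$mode)
    prof <- attr(calls, "profile")
    pk <- attr(calls, "peaks")
    profiles[[tf]] <- prof
    peaks[[tf]] <- pk
    clusters[[tf]] <- calls
    all_calls <- c(all_calls, calls)
    seq_tables[[tf]] <- sequenceTable(seqs)
    ns <- vapply(calls, function(cl) cl@n, numeric(1))
    log <- c(log, sprintf("%s: N=%d, L_max=%d, %d peak(s)%s", tf,
                          length(seqs), length(prof@f), nrow(pk),
                          if (length(ns)) paste0(", n=", paste(sprintf("%.3f", ns),
                                                               collapse = "/"))
                          else ", no cluster"))
  }
  code_map <- assembleCodeMap(all_calls, max_birth_order = config$max_birth_order,
                              condition = condition, tfs = names(profiles))
  result <- new("PCCDResult", profiles = profiles, peaks = peaks,
                clusters = clusters, codeMap = code_map,
                params = configAsList(config), log = log)
  if (!is.null(out_dir)) writeResultBundle(result, seq_tables, out_dir)
  result
}

#' Write a PCCDResult as a report bundle
#'
#' @param result a [PCCDResult-class].
#' @param seq_tables optional named list of sequence tables (written when
#'   provided, as by [runPCCD()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeResultBundle <- function(result, seq_tables = NULL, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (tf in names(result@profiles)) {
    utils::write.table(profileTable(result@profiles[[tf]]),
                       file.path(out_dir, paste0("profile_", tf, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(seq_tables[[tf]])) {
      utils::write.table(seq_tables[[tf]],
                         file.path(out_dir, paste0("sequences_", tf, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  writeCodeMap(result@codeMap, file.path(out_dir, "codemap.tsv"),
               file.path(out_dir, "codemap_report.json"))
  yaml::write_yaml(result@params, file.path(out_dir, "params.yaml"))
  writeLines(result@log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Reconstruct a TFCodeMap from a written JSON report
#'
#' @param path a `codemap_report.json` written by [writeCodeMap()] /
#'   [runPCCD()].
#' @return a [TFCodeMap-class] equivalent to the one that was written.
#' @export
codeMapFromReport <- function(path) {
  rep <- readCodeMapReport(path)
  calls <- lapply(rep$clusters, function(cl) {
    cov <- unlist(cl$coverage)
    new("ClusterCall", tf = cl$tf,
        peak = data.frame(position = cl$peak$position, height = cl$peak$height,
                          prominence = cl$peak$prominence,
                          region_start = cl$peak$region[[1L]],
                          region_end = cl$peak$region[[2L]]),
        n = cl$n, bounds = as.numeric(unlist(cl$bounds)),
        coreSpan = as.integer(unlist(cl$core_span)),
        coverage = stats::setNames(as.numeric(cov), names(cov)))
  })
  assembleCodeMap(calls, max_birth_order = rep$max_birth_order,
                  condition = rep$condition, tfs = unlist(rep$tfs))
}

#' Compare two completed pipeline runs
#'
#' Reads the code-map reports of two output bundles and delegates to
#' [compareCodeMaps()]; a warning is emitted when the two runs used
#' different parameters (the comparison is still returned).
#'
#' @param dir_a,dir_b output directories written by [runPCCD()].
#' @return a `pccdShift` report (see [compareCodeMaps()]).
#' @export
comparePCCDRuns <- function(dir_a, dir_b) {
  map_a <- codeMapFromReport(file.path(dir_a, "codemap_report.json"))
  map_b <- codeMapFromReport(file.path(dir_b, "codemap_report.json"))
  pa <- file.path(dir_a, "params.yaml")
  pb <- file.path(dir_b, "params.yaml")
  if (file.exists(pa) && file.exists(pb) &&
      !identical(yaml::read_yaml(pa), yaml::read_yaml(pb))) {
    warning("runs used different parameters; comparison emitted anyway")
  }
  compareCodeMaps(map_a, map_b)
}
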