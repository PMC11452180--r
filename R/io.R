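## Readers and writers for the package's plain-text interchange formats.
##
## Canonical cell table: long format, one row per cell per assessed TF
## (cells without any call get a single row with an empty tf field):
##   specimen_id  cell_id  class  x_um  y_um  z_um  tf  call
## Calls are serialized as {0, 1}; an empty call cell means "assessed but
## missing" -- a TF with no rows at all in a specimen was not stained
## there, which is a different state from "negative".  Wide format (one
## 0/1/empty column per TF) is accepted on input only.
##
## Per-specimen metadata (genotype, stage, reference cell, stained panel)
## travels in a JSON sidecar so that unequal TF panels and non-NB
## references survive a round-trip.

.coord_fmt <- function(x) sprintf("%.17g", x)  # lossless double round-trip

.read_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""), colClasses = "character")
}

.parse_coords <- function(tab, path) {
  for (col in c("x_um", "y_um", "z_um")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric coordinate '%s' in column %s, row %d of %s",
                   tab[[col]][bad[1L]], col, bad[1L] + 1L, path))
    }
    if (anyNA(v)) {
      stop(sprintf("missing coordinate in column %s, row %d of %s",
                   col, which(is.na(v))[1L] + 1L, path))
    }
    tab[[col]] <- v
  }
  tab
}

.parse_call <- function(v, path) {
  out <- rep(NA, length(v))
  out[v %in% c("1", "TRUE", "true")] <- TRUE
  out[v %in% c("0", "FALSE", "false")] <- FALSE
  bad <- !is.na(v) & is.na(out)
  if (any(bad)) {
    stop(sprintf("uninterpretable call value '%s' in %s (expected 0/1/empty)",
                 v[bad][1L], path))
  }
  out
}

.specimen_from_long <- function(sub, sp_id, meta, path) {
  has_tf <- !is.na(sub$tf)
  # a cell may legitimately appear once per assessed TF; the same
  # (cell, tf) pair twice is a duplicate
  pair <- paste0(sub$cell_id, "\r", sub$tf)
  if (anyDuplicated(pair)) {
    stop(sprintf("duplicate cell_id %s in %s",
                 sub$cell_id[duplicated(pair)][1L], sp_id))
  }
  key <- paste(sub$class, .coord_fmt(sub$x_um), .coord_fmt(sub$y_um),
               .coord_fmt(sub$z_um))
  nkey <- tapply(key, sub$cell_id, function(k) length(unique(k)))
  if (any(nkey > 1L)) {
    stop(sprintf("conflicting class/coordinates for cell_id %s in %s",
                 names(nkey)[nkey > 1L][1L], sp_id))
  }
  cells <- sub[!duplicated(sub$cell_id),
               c("cell_id", "class", "x_um", "y_um", "z_um")]
  names(cells)[2L] <- "cell_class"
  tfs <- unique(sub$tf[has_tf])
  if (!is.null(meta$stained_tfs)) {
    extra <- setdiff(tfs, meta$stained_tfs)
    if (length(extra)) {
      stop(sprintf("specimen %s has calls for TFs outside its declared panel: %s",
                   sp_id, paste(extra, collapse = ", ")))
    }
    tfs <- as.character(meta$stained_tfs)
  }
  calls <- matrix(NA, nrow(cells), length(tfs),
                  dimnames = list(cells$cell_id, tfs))
  for (i in which(has_tf)) {
    calls[sub$cell_id[i], sub$tf[i]] <- sub$call_parsed[i]
  }
  Specimen(sp_id, cells, calls,
           reference_cell_id = meta$reference_cell_id,
           genotype = meta$genotype %||% "unknown",
           stage = meta$stage %||% "unknown")
}

.specimen_from_wide <- function(sub, sp_id, meta, tf_cols, path) {
  if (anyDuplicated(sub$cell_id)) {
    stop(sprintf("duplicate cell_id %s in %s",
                 sub$cell_id[duplicated(sub$cell_id)][1L], sp_id))
  }
  cells <- sub[, c("cell_id", "class", "x_um", "y_um", "z_um")]
  names(cells)[2L] <- "cell_class"
  # a TF column that is entirely empty for this specimen was not stained
  stained <- tf_cols[vapply(tf_cols, function(tf) any(!is.na(sub[[tf]])),
                            logical(1))]
  if (!is.null(meta$stained_tfs)) stained <- as.character(meta$stained_tfs)
  calls <- matrix(NA, nrow(cells), length(stained),
                  dimnames = list(cells$cell_id, stained))
  for (tf in stained) calls[, tf] <- .parse_call(sub[[tf]], path)
  Specimen(sp_id, cells, calls,
           reference_cell_id = meta$reference_cell_id,
           genotype = meta$genotype %||% "unknown",
           stage = meta$stage %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a cohort of specimens from a cell table
#'
#' @param path TSV/CSV cell table, long format (columns `specimen_id`,
#'   `cell_id`, `class`, `x_um`, `y_um`, `z_um`, `tf`, `call`) or wide
#'   format (one 0/1/empty column per TF instead of `tf`/`call`).
#' @param metadata per-specimen metadata: a list keyed by specimen id
#'   (fields `genotype`, `stage`, `reference_cell_id`, `stained_tfs`), a
#'   path to such a JSON file, or `NULL`.  When `NULL`, a sidecar
#'   `<path-without-extension>_meta.json` is read if present; otherwise
#'   the reference defaults to the NB-class cell.
#' @param format `"auto"` (default), `"long"` or `"wide"`.
#' @param sep field separator; default by file extension (`,` for `.csv`,
#'   tab otherwise).
#' @return a [SpecimenSet-class]; TFs absent from a specimen's table/panel
#'   are recorded as not stained, never as negative.
#' @export
loadSpecimens <- function(path, metadata = NULL,
                          format = c("auto", "long", "wide"), sep = NULL) {
  format <- match.arg(format)
  tab <- .read_table(path, sep)
  need <- c("specimen_id", "cell_id", "class", "x_um", "y_um", "z_um")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("cell table lacks required column(s): ", paste(miss, collapse = ", "))
  }
  tab <- .parse_coords(tab, path)
  if (format == "auto") {
    format <- if (all(c("tf", "call") %in% names(tab))) "long" else "wide"
  }
  meta_all <- list()
  if (is.null(metadata)) {
    sidecar <- paste0(tools::file_path_sans_ext(path), "_meta.json")
    if (file.exists(sidecar)) metadata <- sidecar
  }
  if (is.character(metadata)) {
    meta_all <- jsonlite::read_json(metadata, simplifyVector = TRUE,
                                    simplifyDataFrame = FALSE,
                                    simplifyMatrix = FALSE)
  } else if (is.list(metadata)) {
    meta_all <- metadata
  }
  provenance <- meta_all$provenance %||% list(source = path)
  meta_specimens <- meta_all$specimens %||%
    meta_all[setdiff(names(meta_all), "provenance")]

  if (format == "long") {
    if (!all(c("tf", "call") %in% names(tab))) {
      stop("long format requires 'tf' and 'call' columns")
    }
    tab$call_parsed <- .parse_call(tab$call, path)
  }
  tf_cols <- setdiff(names(tab), c(need, "tf", "call", "call_parsed"))
  sp_ids <- unique(tab$specimen_id)
  specimens <- lapply(sp_ids, function(sp_id) {
    sub <- tab[tab$specimen_id == sp_id, , drop = FALSE]
    meta <- meta_specimens[[sp_id]] %||% list()
    if (format == "long") .specimen_from_long(sub, sp_id, meta, path)
    else .specimen_from_wide(sub, sp_id, meta, tf_cols, path)
  })
  SpecimenSet(specimens, provenance = provenance)
}

#' Write a cohort to the canonical long cell table (+ metadata JSON)
#'
#' @param set a [SpecimenSet-class].
#' @param path output TSV path.
#' @param metadata_path output JSON path for per-specimen metadata;
#'   default: sidecar `<path-without-extension>_meta.json`, which
#'   [loadSpecimens()] picks up automatically, making the round-trip
#'   loss-free.
#' @return invisibly, the two paths written.
#' @export
writeSpecimens <- function(set, path,
                           metadata_path = paste0(tools::file_path_sans_ext(path),
                                                  "_meta.json")) {
  stopifnot(is(set, "SpecimenSet"))
  rows <- lapply(set@specimens, function(s) {
    cells <- s@cells
    tfs <- stainedTFs(s)
    base <- data.frame(specimen_id = s@specimenId, cell_id = cells$cell_id,
                       class = cells$cell_class,
                       x_um = .coord_fmt(cells$x_um),
                       y_um = .coord_fmt(cells$y_um),
                       z_um = .coord_fmt(cells$z_um),
                       stringsAsFactors = FALSE)
    if (!length(tfs)) {
      base$tf <- NA_character_
      base$call <- NA_character_
      return(base)
    }
    do.call(rbind, lapply(tfs, function(tf) {
      out <- base
      out$tf <- tf
      out$call <- ifelse(is.na(s@calls[, tf]), NA_character_,
                         as.character(as.integer(s@calls[, tf])))
      out
    }))
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  meta <- list(
    provenance = set@provenance,
    specimens = lapply(set@specimens, function(s) {
      list(genotype = s@genotype, stage = s@stage,
           reference_cell_id = s@referenceCellId,
           stained_tfs = as.list(stainedTFs(s)))
    })
  )
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(table = path, metadata = metadata_path))
}

.codemap_report <- function(map) {
  list(
    condition = map@condition,
    max_birth_order = map@maxBirthOrder,
    tfs = as.list(colnames(map@membership)),
    clusters = lapply(map@calls, function(cl) {
      list(
        tf = cl@tf,
        n = cl@n,
        peak = list(position = cl@peak$position, height = cl@peak$height,
                    prominence = cl@peak$prominence,
                    region = c(cl@peak$region_start, cl@peak$region_end)),
        bounds = cl@bounds,
        core_span = cl@coreSpan,
        coverage = as.list(stats::setNames(as.numeric(cl@coverage),
                                           names(cl@coverage)))
      )
    })
  )
}

#' Write a TF code map as a rank x TF table plus a JSON report
#'
#' @param map a [TFCodeMap-class].
#' @param path output TSV path: columns `rank`, `supernumerary` (0/1) and
#'   one coverage column per TF; annex ranks are appended after the main
#'   axis.
#' @param report_path output JSON path with the structured cluster report
#'   (calls, n values, peaks, coverage indices); default sidecar
#'   `<path-without-extension>_report.json`.
#' @return invisibly, the paths written.
#' @export
writeCodeMap <- function(map, path,
                         report_path = paste0(tools::file_path_sans_ext(path),
                                              "_report.json")) {
  stopifnot(is(map, "TFCodeMap"))
  full <- rbind(map@membership, map@annex)
  tab <- data.frame(rank = as.integer(rownames(full)),
                    supernumerary = as.integer(as.integer(rownames(full)) >
                                               map@maxBirthOrder))
  for (tf in colnames(full)) tab[[tf]] <- full[, tf]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(.codemap_report(map), report_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(table = path, report = report_path))
}

#' Read back a code-map JSON report
#'
#' @param path JSON report written by [writeCodeMap()].
#' @return the report as a list (same structure as the in-memory report).
#' @export
readCodeMapReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}
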