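#' Construct a Specimen
#'
#' @param specimen_id unique specimen identifier.
#' @param cells `data.frame` with columns `cell_id`, `cell_class`, `x_um`,
#'   `y_um`, `z_um`.
#' @param calls logical matrix of TF calls (rows = cells, columns = stained
#'   TFs, `NA` = not assessed), or `NULL` for an unstained specimen.
#' @param reference_cell_id id of the spatial reference cell; defaults to
#'   the NB-class cell when exactly one is present.
#' @param genotype,stage free-text labels.
#' @return a validated [Specimen-class].
#' @examples
#' cells <- data.frame(cell_id = c("nb", "m1"), cell_class = c("NB", "MN"),
#'                     x_um = c(0, 3), y_um = c(0, 4), z_um = c(0, 0))
#' calls <- matrix(TRUE, 2, 1, dimnames = list(cells$cell_id, "Jim"))
#' Specimen("S1", cells, calls)
#' @export
Specimen <- function(specimen_id, cells, calls = NULL,
                     reference_cell_id = NULL,
                     genotype = "unknown", stage = "unknown") {
  cells <- as.data.frame(cells)
  rownames(cells) <- NULL
  cells$cell_id <- as.character(cells$cell_id)
  cells$cell_class <- as.character(cells$cell_class)
  if (is.null(calls)) {
    calls <- matrix(logical(0), nrow = nrow(cells), ncol = 0L,
                    dimnames = list(cells$cell_id, NULL))
  }
  if (is.null(colnames(calls)) && ncol(calls) > 0L) {
    stop("calls matrix must have TF names as colnames")
  }
  storage.mode(calls) <- "logical"
  rownames(calls) <- cells$cell_id
  if (is.null(reference_cell_id)) {
    nb <- cells$cell_id[cells$cell_class == "NB"]
    if (length(nb) != 1L) {
      stop("no NB cell to use as reference in specimen '", specimen_id,
           "': supply reference_cell_id (e.g. a ventrally located cell)")
    }
    reference_cell_id <- nb
  }
  new("Specimen", specimenId = as.character(specimen_id),
      genotype = genotype, stage = stage, cells = cells, calls = calls,
      referenceCellId = as.character(reference_cell_id))
}

#' Construct a SpecimenSet
#'
#' @param specimens list of [Specimen-class] objects.
#' @param provenance list of metadata to carry into reports.
#' @return a validated [SpecimenSet-class].
#' @export
SpecimenSet <- function(specimens = list(), provenance = list()) {
  names(specimens) <- vapply(specimens, function(s) s@specimenId, character(1))
  new("SpecimenSet", specimens = specimens, provenance = provenance)
}

#' Savitzky-Golay configuration
#'
#' Defaults are the pipeline's reference parameters: window 11, polynomial
#' order 3.
#'
#' @param window odd positive integer.
#' @param polyorder non-negative integer `< window`.
#' @param edge_mode `"polynomial_interp"` or `"mirror"`; see
#'   [SmoothingConfig-class].
#' @return a [SmoothingConfig-class].
#' @export
smoothingConfig <- function(window = 11L, polyorder = 3L,
                            edge_mode = c("polynomial_interp", "mirror")) {
  new("SmoothingConfig", window = as.integer(window),
      polyorder = as.integer(polyorder), edgeMode = match.arg(edge_mode))
}

#' Peak-detection configuration
#'
#' Defaults are the pipeline's reference parameters: minimal height 0.2,
#' minimal inter-peak distance 8 ranks, minimal prominence 0.07.
#'
#' @param h_min minimal height (frequency).
#' @param d_min minimal rank distance between retained peaks.
#' @param p_min minimal prominence (frequency).
#' @return a [PeakConfig-class].
#' @export
peakConfig <- function(h_min = 0.2, d_min = 8, p_min = 0.07) {
  new("PeakConfig", hMin = h_min, dMin = d_min, pMin = p_min)
}
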