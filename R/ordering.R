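#' @describeIn normalizeToReference translate so the reference cell is at
#'   the origin.
#' @export
setMethod("normalizeToReference", "Specimen", function(specimen) {
  cells <- specimen@cells
  ref <- which(cells$cell_id == specimen@referenceCellId)
  if (length(ref) != 1L) {
    stop("reference cell '", specimen@referenceCellId, "' not found in specimen '",
         specimen@specimenId,
         "'; designate a ventrally located cell as reference_cell_id")
  }
  origin <- as.numeric(cells[ref, c("x_um", "y_um", "z_um")])
  cells$x_um <- cells$x_um - origin[1L]
  cells$y_um <- cells$y_um - origin[2L]
  cells$z_um <- cells$z_um - origin[3L]
  specimen@cells <- cells
  specimen
})

#' @describeIn distanceToReference distances of all (or selected) cells.
#' @export
setMethod("distanceToReference", "Specimen", function(specimen, cell_ids = NULL) {
  cells <- specimen@cells
  ref <- which(cells$cell_id == specimen@referenceCellId)
  if (length(ref) != 1L) {
    stop("reference cell '", specimen@referenceCellId, "' not found in specimen '",
         specimen@specimenId, "'")
  }
  dx <- cells$x_um - cells$x_um[ref]
  dy <- cells$y_um - cells$y_um[ref]
  dz <- cells$z_um - cells$z_um[ref]
  d <- sqrt(dx^2 + dy^2 + dz^2)
  names(d) <- cells$cell_id
  if (!is.null(cell_ids)) d <- d[as.character(cell_ids)]
  d
})

#' @describeIn orderSequence sort MN-class cells by descending distance
#'   from the reference.
#' @export
setMethod("orderSequence", "Specimen",
          function(specimen, tf, include_apoptotic = FALSE) {
  if (!tf %in% stainedTFs(specimen)) {
    stop("TF '", tf, "' was not stained in specimen '", specimen@specimenId, "'")
  }
  cells <- specimen@cells
  keep_class <- if (include_apoptotic) c("MN", "apoptotic") else "MN"
  eligible <- cells$cell_class %in% keep_class & !is.na(specimen@calls[, tf])
  if (!any(eligible)) {
    warning("no eligible cells for TF '", tf, "' in specimen '",
            specimen@specimenId, "'; returning an empty sequence")
    return(new("OrderedSequence", specimenId = specimen@specimenId, tf = tf,
               calls = logical(0), distances = numeric(0), cellIds = character(0)))
  }
  d <- distanceToReference(specimen)[eligible]
  ids <- cells$cell_id[eligible]
  # stable sort on (-distance, cell_id): rank 1 = furthest = oldest
  ord <- order(-d, ids)
  new("OrderedSequence",
      specimenId = specimen@specimenId, tf = tf,
      calls = unname(specimen@calls[eligible, tf][ord]),
      distances = unname(d[ord]),
      cellIds = ids[ord])
})

#' Build birth-order sequences for one TF across a cohort
#'
#' Applies [orderSequence()] to every specimen of the set that stained
#' `tf`, skipping (with a message in the result's attributes) specimens
#' that did not.
#'
#' @param set a [SpecimenSet-class].
#' @param tf TF name.
#' @param include_apoptotic passed to [orderSequence()].
#' @return list of [OrderedSequence-class], one per staining specimen.
#' @export
orderSequences <- function(set, tf, include_apoptotic = FALSE) {
  stopifnot(is(set, "SpecimenSet"))
  staining <- Filter(function(s) tf %in% stainedTFs(s), set@specimens)
  lapply(staining, orderSequence, tf = tf, include_apoptotic = include_apoptotic)
}

#' Export ordered sequences as a long table
#'
#' @param sequences list of [OrderedSequence-class].
#' @return `data.frame` with columns `specimen_id`, `tf`, `rank`, `cell_id`,
#'   `call`, `distance_um`.
#' @export
sequenceTable <- function(sequences) {
  do.call(rbind, c(list(
    data.frame(specimen_id = character(0), tf = character(0), rank = integer(0),
               cell_id = character(0), call = integer(0), distance_um = numeric(0))),
    lapply(sequences, function(s) {
      L <- length(s@calls)
      if (!L) return(NULL)
      data.frame(specimen_id = s@specimenId, tf = s@tf, rank = seq_len(L),
                 cell_id = s@cellIds, call = as.integer(s@calls),
                 distance_um = s@distances)
    })))
}
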