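#' @rdname Specimen-accessors
#' @export
setGeneric("specimenId", function(x) standardGeneric("specimenId"))

#' @rdname Specimen-accessors
#' @export
setGeneric("genotype", function(x) standardGeneric("genotype"))

#' @rdname Specimen-accessors
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))

#' @rdname Specimen-accessors
#' @export
setGeneric("cellTable", function(x) standardGeneric("cellTable"))

#' @rdname Specimen-accessors
#' @export
setGeneric("tfCalls", function(x) standardGeneric("tfCalls"))

#' @rdname Specimen-accessors
#' @export
setGeneric("stainedTFs", function(x) standardGeneric("stainedTFs"))

#' @rdname Specimen-accessors
#' @export
setGeneric("referenceCellId", function(x) standardGeneric("referenceCellId"))

#' @rdname SpecimenSet-accessors
#' @export
setGeneric("specimens", function(x) standardGeneric("specimens"))

#' @rdname SpecimenSet-accessors
#' @export
setGeneric("specimenIds", function(x) standardGeneric("specimenIds"))

#' @rdname SpecimenSet-accessors
#' @export
setGeneric("tfStainCounts", function(x) standardGeneric("tfStainCounts"))

#' @rdname FrequencyProfile-accessors
#' @export
setGeneric("frequencies", function(x, smoothed = FALSE) standardGeneric("frequencies"))

#' @rdname FrequencyProfile-accessors
#' @export
setGeneric("positives", function(x) standardGeneric("positives"))

#' @rdname FrequencyProfile-accessors
#' @export
setGeneric("atRisk", function(x) standardGeneric("atRisk"))

#' @rdname TFCodeMap-accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname TFCodeMap-accessors
#' @export
setGeneric("annex", function(x) standardGeneric("annex"))

#' @rdname TFCodeMap-accessors
#' @export
setGeneric("clusterCalls", function(x) standardGeneric("clusterCalls"))

#' Normalize a specimen's coordinates to its reference cell
#'
#' Translates all cell coordinates so that the reference cell (the
#' neuroblast when present) sits at the origin `(0, 0, 0)`.  A pure
#' translation: classes, calls and all inter-cell distances are unchanged.
#'
#' @param specimen a [Specimen-class].
#' @return the translated [Specimen-class].
#' @export
setGeneric("normalizeToReference", function(specimen) standardGeneric("normalizeToReference"))

#' Euclidean distance of each cell from the reference cell
#'
#' @param specimen a [Specimen-class].
#' @param cell_ids optional character vector restricting the result.
#' @return named numeric vector of distances in µm (translation-invariant:
#'   the specimen need not be normalized first).
#' @export
setGeneric("distanceToReference",
           function(specimen, cell_ids = NULL) standardGeneric("distanceToReference"))

#' Order a specimen's motoneurons into a birth-order sequence for one TF
#'
#' Motoneuron-class cells with a non-missing call for `tf` are sorted by
#' descending distance from the reference cell: rank 1 is the furthest
#' cell, i.e. the oldest (first-born) on average.  Ties in distance are
#' broken by ascending `cell_id`, then input order, so the ranking is
#' deterministic.
#'
#' @param specimen a [Specimen-class].
#' @param tf TF name; must be in the specimen's stained set.
#' @param include_apoptotic include cells of class `apoptotic`
#'   (default `FALSE`).
#' @return an [OrderedSequence-class]; empty (length 0) with a warning if
#'   no cell is eligible.
#' @export
setGeneric("orderSequence",
           function(specimen, tf, include_apoptotic = FALSE) standardGeneric("orderSequence"))

#' @rdname census
#' @export
setGeneric("census", function(x) standardGeneric("census"))
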