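#' Accessors for Specimen objects
#'
#' @param x a [Specimen-class].
#' @return `specimenId`, `genotype`, `stage`, `referenceCellId`: a single
#'   character.  `cellTable`: the cell `data.frame`.  `tfCalls`: the
#'   logical call matrix (cells x stained TFs).  `stainedTFs`: character
#'   vector of TF names stained in this specimen.
#' @name Specimen-accessors
NULL

#' @rdname Specimen-accessors
#' @export
setMethod("specimenId", "Specimen", function(x) x@specimenId)

#' @rdname Specimen-accessors
#' @export
setMethod("genotype", "Specimen", function(x) x@genotype)

#' @rdname Specimen-accessors
#' @export
setMethod("stage", "Specimen", function(x) x@stage)

#' @rdname Specimen-accessors
#' @export
setMethod("cellTable", "Specimen", function(x) x@cells)

#' @rdname Specimen-accessors
#' @export
setMethod("tfCalls", "Specimen", function(x) x@calls)

#' @rdname Specimen-accessors
#' @export
setMethod("stainedTFs", "Specimen", function(x) colnames(x@calls))

#' @rdname Specimen-accessors
#' @export
setMethod("referenceCellId", "Specimen", function(x) x@referenceCellId)

#' Accessors for SpecimenSet objects
#'
#' @param x a [SpecimenSet-class].
#' @return `specimens`: the list of [Specimen-class]s.  `specimenIds`:
#'   character vector of ids.  `stainedTFs`: union of TF panels.
#'   `tfStainCounts`: named integer vector, per TF the number of
#'   specimens staining it (the cohort N reported alongside profiles).
#' @name SpecimenSet-accessors
NULL

#' @rdname SpecimenSet-accessors
#' @export
setMethod("specimens", "SpecimenSet", function(x) x@specimens)

#' @rdname SpecimenSet-accessors
#' @export
setMethod("specimenIds", "SpecimenSet",
          function(x) vapply(x@specimens, specimenId, character(1), USE.NAMES = FALSE))

#' @rdname SpecimenSet-accessors
#' @export
setMethod("stainedTFs", "SpecimenSet", function(x) {
  sort(unique(unlist(lapply(x@specimens, stainedTFs))))
})

#' @rdname SpecimenSet-accessors
#' @export
setMethod("tfStainCounts", "SpecimenSet", function(x) {
  tfs <- stainedTFs(x)
  counts <- vapply(tfs, function(tf) {
    sum(vapply(x@specimens, function(s) tf %in% stainedTFs(s), logical(1)))
  }, integer(1))
  counts
})

#' @rdname SpecimenSet-accessors
#' @export
setMethod("length", "SpecimenSet", function(x) length(x@specimens))

#' @rdname SpecimenSet-accessors
#' @param i index or specimen id.
#' @export
setMethod("[[", "SpecimenSet", function(x, i) x@specimens[[i]])

#' @rdname SpecimenSet-accessors
#' @export
setMethod("names", "SpecimenSet", function(x) specimenIds(x))

#' Accessors for FrequencyProfile objects
#'
#' @param x a [FrequencyProfile-class].
#' @param smoothed if `TRUE` return the smoothed frequency (error if the
#'   profile has not been smoothed yet).
#' @return `frequencies`: numeric vector indexed by rank.  `positives`:
#'   integer vector of per-rank positive counts.  `atRisk`: integer vector
#'   of per-rank at-risk sequence counts.
#' @name FrequencyProfile-accessors
NULL

#' @rdname FrequencyProfile-accessors
#' @export
setMethod("frequencies", "FrequencyProfile", function(x, smoothed = FALSE) {
  if (smoothed) {
    if (!length(x@fSmooth)) stop("profile has not been smoothed; run smoothProfile()")
    x@fSmooth
  } else x@f
})

#' @rdname FrequencyProfile-accessors
#' @export
setMethod("positives", "FrequencyProfile", function(x) x@P)

#' @rdname FrequencyProfile-accessors
#' @export
setMethod("atRisk", "FrequencyProfile", function(x) x@Nseq)

#' @rdname FrequencyProfile-accessors
#' @export
setMethod("length", "FrequencyProfile", function(x) length(x@f))

#' Accessors for TFCodeMap objects
#'
#' @param x a [TFCodeMap-class].
#' @return `membership`: the rank x TF coverage matrix (main axis).
#'   `annex`: the supernumerary-rank matrix.  `clusterCalls`: list of
#'   [ClusterCall-class]s.
#' @name TFCodeMap-accessors
NULL

#' @rdname TFCodeMap-accessors
#' @export
setMethod("membership", "TFCodeMap", function(x) x@membership)

#' @rdname TFCodeMap-accessors
#' @export
setMethod("annex", "TFCodeMap", function(x) x@annex)

#' @rdname TFCodeMap-accessors
#' @export
setMethod("clusterCalls", "TFCodeMap", function(x) x@calls)
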