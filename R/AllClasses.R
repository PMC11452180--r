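#' @import methods
NULL

.CELL_CLASSES <- c("NB", "GMC", "MN", "glia", "apoptotic", "other")

#' Specimen: one imaged lineage
#'
#' A `Specimen` holds the segmented, annotated cells of a single lineage
#' (one animal / one hemisegment): per-cell 3D coordinates in micrometres,
#' a cell-class label, and binary expression calls for the transcription
#' factors (TFs) that were stained in this specimen.  Calls are stored as a
#' logical matrix with one row per cell and one column per stained TF;
#' `NA` means the cell was not assessed for that TF.  TFs that were never
#' stained in a specimen have no column at all — absence of a column and
#' `FALSE` are deliberately distinct states.
#'
#' @slot specimenId single character identifier, unique within a set.
#' @slot genotype free-text genotype/condition label (e.g. `"control"`).
#' @slot stage free-text developmental stage label (e.g. `"L3"`).
#' @slot cells `data.frame` with columns `cell_id`, `cell_class`
#'   (one of NB, GMC, MN, glia, apoptotic, other), `x_um`, `y_um`, `z_um`.
#' @slot calls logical matrix, `nrow(cells)` rows (rownames = `cell_id`),
#'   one column per stained TF.
#' @slot referenceCellId id of the cell used as the spatial origin: the
#'   neuroblast when present, otherwise a designated ventral reference.
#'
#' @seealso [loadSpecimens()], [normalizeToReference()], [orderSequence()]
#' @export
setClass("Specimen",
  representation(
    specimenId = "character",
    genotype = "character",
    stage = "character",
    cells = "data.frame",
    calls = "matrix",
    referenceCellId = "character"
  )
)

setValidity("Specimen", function(object) {
  msg <- character(0)
  cells <- object@cells
  need <- c("cell_id", "cell_class", "x_um", "y_um", "z_um")
  if (!all(need %in% names(cells))) {
    return(paste("cells must have columns", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(cells$cell_id)) {
    dup <- cells$cell_id[duplicated(cells$cell_id)][1L]
    msg <- c(msg, sprintf("duplicate cell_id %s in %s", dup, object@specimenId))
  }
  bad <- setdiff(unique(cells$cell_class), .CELL_CLASSES)
  if (length(bad)) {
    msg <- c(msg, sprintf("unknown cell class label(s): %s",
                          paste(bad, collapse = ", ")))
  }
  xyz <- as.matrix(cells[, c("x_um", "y_um", "z_um")])
  if (!is.numeric(xyz) || any(!is.finite(xyz))) {
    msg <- c(msg, "coordinates must be finite numbers")
  }
  if (sum(cells$cell_class == "NB") > 1L) {
    msg <- c(msg, sprintf("specimen %s has more than one NB", object@specimenId))
  }
  if (length(object@referenceCellId) != 1L ||
      sum(cells$cell_id == object@referenceCellId) != 1L) {
    msg <- c(msg, sprintf("reference cell '%s' does not resolve to exactly one cell in %s",
                          object@referenceCellId[1L], object@specimenId))
  }
  if (nrow(object@calls) > 0L || ncol(object@calls) > 0L) {
    if (nrow(object@calls) != nrow(cells)) {
      msg <- c(msg, "calls must have one row per cell")
    } else if (!identical(rownames(object@calls), as.character(cells$cell_id))) {
      msg <- c(msg, "rownames(calls) must equal cells$cell_id")
    }
    if (!is.logical(object@calls)) msg <- c(msg, "calls must be a logical matrix")
  }
  if (length(msg)) msg else TRUE
})

#' SpecimenSet: a cohort of specimens
#'
#' Ordered container of [Specimen-class] objects with free-form provenance
#' metadata (generator configuration, file of origin, ...).  Specimen ids
#' must be unique.
#'
#' @slot specimens list of `Specimen`.
#' @slot provenance list of metadata carried along into reports.
#' @export
setClass("SpecimenSet",
  representation(specimens = "list", provenance = "list")
)

setValidity("SpecimenSet", function(object) {
  if (!all(vapply(object@specimens, is, logical(1), "Specimen"))) {
    return("all elements of specimens must be Specimen objects")
  }
  ids <- vapply(object@specimens, function(s) s@specimenId, character(1))
  if (anyDuplicated(ids)) {
    return(sprintf("duplicate specimen id(s): %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  TRUE
})

#' OrderedSequence: one specimen's birth-order sequence for one TF
#'
#' Motoneuron-class cells with a non-missing call for `tf`, sorted by
#' descending Euclidean distance from the reference cell.  Rank 1 is the
#' cell furthest from the neuroblast, i.e. the oldest (first-born) cell on
#' average; the last rank is the youngest, closest to the NB.
#'
#' @slot specimenId source specimen.
#' @slot tf transcription factor name.
#' @slot calls logical vector indexed by rank (no `NA`).
#' @slot distances numeric vector of distances to the reference (µm),
#'   parallel to `calls`, non-increasing.
#' @slot cellIds character vector of cell ids, parallel to `calls`.
#' @export
setClass("OrderedSequence",
  representation(
    specimenId = "character",
    tf = "character",
    calls = "logical",
    distances = "numeric",
    cellIds = "character"
  )
)

setValidity("OrderedSequence", function(object) {
  L <- length(object@calls)
  if (length(object@distances) != L || length(object@cellIds) != L) {
    return("calls, distances and cellIds must have equal length")
  }
  if (anyNA(object@calls)) return("calls must not contain NA")
  if (L > 1L && any(diff(object@distances) > 1e-9)) {
    return("distances must be non-increasing in rank")
  }
  TRUE
})

#' Savitzky-Golay smoothing configuration
#'
#' @slot window odd positive integer window length (default 11).
#' @slot polyorder polynomial order, `< window` (default 3).
#' @slot edgeMode `"polynomial_interp"` (fit one polynomial to the first /
#'   last window and evaluate it at the edge ranks) or `"mirror"`
#'   (reflect-pad the profile before filtering).
#' @export
setClass("SmoothingConfig",
  representation(window = "integer", polyorder = "integer", edgeMode = "character")
)

setValidity("SmoothingConfig", function(object) {
  w <- object@window
  p <- object@polyorder
  if (length(w) != 1L || w < 1L || w %% 2L == 0L) return("window must be an odd positive integer")
  if (length(p) != 1L || p < 0L || p >= w) return("polyorder must satisfy 0 <= polyorder < window")
  if (!object@edgeMode %in% c("polynomial_interp", "mirror")) {
    return("edgeMode must be 'polynomial_interp' or 'mirror'")
  }
  TRUE
})

#' Peak-detection configuration
#'
#' @slot hMin minimal peak height, a frequency in `[0, 1]` (default 0.2).
#' @slot dMin minimal rank distance between retained peaks (default 8).
#' @slot pMin minimal prominence, a frequency in `[0, 1]` (default 0.07).
#' @export
setClass("PeakConfig",
  representation(hMin = "numeric", dMin = "numeric", pMin = "numeric")
)

setValidity("PeakConfig", function(object) {
  v <- c(object@hMin, object@dMin, object@pMin)
  if (length(v) != 3L || any(!is.finite(v)) || any(v < 0)) {
    return("h_min, d_min, p_min must be finite and non-negative")
  }
  if (object@hMin > 1 || object@pMin > 1) return("h_min and p_min are frequencies and must be <= 1")
  TRUE
})

#' FrequencyProfile: per-rank expression frequency of one TF
#'
#' For each rank i across a cohort of [OrderedSequence-class]s:
#' `P[i]` is the number of positive cells at rank i, `Nseq[i]` the number
#' of sequences long enough to reach rank i ("at risk"), and `NTotal` the
#' number of sequences.  In `relative` mode `f[i] = P[i]/Nseq[i]`, which is
#' unbiased under right-censoring of sequence lengths; in `global` mode
#' `f[i] = P[i]/NTotal`, which treats unobserved ranks as negative and is
#' biased low at deep ranks.  `fSmooth` holds the Savitzky-Golay smoothed
#' frequency once [smoothProfile()] has been applied (length 0 before).
#'
#' @slot tf TF name.
#' @slot P integer vector of per-rank positive counts.
#' @slot Nseq integer vector of per-rank at-risk counts (non-increasing).
#' @slot NTotal number of sequences contributing.
#' @slot mode `"relative"` or `"global"`.
#' @slot f numeric vector of raw frequencies.
#' @slot fSmooth numeric vector of smoothed frequencies (may be empty).
#' @slot smoothing list; echo of the smoothing parameters used (empty
#'   before smoothing).
#' @export
setClass("FrequencyProfile",
  representation(
    tf = "character",
    P = "integer",
    Nseq = "integer",
    NTotal = "integer",
    mode = "character",
    f = "numeric",
    fSmooth = "numeric",
    smoothing = "list"
  )
)

setValidity("FrequencyProfile", function(object) {
  L <- length(object@P)
  if (length(object@Nseq) != L || length(object@f) != L) {
    return("P, Nseq and f must have equal length")
  }
  if (any(object@P < 0L) || any(object@P > object@Nseq)) {
    return("0 <= P[i] <= Nseq[i] violated")
  }
  if (L > 1L && any(diff(object@Nseq) > 0L)) return("Nseq must be non-increasing")
  if (L > 0L && object@Nseq[1L] > object@NTotal) return("Nseq[1] must be <= NTotal")
  if (!object@mode %in% c("relative", "global")) return("mode must be 'relative' or 'global'")
  if (length(object@fSmooth) && length(object@fSmooth) != L) {
    return("fSmooth must be empty or the same length as f")
  }
  TRUE
})

#' ClusterCall: one positive-cell cluster under one peak
#'
#' The cluster is a continuous interval on the rank axis of total width
#' `n` (the cohort-mean number of positive cells in the peak's region).
#' Integer ranks fully inside the interval form the core span with
#' coverage 1; the at most two partially covered border ranks carry a
#' fractional coverage index, so that coverage sums to `n`.
#'
#' @slot tf TF name.
#' @slot peak one-row `data.frame` (`position`, `height`, `prominence`,
#'   `region_start`, `region_end`) describing the peak the cluster sits
#'   under.
#' @slot n cohort-mean positive-cell count in the peak region (real).
#' @slot bounds numeric length-2 continuous interval `[x_l, x_r]` on the
#'   rank axis (rank r occupies `[r - 0.5, r + 0.5]`); length 0 if empty.
#' @slot coreSpan integer length-2 `[ip', jp']` of fully covered ranks;
#'   length 0 if no rank is fully covered.
#' @slot coverage named numeric vector, rank -> coverage in `[0, 1]`,
#'   restricted to ranks with positive coverage.
#' @export
setClass("ClusterCall",
  representation(
    tf = "character",
    peak = "data.frame",
    n = "numeric",
    bounds = "numeric",
    coreSpan = "integer",
    coverage = "numeric"
  )
)

setValidity("ClusterCall", function(object) {
  if (length(object@coverage)) {
    if (any(object@coverage < -1e-9) || any(object@coverage > 1 + 1e-9)) {
      return("coverage values must lie in [0, 1]")
    }
    if (is.null(names(object@coverage))) return("coverage must be named by rank")
  }
  if (length(object@bounds) && (length(object@bounds) != 2L ||
      object@bounds[2L] < object@bounds[1L])) {
    return("bounds must be an interval [x_l, x_r] with x_l <= x_r")
  }
  TRUE
})

#' TFCodeMap: the per-rank combinatorial TF code
#'
#' Membership matrix over the birth-order axis (ranks 1..`maxBirthOrder`,
#' rows) and the TF panel (columns); entries are the coverage in `[0, 1]`
#' contributed by cluster calls.  Ranks beyond `maxBirthOrder`
#' (supernumerary, typically death-fated cells in larval cohorts) are kept
#' apart in `annex` rather than rescaled onto the main axis.
#'
#' @slot membership numeric matrix, `maxBirthOrder` rows, one column per TF.
#' @slot annex numeric matrix for ranks `> maxBirthOrder` (may have 0 rows).
#' @slot condition genotype/condition label of the cohort.
#' @slot maxBirthOrder length of the main birth-order axis (default 29,
#'   the adult survivor count of the lineage).
#' @slot calls list of the [ClusterCall-class]s the map was built from.
#' @export
setClass("TFCodeMap",
  representation(
    membership = "matrix",
    annex = "matrix",
    condition = "character",
    maxBirthOrder = "integer",
    calls = "list"
  )
)

setValidity("TFCodeMap", function(object) {
  m <- object@membership
  if (nrow(m) != object@maxBirthOrder) return("membership must have maxBirthOrder rows")
  vals <- c(m, object@annex)
  if (length(vals) && (any(vals < -1e-9) || any(vals > 1 + 1e-9))) {
    return("membership values must lie in [0, 1]")
  }
  if (ncol(object@annex) != ncol(m)) return("annex must have the same TF columns as membership")
  TRUE
})

#' GeneratorConfig: synthetic-lineage generator settings
#'
#' Describes the statistical structure the pipeline assumes: a neuroblast
#' at the origin; motoneurons placed at radial distances that decrease
#' with later birth (first-born cells lie furthest away); TF expression in
#' one or two contiguous birth-order intervals with per-cell Bernoulli
#' noise and per-specimen integer jitter of the interval endpoints; and
#' optional right-truncation of the observed sequence.
#'
#' @slot nMn mean motoneuron count per specimen (stage presets: larval 39,
#'   24h APF 32, adult 29).
#' @slot countSd SD of the motoneuron count across specimens.
#' @slot d0 distance (µm) of the last-born MN from the NB.
#' @slot step distance increment (µm) per birth rank.
#' @slot posNoiseSd SD (µm) of radial placement noise.
#' @slot nGmc number of decoy GMC cells placed near the NB.
#' @slot tfSpecs named list; per TF a list with `intervals` (list of
#'   `c(lo, hi)` birth-rank intervals), `p_in` (per-interval positive rate,
#'   recycled), `p_out` (background rate) and `jitter` (max absolute
#'   integer shift of each interval endpoint per specimen).
#' @slot truncation list; `list(type = "none")` or
#'   `list(type = "uniform", min =, max =)` observed sequence length.
#' @slot genotype condition label stamped on generated specimens.
#' @slot stage stage label stamped on generated specimens.
#' @export
setClass("GeneratorConfig",
  representation(
    nMn = "numeric",
    countSd = "numeric",
    d0 = "numeric",
    step = "numeric",
    posNoiseSd = "numeric",
    nGmc = "integer",
    tfSpecs = "list",
    truncation = "list",
    genotype = "character",
    stage = "character"
  )
)

setValidity("GeneratorConfig", function(object) {
  if (object@nMn < 1) return("nMn must be >= 1")
  if (object@countSd < 0 || object@posNoiseSd < 0) return("SDs must be non-negative")
  if (object@step <= 0) return("step must be > 0 (distance decreases with later birth)")
  for (tf in names(object@tfSpecs)) {
    sp <- object@tfSpecs[[tf]]
    p_in <- rep(sp$p_in, length.out = length(sp$intervals))
    if (any(sp$p_out > p_in)) return(sprintf("%s: p_out must be <= p_in", tf))
    if (any(p_in > 1) || sp$p_out < 0) return(sprintf("%s: rates must lie in [0, 1]", tf))
    for (iv in sp$intervals) {
      if (length(iv) != 2L || iv[1L] > iv[2L] || iv[1L] < 1L) {
        return(sprintf("%s: invalid interval [%s]", tf, paste(iv, collapse = ",")))
      }
    }
  }
  TRUE
})

#' PCCDResult: full pipeline output for one cohort
#'
#' @slot profiles named list of smoothed [FrequencyProfile-class]s, per TF.
#' @slot peaks named list of peak tables (`data.frame`), per TF.
#' @slot clusters named list of lists of [ClusterCall-class], per TF.
#' @slot codeMap the assembled [TFCodeMap-class].
#' @slot params list of all tunable parameters actually used.
#' @slot log character vector of run messages.
#' @export
setClass("PCCDResult",
  representation(
    profiles = "list",
    peaks = "list",
    clusters = "list",
    codeMap = "TFCodeMap",
    params = "list",
    log = "character"
  )
)
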