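## Positive-cell cluster placement (the second half of the peak step and
## the code-map assembly).
##
## The smoothed profile is read as a piecewise-linear curve over a
## continuous rank axis in which rank r occupies the unit cell
## [r - 0.5, r + 0.5] (with the curve held flat over the outer half-cells
## of a region).  A horizontal cut is lowered from the peak apex; at each
## level the contiguous super-level interval containing the peak has a
## width in cell units, and the level at which that width equals the
## cohort-mean positive count n defines the cluster.  Integer ranks fully
## inside the interval get coverage 1 (the core span); the at most two
## partially covered border ranks get the fractional remainder, split
## proportionally to the interpolated overhang on each side, so coverage
## always sums to n.

# contiguous super-level interval containing rank p at level lam,
# restricted to ranks a..b of x; returns c(x_l, x_r) on the continuous axis
.levelInterval <- function(x, p, a, b, lam) {
  i <- p - 1L
  while (i >= a && x[i] >= lam) i <- i - 1L
  xl <- if (i < a) a - 0.5 else i + (lam - x[i]) / (x[i + 1L] - x[i])
  j <- p + 1L
  while (j <= b && x[j] >= lam) j <- j + 1L
  xr <- if (j > b) b + 0.5 else j - (lam - x[j]) / (x[j - 1L] - x[j])
  c(xl, xr)
}

#' Cohort-mean number of positive cells in a rank region
#'
#' @param sequences list of [OrderedSequence-class] for one TF.
#' @param region integer length-2 rank interval `c(lo, hi)` (1-based,
#'   closed).
#' @return the mean, over sequences, of the number of positive calls at
#'   ranks inside the region; sequences shorter than the region contribute
#'   their observed ranks only.
#' @export
meanPositiveCount <- function(sequences, region) {
  if (length(region) != 2L || region[1L] > region[2L] || region[1L] < 1L) {
    stop("region must be a non-empty rank interval c(lo, hi) with lo >= 1")
  }
  if (!length(sequences)) stop("meanPositiveCount() needs at least one sequence")
  counts <- vapply(sequences, function(s) {
    hi <- min(region[2L], length(s@calls))
    if (hi < region[1L]) 0L else sum(s@calls[region[1L]:hi])
  }, integer(1))
  mean(counts)
}

#' Place a positive-cell cluster of mean size n under a peak
#'
#' Lowers a horizontal cut level from the peak apex until the contiguous
#' super-level interval containing the peak (linearly interpolated
#' between ranks, clipped to the peak's region) spans exactly `n` cells.
#' Integer ranks fully covered by the resulting interval form the core
#' span; the at most two partially covered border ranks receive a
#' fractional coverage index such that the coverages sum to `n`.  If the
#' width-n level falls inside a plateau of the profile (where the
#' interval width jumps), the fractional remainder is split across the
#' two sides proportionally to the interpolated overhang of each side.
#'
#' @param profile smoothed profile vector or smoothed
#'   [FrequencyProfile-class].
#' @param peak one-row peak table from [partitionRegions()] (needs
#'   `position`, `region_start`, `region_end`).
#' @param n target mean positive count, real-valued, `>= 0`.  `n = 0`
#'   yields an empty call; `n` exceeding the region width saturates the
#'   region (coverage capped at 1 per rank) with a warning.
#' @param tf TF label stored on the call.
#' @return a [ClusterCall-class].
#' @export
placeCluster <- function(profile, peak, n, tf = "TF") {
  x <- if (is(profile, "FrequencyProfile")) frequencies(profile, smoothed = TRUE)
       else as.numeric(profile)
  stopifnot(nrow(peak) == 1L, n >= 0)
  a <- as.integer(peak$region_start)
  b <- as.integer(peak$region_end)
  p <- as.integer(peak$position)
  if (a < 1L || b > length(x) || p < a || p > b) stop("invalid peak region")
  peak <- as.data.frame(peak)[, c("position", "height", "prominence",
                                  "region_start", "region_end")]
  if (n < 1e-12) {
    return(new("ClusterCall", tf = tf, peak = peak, n = n,
               bounds = numeric(0), coreSpan = integer(0),
               coverage = numeric(0)))
  }
  width_max <- b - a + 1
  if (n > width_max + 1e-9) {
    warning(sprintf("n = %.3f exceeds the region width %d; cluster saturates [%d, %d]",
                    n, width_max, a, b))
    n_eff <- width_max
  } else {
    n_eff <- min(n, width_max)
  }
  levels <- sort(unique(x[a:b][x[a:b] <= x[p]]), decreasing = TRUE)
  hi_int <- NULL
  hi_w <- 0
  bounds <- NULL
  for (lam in levels) {
    int <- .levelInterval(x, p, a, b, lam)
    w <- int[2L] - int[1L]
    if (w >= n_eff - 1e-12) {
      if (is.null(hi_int)) {
        # apex level is already wider than n: centre the span on the apex
        # interval's midpoint
        mid <- (int[1L] + int[2L]) / 2
        hi_int <- c(mid, mid)
        hi_w <- 0
      }
      t <- if (w - hi_w < 1e-15) 1 else (n_eff - hi_w) / (w - hi_w)
      bounds <- c(hi_int[1L] + t * (int[1L] - hi_int[1L]),
                  hi_int[2L] + t * (int[2L] - hi_int[2L]))
      break
    }
    hi_int <- int
    hi_w <- w
  }
  if (is.null(bounds)) bounds <- c(a - 0.5, b + 0.5)  # unreachable safety net
  ranks <- a:b
  cov <- pmax(0, pmin(bounds[2L], ranks + 0.5) - pmax(bounds[1L], ranks - 0.5))
  keep <- cov > 1e-12
  coverage <- cov[keep]
  names(coverage) <- ranks[keep]
  core <- ranks[cov >= 1 - 1e-9]
  new("ClusterCall", tf = tf, peak = peak, n = n, bounds = bounds,
      coreSpan = if (length(core)) range(core) else integer(0),
      coverage = coverage)
}

#' Full cluster detection for one TF
#'
#' Runs the whole per-TF chain: frequency profile, Savitzky-Golay
#' smoothing, peak detection, region partitioning, per-region mean
#' positive count, and level-set cluster placement.  With a single
#' detected peak the whole axis is one region; with multiple peaks the
#' axis is split at the valleys between them and each region is processed
#' independently with its own mean count.
#'
#' @param sequences non-empty list of [OrderedSequence-class] for one TF.
#' @param smoothing a [SmoothingConfig-class].
#' @param peaks_cfg a [PeakConfig-class].
#' @param mode frequency mode, `"relative"` (default) or `"global"`.
#' @return list of [ClusterCall-class] (empty when no peak is detected),
#'   with the smoothed [FrequencyProfile-class] in `attr(, "profile")`
#'   and the region-annotated peak table in `attr(, "peaks")`.
#' @export
detectClusters <- function(sequences, smoothing = smoothingConfig(),
                           peaks_cfg = peakConfig(), mode = "relative") {
  profile <- smoothProfile(frequencyProfile(sequences, mode = mode), smoothing)
  pk <- partitionRegions(findPeaks(profile, peaks_cfg), profile)
  calls <- vector("list", nrow(pk))
  for (i in seq_len(nrow(pk))) {
    region <- c(pk$region_start[i], pk$region_end[i])
    n <- meanPositiveCount(sequences, region)
    calls[[i]] <- placeCluster(profile, pk[i, ], n, tf = profile@tf)
  }
  calls <- Filter(function(cl) length(cl@bounds) > 0L, calls)
  attr(calls, "profile") <- profile
  attr(calls, "peaks") <- pk
  calls
}

#' Integer rank span of a cluster call
#'
#' The continuous cluster interval rendered at integer resolution: the
#' range of ranks whose coverage is at least `threshold` (default 0.5,
#' i.e. ranks that are mostly inside the interval).  For an integer `n`
#' this span contains exactly `n` ranks; fractional borders below the
#' threshold remain visible through the coverage index.
#'
#' @param call a [ClusterCall-class].
#' @param threshold minimal coverage for a rank to be counted.
#' @return integer length-2 `c(lo, hi)`, or `integer(0)` for an empty
#'   call.
#' @export
clusterSpan <- function(call, threshold = 0.5) {
  stopifnot(is(call, "ClusterCall"))
  if (!length(call@coverage)) return(integer(0))
  rks <- as.integer(names(call@coverage))[call@coverage >= threshold - 1e-9]
  if (!length(rks)) return(integer(0))
  range(rks)
}
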