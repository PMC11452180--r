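## Peak detection on smoothed frequency profiles.
##
## Semantics follow the standard 1D signal convention: a peak is a sample
## strictly greater than its neighbours (a plateau is represented by its
## midpoint); prominence is the vertical drop from the peak to the higher
## of the two minima separating it from the nearest strictly higher
## samples (or the signal ends); candidates are filtered by height, then
## minimal distance (higher peaks silence lower ones within d_min), then
## prominence.

# positions of interior local maxima; plateaus -> midpoint rank
.localMaxima <- function(x) {
  n <- length(x)
  out <- integer(0)
  if (n < 3L) return(out)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i - 1L] < x[i]) {
      ahead <- i + 1L
      while (ahead < n && x[ahead] == x[i]) ahead <- ahead + 1L
      if (x[ahead] < x[i]) {
        out <- c(out, (i + ahead - 1L) %/% 2L)
        i <- ahead
      }
    }
    i <- i + 1L
  }
  out
}

# prominence of the peak at index p: descend each side while values do
# not exceed x[p], track the minimum; base = the higher of the two minima
.prominence <- function(x, p) {
  n <- length(x)
  left_min <- x[p]
  i <- p - 1L
  while (i >= 1L && x[i] <= x[p]) {
    if (x[i] < left_min) left_min <- x[i]
    i <- i - 1L
  }
  right_min <- x[p]
  i <- p + 1L
  while (i <= n && x[i] <= x[p]) {
    if (x[i] < right_min) right_min <- x[i]
    i <- i + 1L
  }
  x[p] - max(left_min, right_min)
}

# keep highest peaks first; remove unkept neighbours closer than dmin
.selectByDistance <- function(positions, heights, dmin) {
  k <- length(positions)
  keep <- rep(TRUE, k)
  for (idx in rev(order(heights))) {   # stable: rightmost of tied heights first
    if (!keep[idx]) next
    j <- idx - 1L
    while (j >= 1L && positions[idx] - positions[j] < dmin) {
      keep[j] <- FALSE
      j <- j - 1L
    }
    j <- idx + 1L
    while (j <= k && positions[j] - positions[idx] < dmin) {
      keep[j] <- FALSE
      j <- j + 1L
    }
  }
  keep
}

#' Detect peaks in a smoothed frequency profile
#'
#' Local maxima of the profile are retained when their height is at least
#' `h_min`, they are at least `d_min` ranks away from every higher
#' retained peak, and their prominence is at least `p_min`.  Prominence is
#' the vertical distance between the peak and the altitude of the largest
#' region it dominates: on each side, walk until a strictly higher sample
#' (or the profile end) and take the minimum; the higher of the two minima
#' is the peak's base.  Plateau maxima are reported at their midpoint
#' rank.  Filters are applied in the order height, distance, prominence.
#'
#' @param profile numeric vector (a smoothed frequency profile) or a
#'   smoothed [FrequencyProfile-class].
#' @param cfg a [PeakConfig-class]; defaults `h_min = 0.2`, `d_min = 8`,
#'   `p_min = 0.07`.
#' @return `data.frame` with one row per retained peak, sorted by
#'   position: `position`, `height`, `prominence` (an empty data.frame
#'   when no peak qualifies).
#' @examples
#' findPeaks(c(0, 0.3, 0.1, 0.25, 0))  # one peak at rank 2
#' @export
findPeaks <- function(profile, cfg = peakConfig()) {
  x <- if (is(profile, "FrequencyProfile")) frequencies(profile, smoothed = TRUE)
       else as.numeric(profile)
  stopifnot(is(cfg, "PeakConfig"))
  validObject(cfg)
  empty <- data.frame(position = integer(0), height = numeric(0),
                      prominence = numeric(0))
  if (!length(x)) return(empty)
  pos <- .localMaxima(x)
  pos <- pos[x[pos] >= cfg@hMin]
  if (!length(pos)) return(empty)
  pos <- pos[.selectByDistance(pos, x[pos], cfg@dMin)]
  prom <- vapply(pos, .prominence, numeric(1), x = x)
  sel <- prom >= cfg@pMin
  data.frame(position = pos[sel], height = x[pos[sel]], prominence = prom[sel])
}

#' Partition the rank axis into peak-prevailing regions
#'
#' Splits `[1, L]` into one interval per peak such that each peak lies in
#' its own interval and the intervals tile the axis without overlap.  The
#' boundary between two adjacent peaks is the rank of the minimum of the
#' smoothed profile strictly between them; when the minimum is attained on
#' a run of tied ranks, the midpoint of the run is used.  The boundary
#' rank joins the left region.
#'
#' @param peaks peak table from [findPeaks()] (sorted by position).
#' @param profile the smoothed profile vector (or smoothed
#'   [FrequencyProfile-class]) the peaks were detected in.
#' @return the peak table with `region_start` and `region_end` columns
#'   added; an empty table yields an empty result.
#' @export
partitionRegions <- function(peaks, profile) {
  x <- if (is(profile, "FrequencyProfile")) frequencies(profile, smoothed = TRUE)
       else as.numeric(profile)
  L <- length(x)
  k <- nrow(peaks)
  if (k == 0L) {
    peaks$region_start <- integer(0)
    peaks$region_end <- integer(0)
    return(peaks)
  }
  if (is.unsorted(peaks$position)) stop("peaks must be sorted by position")
  bounds <- integer(k - 1L)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      p1 <- peaks$position[i]
      p2 <- peaks$position[i + 1L]
      if (p2 - p1 <= 1L) {
        bounds[i] <- p1
      } else {
        between <- (p1 + 1L):(p2 - 1L)
        m <- min(x[between])
        tied <- between[x[between] == m]
        bounds[i] <- (tied[1L] + tied[length(tied)]) %/% 2L
      }
    }
  }
  peaks$region_start <- c(1L, bounds + 1L)
  peaks$region_end <- c(bounds, L)
  peaks
}
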