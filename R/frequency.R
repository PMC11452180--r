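#' Per-rank expression frequency across a cohort of ordered sequences
#'
#' For each rank i up to the longest observed sequence, counts the number
#' of positive cells `P[i]` and the number of sequences that reach rank i,
#' `Nseq[i]`.  The default `relative` mode divides by `Nseq[i]`, so that
#' specimens with fewer observed cells do not drag deep-rank frequencies
#' towards zero; `global` mode divides by the total number of sequences
#' and therefore treats every unobserved rank as negative.
#'
#' @param sequences non-empty list of [OrderedSequence-class], all for the
#'   same TF.
#' @param tf optional TF name; defaults to the sequences' TF, and is
#'   checked against it.
#' @param mode `"relative"` (default) or `"global"`.
#' @return a [FrequencyProfile-class] (unsmoothed).
#' @examples
#' s1 <- new("OrderedSequence", specimenId = "a", tf = "Jim",
#'           calls = c(TRUE, FALSE, TRUE), distances = c(3, 2, 1),
#'           cellIds = c("c1", "c2", "c3"))
#' s2 <- new("OrderedSequence", specimenId = "b", tf = "Jim",
#'           calls = c(TRUE, TRUE), distances = c(2, 1), cellIds = c("c1", "c2"))
#' frequencies(frequencyProfile(list(s1, s2)))  # 1.0 0.5 1.0
#' @export
frequencyProfile <- function(sequences, tf = NULL,
                             mode = c("relative", "global")) {
  mode <- match.arg(mode)
  if (!length(sequences)) stop("frequencyProfile() needs at least one sequence")
  tfs <- unique(vapply(sequences, function(s) s@tf, character(1)))
  if (length(tfs) != 1L) {
    stop("sequences mix TFs: ", paste(tfs, collapse = ", "))
  }
  if (is.null(tf)) tf <- tfs
  if (!identical(tf, tfs)) stop("sequences are for '", tfs, "', not '", tf, "'")
  lens <- vapply(sequences, function(s) length(s@calls), integer(1))
  L <- max(lens)
  if (L == 0L) stop("all sequences are empty")
  P <- integer(L)
  Nseq <- integer(L)
  for (s in sequences) {
    Ls <- length(s@calls)
    if (!Ls) next
    idx <- seq_len(Ls)
    P[idx] <- P[idx] + as.integer(s@calls)
    Nseq[idx] <- Nseq[idx] + 1L
  }
  # ranks reached by no sequence cannot occur (L is the max length)
  f <- if (mode == "relative") P / Nseq else P / length(sequences)
  new("FrequencyProfile", tf = tf, P = P, Nseq = Nseq,
      NTotal = length(sequences), mode = mode, f = f,
      fSmooth = numeric(0), smoothing = list())
}

#' Savitzky-Golay smoothing of a frequency profile
#'
#' Fits, around every rank, a least-squares polynomial of order
#' `cfg@polyorder` over a centred window of `cfg@window` ranks and takes
#' its value at the centre; this preserves polynomial structure up to the
#' filter order while averaging out specimen-to-specimen jitter of cluster
#' boundaries.  At the profile ends the `polynomial_interp` edge mode
#' evaluates the polynomial fitted to the first/last full window at the
#' edge ranks (so clusters abutting either end of the sequence are not
#' flattened); `mirror` reflect-pads instead.  Profiles shorter than the
#' window are smoothed with the largest odd window that fits, with the
#' polynomial order capped at `window - 1`; profiles of length < 2 are
#' returned unsmoothed with a warning.  Smoothed values are clipped to
#' `[0, 1]`, since frequencies are probabilities and the filter can
#' overshoot.
#'
#' @param profile a [FrequencyProfile-class].
#' @param cfg a [SmoothingConfig-class]; default window 11, order 3.
#' @return the profile with `fSmooth` filled in.
#' @export
smoothProfile <- function(profile, cfg = smoothingConfig()) {
  stopifnot(is(profile, "FrequencyProfile"), is(cfg, "SmoothingConfig"))
  validObject(cfg)
  x <- profile@f
  L <- length(x)
  if (L < 2L) {
    warning("profile of length ", L, " returned unsmoothed")
    profile@fSmooth <- x
    profile@smoothing <- list(window = NA_integer_, polyorder = NA_integer_,
                              edge_mode = cfg@edgeMode, applied = FALSE)
    return(profile)
  }
  w <- as.integer(cfg@window)
  if (w > L) w <- if (L %% 2L == 1L) L else L - 1L
  p <- min(cfg@polyorder, w - 1L)
  y <- if (w < 2L) {
    x
  } else if (cfg@edgeMode == "mirror") {
    h <- (w - 1L) %/% 2L
    # reflect about the end points without repeating them
    pad <- c(x[(h + 1L):2L], x, x[(L - 1L):(L - h)])
    as.numeric(signal::sgolayfilt(pad, p = p, n = w))[(h + 1L):(h + L)]
  } else {
    as.numeric(signal::sgolayfilt(x, p = p, n = w))
  }
  profile@fSmooth <- pmin(1, pmax(0, y))
  profile@smoothing <- list(window = w, polyorder = p,
                            edge_mode = cfg@edgeMode, applied = w >= 2L)
  profile
}

#' Export a frequency profile as a table
#'
#' @param profile a [FrequencyProfile-class].
#' @return `data.frame` with columns `tf`, `rank`, `P`, `N`, `f` and, when
#'   present, `f_smooth`.
#' @export
profileTable <- function(profile) {
  stopifnot(is(profile, "FrequencyProfile"))
  out <- data.frame(tf = profile@tf, rank = seq_along(profile@f),
                    P = profile@P, N = profile@Nseq, f = profile@f)
  if (length(profile@fSmooth)) out$f_smooth <- profile@fSmooth
  out
}
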