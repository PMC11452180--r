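# Independent oracles used to cross-check the package's numerics.
# Deliberately written with different mechanics than the implementation:
# per-window least-squares fits instead of convolution, vectorized
# key-saddle search instead of pointer walks.

# Savitzky-Golay as explicit per-window polynomial least squares with the
# edge convention "fit one polynomial to the first/last window and
# evaluate it at the edge positions" (no clipping).
oracle_savgol <- function(x, w = 11L, p = 3L) {
  L <- length(x)
  h <- (w - 1L) %/% 2L
  fitwin <- function(idx, at) {
    fit <- stats::lm(y ~ stats::poly(t, degree = p, raw = TRUE),
                     data = data.frame(t = idx, y = x[idx]))
    unname(stats::predict(fit, newdata = data.frame(t = at)))
  }
  out <- numeric(L)
  for (i in seq_len(L)) {
    out[i] <- if (i <= h) fitwin(1:w, i)
    else if (i > L - h) fitwin((L - w + 1L):L, i)
    else fitwin((i - h):(i + h), i)
  }
  out
}

# all interior local maxima, plateaus at their midpoint rank
oracle_local_maxima <- function(x) {
  n <- length(x)
  out <- integer(0)
  if (n < 3L) return(out)
  for (i in 2:(n - 1L)) {
    if (x[i - 1L] < x[i]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) out <- c(out, (i + j) %/% 2L)
    }
  }
  out
}

# prominence by the key-saddle definition: on each side, the dominated
# region ends at the nearest strictly higher sample (or the signal end);
# the base is the higher of the two minima over those regions
oracle_prominence <- function(x, p) {
  n <- length(x)
  higher <- which(x > x[p])
  hl <- higher[higher < p]
  hr <- higher[higher > p]
  lmin <- min(x[(if (length(hl)) max(hl) else 1L):p])
  rmin <- min(x[p:(if (length(hr)) min(hr) else n)])
  x[p] - max(lmin, rmin)
}

# greedy distance pruning: repeatedly accept the highest remaining
# candidate (rightmost on ties) and discard unaccepted candidates closer
# than dmin
oracle_select_distance <- function(pos, height, dmin) {
  state <- rep("open", length(pos))   # open / kept / dropped
  while (any(state == "open")) {
    open <- which(state == "open")
    best <- open[height[open] == max(height[open])]
    best <- best[length(best)]
    state[best] <- "kept"
    near <- abs(pos - pos[best]) < dmin & state != "kept"
    state[near] <- "dropped"
  }
  state == "kept"
}

oracle_find_peaks <- function(x, h_min = 0.2, d_min = 8, p_min = 0.07) {
  pos <- oracle_local_maxima(x)
  pos <- pos[x[pos] >= h_min]
  if (!length(pos)) {
    return(data.frame(position = integer(0), prominence = numeric(0)))
  }
  pos <- pos[oracle_select_distance(pos, x[pos], d_min)]
  prom <- vapply(pos, oracle_prominence, numeric(1), x = x)
  keep <- prom >= p_min
  data.frame(position = pos[keep], prominence = prom[keep])
}
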