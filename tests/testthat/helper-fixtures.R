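# Small fixtures built in code.

# a hand-sized specimen: NB at (5,5,5), three MNs on a line, one glia
toy_specimen <- function() {
  cells <- data.frame(
    cell_id = c("nb", "m1", "m2", "m3", "gl"),
    cell_class = c("NB", "MN", "MN", "MN", "glia"),
    x_um = c(5, 35, 25, 15, 6),
    y_um = c(5, 5, 5, 5, 7),
    z_um = c(5, 5, 5, 5, 5)
  )
  calls <- matrix(c(NA, FALSE, TRUE, TRUE, NA), ncol = 1,
                  dimnames = list(cells$cell_id, "Jim"))
  Specimen("T1", cells, calls, genotype = "control", stage = "L3")
}

# FrequencyProfile carrying an arbitrary frequency vector (for smoother
# tests, where only f matters)
profile_of <- function(f, tf = "X") {
  new("FrequencyProfile", tf = tf, P = integer(length(f)),
      Nseq = rep(1L, length(f)), NTotal = 1L, mode = "relative",
      f = as.numeric(f), fSmooth = numeric(0), smoothing = list())
}

# OrderedSequence from a plain 0/1 vector
seq_of <- function(calls, tf = "X", id = "S1") {
  L <- length(calls)
  new("OrderedSequence", specimenId = id, tf = tf,
      calls = as.logical(calls), distances = rev(seq_len(L)) + 0,
      cellIds = sprintf("c%02d", seq_len(L)))
}

# generator config with a single TF pattern and explicit noise settings
block_config <- function(intervals, p_in = 1, p_out = 0, jitter = 0L,
                         pos_noise_sd = 0, truncation = list(type = "none"),
                         tf = "X", ...) {
  generatorConfig(
    pos_noise_sd = pos_noise_sd, truncation = truncation,
    tf_specs = stats::setNames(
      list(tfSpec(intervals, p_in = p_in, p_out = p_out, jitter = jitter)),
      tf),
    ...
  )
}

# random profiles for oracle sweeps: a mix of smooth-ish continuous
# vectors and coarsely quantized ones (plateaus, ties)
random_profiles <- function(n, max_len = 60L) {
  lapply(seq_len(n), function(i) {
    L <- sample(5:max_len, 1L)
    x <- stats::runif(L)
    if (i %% 3L == 0L) x <- round(x, 1)
    x
  })
}
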