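#' Assemble (or read) a pipeline configuration
#'
#' Configuration is a plain nested list with sections `smoothing`
#' (`window`, `polyorder`, `edge_mode`), `peaks` (`h_min`, `d_min`,
#' `p_min`), `frequency` (`mode`), `clusters` (`max_birth_order`) and
#' optionally `tfs` (restrict the panel) and `generator` (see
#' [generatorFromList()]).  Values omitted fall back to the pipeline
#' defaults.
#'
#' @param path optional YAML file to read.
#' @param ... named overrides, e.g. `peaks = list(h_min = 0.5)`; applied
#'   on top of the file values.
#' @return list with elements `smoothing` ([SmoothingConfig-class]),
#'   `peaks` ([PeakConfig-class]), `mode`, `max_birth_order`, `tfs`
#'   (`NULL` = all), `generator` (list or `NULL`).
#' @export
pccdConfig <- function(path = NULL, ...) {
  raw <- if (!is.null(path)) yaml::read_yaml(path) else list()
  over <- list(...)
  for (sec in names(over)) {
    if (is.list(over[[sec]]) && !is.null(names(over[[sec]]))) {
      for (k in names(over[[sec]])) raw[[sec]][[k]] <- over[[sec]][[k]]
    } else {
      raw[[sec]] <- over[[sec]]
    }
  }
  sm <- raw$smoothing
  pk <- raw$peaks
  list(
    smoothing = smoothingConfig(
      window = sm$window %||% 11L,
      polyorder = sm$polyorder %||% 3L,
      edge_mode = sm$edge_mode %||% "polynomial_interp"
    ),
    peaks = peakConfig(
      h_min = pk$h_min %||% 0.2,
      d_min = pk$d_min %||% 8,
      p_min = pk$p_min %||% 0.07
    ),
    mode = raw$frequency$mode %||% "relative",
    max_birth_order = as.integer(raw$clusters$max_birth_order %||% 29L),
    min_specimens = as.integer(raw$clusters$min_specimens %||% 15L),
    tfs = raw$tfs,
    generator = raw$generator
  )
}

#' Flatten a pipeline configuration for echo / logging
#'
#' @param cfg a configuration list from [pccdConfig()].
#' @return nested list of plain values, suitable for
#'   `yaml::write_yaml()`.
#' @export
configAsList <- function(cfg) {
  list(
    smoothing = list(window = cfg$smoothing@window,
                     polyorder = cfg$smoothing@polyorder,
                     edge_mode = cfg$smoothing@edgeMode),
    peaks = list(h_min = cfg$peaks@hMin, d_min = cfg$peaks@dMin,
                 p_min = cfg$peaks@pMin),
    frequency = list(mode = cfg$mode),
    clusters = list(max_birth_order = cfg$max_birth_order,
                    min_specimens = cfg$min_specimens),
    tfs = cfg$tfs,
    generator = cfg$generator
  )
}

#' Build a GeneratorConfig from a plain list (YAML `generator` section)
#'
#' Inverse of [generatorAsList()]; unknown presets fall back to explicit
#' fields.
#'
#' @param lst list with optional `preset` plus any [generatorConfig()]
#'   field in snake_case.
#' @return a [GeneratorConfig-class].
#' @export
generatorFromList <- function(lst) {
  if (!is.null(lst$preset)) {
    args <- lst[setdiff(names(lst), c("preset", "tf_specs"))]
    return(do.call(genotypePreset, c(list(preset = lst$preset), args)))
  }
  specs <- lapply(lst$tf_specs %||% list(), function(sp) {
    tfSpec(intervals = sp$intervals, p_in = unlist(sp$p_in),
           p_out = sp$p_out %||% 0.02, jitter = sp$jitter %||% 1L)
  })
  args <- lst[intersect(names(lst),
                        c("n_mn", "count_sd", "stage", "d0", "step",
                          "pos_noise_sd", "n_gmc", "truncation", "genotype",
                          "stage_label"))]
  do.call(generatorConfig, c(args, list(tf_specs = specs)))
}
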