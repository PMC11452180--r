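## Synthetic lineage generator.
##
## Emulates the statistical structure the pipeline assumes: a neuroblast
## at the origin; motoneurons placed at radial distances decreasing with
## later birth (first-born cells furthest away), so that the distance
## ranking recovers birth order up to placement noise; TF expression in
## one or two contiguous birth-order intervals with Bernoulli dropout /
## ectopic noise and per-specimen jitter of the interval endpoints; and
## census variability across specimens.  Every specimen is a deterministic
## function of (master seed, specimen index).

.STAGE_CENSUS <- list(
  larval = c(n = 39, sd = 2),
  apf24 = c(n = 32, sd = 1),
  adult = c(n = 29, sd = 1)
)

#' Define a planted TF expression pattern
#'
#' @param intervals list of `c(lo, hi)` birth-rank intervals (1 or 2 for
#'   the factors this lineage is stained for).
#' @param p_in per-cell probability of a positive call inside an interval;
#'   recycled across intervals so a factor can have one strong and one
#'   attenuated cluster.
#' @param p_out background (ectopic) positive probability outside all
#'   intervals.
#' @param jitter maximal absolute integer shift applied independently to
#'   each interval endpoint in each specimen.
#' @return a list understood by [generatorConfig()]'s `tf_specs`.
#' @export
tfSpec <- function(intervals, p_in = 0.9, p_out = 0.02, jitter = 1L) {
  if (is.numeric(intervals)) intervals <- list(intervals)
  list(intervals = lapply(intervals, function(iv) as.integer(round(iv))),
       p_in = p_in, p_out = p_out, jitter = as.integer(jitter))
}

#' Synthetic-cohort generator configuration
#'
#' Defaults describe a wandering third-instar larval cohort: 39 +/- 2
#' motoneurons, the last-born cell 5 µm from the NB and 2 µm of distance
#' gained per birth rank, with 1 µm of radial placement noise.
#'
#' @param n_mn mean MN count; defaults to the `stage` census preset.
#' @param count_sd SD of the MN count; defaults to the `stage` preset.
#' @param stage `"larval"` (39 +/- 2), `"apf24"` (32 +/- 1) or `"adult"`
#'   (29 +/- 1).
#' @param d0 distance (µm) of the last-born MN from the NB.
#' @param step distance increment (µm) per birth rank (must be positive:
#'   earlier-born cells lie further from the NB).
#' @param pos_noise_sd SD (µm) of radial placement noise.
#' @param n_gmc number of decoy GMC cells near the NB (they must never
#'   influence the MN ordering).
#' @param tf_specs named list of [tfSpec()] patterns.
#' @param truncation `list(type = "none")` (default; sequence lengths vary
#'   only through the MN census) or `list(type = "uniform", min =, max =)`
#'   for additional right-truncation of the observed sequence.
#' @param genotype,stage_label labels stamped on generated specimens.
#' @return a [GeneratorConfig-class].
#' @export
generatorConfig <- function(n_mn = NULL, count_sd = NULL,
                            stage = c("larval", "apf24", "adult"),
                            d0 = 5, step = 2, pos_noise_sd = 1,
                            n_gmc = 2L, tf_specs = list(),
                            truncation = list(type = "none"),
                            genotype = "control", stage_label = NULL) {
  stage <- match.arg(stage)
  census <- .STAGE_CENSUS[[stage]]
  if (is.null(n_mn)) n_mn <- census[["n"]]
  if (is.null(count_sd)) count_sd <- census[["sd"]]
  if (is.null(stage_label)) stage_label <- stage
  new("GeneratorConfig", nMn = n_mn, countSd = count_sd, d0 = d0, step = step,
      posNoiseSd = pos_noise_sd, nGmc = as.integer(n_gmc), tfSpecs = tf_specs,
      truncation = truncation, genotype = genotype, stage = stage_label)
}

#' Genotype presets for the three-factor staining panel
#'
#' Returns a [GeneratorConfig-class] whose planted patterns reproduce the
#' qualitative contrasts between a control lineage and the two
#' perturbations that shift the early-born RNA-binding-protein balance:
#'
#' * `control`: Jim in a single mid-lineage cluster (ranks 16-23, 8
#'   cells); RunxA and Nvy each in two clusters, one NB-distal
#'   (early-born) and one NB-proximal (last-born).
#' * `imp_oe` (Imp overexpression): the Jim cluster extends into the
#'   NB-proximal last-born ranks (16-30); the NB-proximal RunxA cluster
#'   is lost; the NB-proximal Nvy cluster is attenuated (`p_in` halved).
#' * `syp_rnai` (Syp knockdown): same qualitative pattern as `imp_oe`
#'   with a slightly shorter Jim extension (16-29).
#'
#' Interval ranks are generator defaults chosen to be consistent with the
#' described phenotypes; they are configuration values, not measurements.
#'
#' @param preset one of `"control"`, `"imp_oe"`, `"syp_rnai"`.
#' @param ... further arguments passed to [generatorConfig()].
#' @return a [GeneratorConfig-class].
#' @export
genotypePreset <- function(preset = c("control", "imp_oe", "syp_rnai"), ...) {
  preset <- match.arg(preset)
  specs <- switch(preset,
    control = list(
      Jim = tfSpec(list(c(16, 23))),
      RunxA = tfSpec(list(c(4, 11), c(28, 36))),
      Nvy = tfSpec(list(c(6, 12), c(27, 35)))
    ),
    imp_oe = list(
      Jim = tfSpec(list(c(16, 30))),
      RunxA = tfSpec(list(c(4, 11))),
      Nvy = tfSpec(list(c(6, 12), c(27, 35)), p_in = c(0.9, 0.45))
    ),
    syp_rnai = list(
      Jim = tfSpec(list(c(16, 29))),
      RunxA = tfSpec(list(c(4, 11))),
      Nvy = tfSpec(list(c(6, 12), c(27, 35)), p_in = c(0.9, 0.45))
    )
  )
  generatorConfig(tf_specs = specs, genotype = preset, ...)
}

# deterministic per-specimen seed below 2^31
.deriveSeed <- function(seed, index) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 69621 + as.numeric(index)) %% 2147483647)
}

# uniform random unit vector in the upper hemisphere
.hemisphereDir <- function() {
  v <- stats::rnorm(3)
  v <- v / sqrt(sum(v^2))
  v[3L] <- abs(v[3L])
  v
}

#' Generate one synthetic specimen
#'
#' Deterministic given `(seed, index)`: the same pair always yields an
#' identical specimen, independently of how many other specimens were
#' generated before.
#'
#' @param cfg a [GeneratorConfig-class].
#' @param index specimen index within the cohort (part of the seed).
#' @param seed master seed.
#' @return list with elements `specimen` (a [Specimen-class]) and `truth`
#'   (ground truth: `birth`, a `data.frame` mapping `cell_id` to
#'   `birth_index`; `intervals`, the per-TF jittered intervals actually
#'   used; `observed_length`, the right-truncation applied).
#' @export
generateSpecimen <- function(cfg, index, seed = 1L) {
  stopifnot(is(cfg, "GeneratorConfig"))
  validObject(cfg)
  had_seed <- exists(".Random.seed", envir = globalenv())
  if (had_seed) saved <- get(".Random.seed", envir = globalenv())
  on.exit(if (had_seed) assign(".Random.seed", saved, envir = globalenv()),
          add = TRUE)
  set.seed(.deriveSeed(seed, index))

  n <- max(1L, as.integer(round(stats::rnorm(1, cfg@nMn, cfg@countSd))))
  birth <- seq_len(n)
  # first-born (birth 1) lies furthest from the NB
  dist <- cfg@d0 + cfg@step * (n - birth) + stats::rnorm(n, 0, cfg@posNoiseSd)
  dist <- pmax(dist, 0.1)
  dirs <- t(vapply(birth, function(k) .hemisphereDir(), numeric(3)))
  mn_xyz <- dirs * dist
  mn_ids <- sprintf("m%02d", birth)

  gmc_ids <- if (cfg@nGmc > 0L) sprintf("g%02d", seq_len(cfg@nGmc)) else character(0)
  gmc_xyz <- t(vapply(seq_len(cfg@nGmc),
                      function(k) .hemisphereDir() * stats::runif(1, 2, 4),
                      numeric(3)))
  if (cfg@nGmc == 0L) gmc_xyz <- matrix(numeric(0), 0L, 3L)

  cells <- data.frame(
    cell_id = c("nb", gmc_ids, mn_ids),
    cell_class = c("NB", rep("GMC", cfg@nGmc), rep("MN", n)),
    x_um = c(0, gmc_xyz[, 1L], mn_xyz[, 1L]),
    y_um = c(0, gmc_xyz[, 2L], mn_xyz[, 2L]),
    z_um = c(0, gmc_xyz[, 3L], mn_xyz[, 3L])
  )

  tfs <- names(cfg@tfSpecs)
  calls <- matrix(NA, nrow(cells), length(tfs),
                  dimnames = list(cells$cell_id, tfs))
  used_intervals <- list()
  for (tf in tfs) {
    sp <- cfg@tfSpecs[[tf]]
    p_in <- rep(sp$p_in, length.out = length(sp$intervals))
    q <- rep(sp$p_out, n)
    ivs <- list()
    for (k in seq_along(sp$intervals)) {
      iv <- sp$intervals[[k]]
      j <- sp$jitter
      lo <- iv[1L] + if (j > 0L) sample(-j:j, 1L) else 0L
      hi <- iv[2L] + if (j > 0L) sample(-j:j, 1L) else 0L
      lo <- max(1L, lo)
      hi <- min(n, hi)
      ivs[[k]] <- c(lo, hi)
      if (lo <= hi) q[lo:hi] <- pmax(q[lo:hi], p_in[k])
    }
    used_intervals[[tf]] <- ivs
    calls[mn_ids, tf] <- stats::runif(n) < q
  }

  L_obs <- n
  if (identical(cfg@truncation$type, "uniform")) {
    L_obs <- min(n, sample(cfg@truncation$min:cfg@truncation$max, 1L))
  }
  if (L_obs < n) {
    drop <- cells$cell_id %in% mn_ids[birth > L_obs]
    cells <- cells[!drop, , drop = FALSE]
    calls <- calls[!drop, , drop = FALSE]
  }

  sp_id <- sprintf("S%03d", as.integer(index))
  specimen <- Specimen(sp_id, cells, calls, reference_cell_id = "nb",
                       genotype = cfg@genotype, stage = cfg@stage)
  truth <- list(
    birth = data.frame(cell_id = mn_ids[birth <= L_obs],
                       birth_index = birth[birth <= L_obs]),
    intervals = used_intervals,
    observed_length = L_obs,
    n_mn = n
  )
  list(specimen = specimen, truth = truth)
}

#' Generate a synthetic cohort
#'
#' @param cfg a [GeneratorConfig-class].
#' @param n_specimens cohort size (`>= 1`).
#' @param seed master seed; each specimen derives its own stream from
#'   `(seed, index)`, so cohorts are reproducible and order-independent.
#' @return list with `set` (a [SpecimenSet-class] whose provenance echoes
#'   the configuration and seed) and `truth` (list of per-specimen ground
#'   truths, named by specimen id).
#' @export
generateCohort <- function(cfg, n_specimens, seed = 1L) {
  stopifnot(n_specimens >= 1L)
  gen <- lapply(seq_len(n_specimens), function(i) generateSpecimen(cfg, i, seed))
  specimens <- lapply(gen, `[[`, "specimen")
  truths <- lapply(gen, `[[`, "truth")
  names(truths) <- vapply(specimens, specimenId, character(1))
  set <- SpecimenSet(specimens,
                     provenance = list(generator = generatorAsList(cfg),
                                       seed = seed, n_specimens = n_specimens))
  list(set = set, truth = truths)
}

#' Serialize a GeneratorConfig to a plain list (for provenance / YAML)
#'
#' @param cfg a [GeneratorConfig-class].
#' @return a nested list of plain values.
#' @export
generatorAsList <- function(cfg) {
  list(n_mn = cfg@nMn, count_sd = cfg@countSd, d0 = cfg@d0, step = cfg@step,
       pos_noise_sd = cfg@posNoiseSd, n_gmc = cfg@nGmc,
       genotype = cfg@genotype, stage = cfg@stage,
       truncation = cfg@truncation,
       tf_specs = lapply(cfg@tfSpecs, function(sp) {
         list(intervals = lapply(sp$intervals, as.integer),
              p_in = sp$p_in, p_out = sp$p_out, jitter = sp$jitter)
       }))
}

#' Census of cell classes across a cohort
#'
#' @param x a [SpecimenSet-class].
#' @return list with `per_specimen` (`data.frame`: one row per specimen,
#'   one column per cell class) and `summary` (`data.frame`: per class
#'   mean and SD across specimens); both empty for an empty set.
#' @name census
#' @export
setMethod("census", "SpecimenSet", function(x) {
  if (!length(x@specimens)) {
    return(list(per_specimen = data.frame(), summary = data.frame()))
  }
  per <- do.call(rbind, lapply(x@specimens, function(s) {
    counts <- table(factor(s@cells$cell_class, levels = .CELL_CLASSES))
    as.data.frame(rbind(counts))
  }))
  rownames(per) <- specimenIds(x)
  keep <- colSums(per) > 0
  per <- per[, keep, drop = FALSE]
  summ <- data.frame(
    cell_class = colnames(per),
    mean = colMeans(per),
    sd = apply(per, 2L, stats::sd),
    row.names = NULL
  )
  list(per_specimen = per, summary = summ)
})
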