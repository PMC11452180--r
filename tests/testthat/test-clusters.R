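triangle_peak <- function() {
  # symmetric triangular hump centred at rank 20 on a 40-rank axis
  x <- pmax(0, 0.8 - 0.1 * abs(1:40 - 20))
  pk <- partitionRegions(findPeaks(x), x)
  list(x = x, pk = pk)
}

test_that("mean positive counts follow the censoring-aware bookkeeping", {
  s1 <- seq_of(c(0, 0, 0, 1, 1, 1, 0, 0, 0))
  s2 <- seq_of(c(0, 0, 0, 1, 1, 1, 1, 0, 0, 0))
  expect_equal(meanPositiveCount(list(s1, s2), c(4, 9)), 3.5)
  # all-negative cohort
  expect_equal(meanPositiveCount(list(seq_of(rep(0, 10))), c(2, 6)), 0)
  # perfect planted block of width 5
  blk <- seq_of(c(0, 0, 1, 1, 1, 1, 1, 0))
  expect_equal(meanPositiveCount(list(blk, blk), c(1, 8)), 5)
  # a short sequence contributes only its observed ranks
  expect_equal(meanPositiveCount(list(seq_of(c(1, 1)), seq_of(c(1, 1, 1, 1))),
                                 c(1, 4)), 3)
  expect_error(meanPositiveCount(list(s1), c(5, 4)), "interval")
})

test_that("level-set placement on a symmetric triangle matches hand computation", {
  tri <- triangle_peak()
  # integer n: clean span, unit coverage everywhere
  cl5 <- placeCluster(tri$x, tri$pk, 5)
  expect_equal(cl5@bounds, c(17.5, 22.5))
  expect_equal(cl5@coreSpan, c(18L, 22L))
  expect_equal(unname(cl5@coverage), rep(1, 5))
  # fractional n: borders carry the remainder symmetrically
  cl46 <- placeCluster(tri$x, tri$pk, 4.6)
  expect_equal(cl46@coreSpan, c(19L, 21L))
  expect_equal(cl46@coverage[["18"]], 0.8, tolerance = 1e-9)
  expect_equal(cl46@coverage[["22"]], 0.8, tolerance = 1e-9)
  expect_equal(sum(cl46@coverage), 4.6, tolerance = 1e-9)
  expect_equal(clusterSpan(cl46), c(18L, 22L))
  # n = 0: empty call
  cl0 <- placeCluster(tri$x, tri$pk, 0)
  expect_length(cl0@bounds, 0)
  expect_length(cl0@coverage, 0)
})

test_that("n exceeding the region width saturates it with a warning", {
  x <- c(0, 0.25, 0.5, 0.25, 0)
  pk <- partitionRegions(findPeaks(x), x)
  expect_warning(cl <- placeCluster(x, pk, 7), "saturates")
  expect_equal(unname(cl@coverage), rep(1, 5))
  expect_equal(cl@coreSpan, c(1L, 5L))
})

test_that("an asymmetric cut splits the remainder proportionally to the overhang", {
  # plateau shoulder to the right of the peak: at the cut level the
  # super-level interval is [2, 6], width 4; n = 2 sits halfway down
  x <- c(0, 0.5, 1, 0.5, 0.5, 0.5, 0)
  pk <- data.frame(position = 3L, height = 1, prominence = 1,
                   region_start = 1L, region_end = 7L)
  cl <- placeCluster(x, pk, 2)
  # overhang left: 1 rank, right: 3 ranks -> remainder split 1:3
  expect_equal(cl@bounds, c(2.5, 4.5), tolerance = 1e-9)
  expect_equal(sum(cl@coverage), 2, tolerance = 1e-9)
})

test_that("coverage always sums to n and never exceeds 1 per rank", {
  set.seed(47)
  for (rep in 1:50) {
    f <- stats::runif(sample(10:50, 1))
    sm <- pmin(1, pmax(0, oracle_savgol(f, min(11L, length(f) - !(length(f) %% 2)), 3L)))
    pk <- partitionRegions(findPeaks(sm, peakConfig(0.1, 4, 0.02)), sm)
    for (i in seq_len(nrow(pk))) {
      wmax <- pk$region_end[i] - pk$region_start[i] + 1
      n <- stats::runif(1, 0, wmax)
      cl <- placeCluster(sm, pk[i, ], n)
      if (!length(cl@coverage)) next
      expect_equal(sum(cl@coverage), n, tolerance = 1e-9)
      expect_true(all(cl@coverage <= 1 + 1e-9))
      # cluster stays inside its region
      expect_gte(cl@bounds[1], pk$region_start[i] - 0.5 - 1e-9)
      expect_lte(cl@bounds[2], pk$region_end[i] + 0.5 + 1e-9)
    }
  }
})

test_that("zero-noise planted blocks are recovered exactly, one and two clusters", {
  # single mid-lineage block
  coh1 <- generateCohort(block_config(c(16, 23)), 20, seed = 1)
  calls1 <- detectClusters(orderSequences(coh1$set, "X"))
  expect_length(calls1, 1)
  expect_equal(calls1[[1]]@n, 8)
  expect_equal(clusterSpan(calls1[[1]]), c(16L, 23L))
  expect_equal(calls1[[1]]@bounds, c(15.5, 23.5), tolerance = 1e-9)

  # two blocks separated by more than d_min
  coh2 <- generateCohort(block_config(list(c(5, 11), c(27, 33))), 20, seed = 1)
  calls2 <- detectClusters(orderSequences(coh2$set, "X"))
  expect_length(calls2, 2)
  expect_equal(vapply(calls2, function(cl) cl@n, numeric(1)), c(7, 7))
  expect_equal(clusterSpan(calls2[[1]]), c(5L, 11L))
  expect_equal(clusterSpan(calls2[[2]]), c(27L, 33L))

  # all-negative cohort: no clusters at all
  coh0 <- generateCohort(block_config(c(16, 23), p_in = 0, p_out = 0), 20, seed = 1)
  calls0 <- detectClusters(orderSequences(coh0$set, "X"))
  expect_length(calls0, 0)
})

test_that("code maps assemble coverage per rank with a supernumerary annex", {
  tri <- triangle_peak()
  jim <- placeCluster(tri$x, tri$pk, 5, tf = "Jim")    # ranks 18..22
  x2 <- pmax(0, 0.8 - 0.1 * abs(1:40 - 28))
  pk2 <- partitionRegions(findPeaks(x2), x2)
  nvy <- placeCluster(x2, pk2, 8, tf = "Nvy")          # bounds [24, 32]
  map <- assembleCodeMap(list(jim, nvy), max_birth_order = 29L,
                         condition = "control")
  m <- membership(map)
  expect_equal(unname(m["20", ]), c(1, 0))
  expect_equal(unname(m["26", ]), c(0, 1))
  expect_equal(nrow(annex(map)), 3)                    # ranks 30..32
  expect_equal(unname(annex(map)["31", "Nvy"]), 1)
  # the even-n cut on an integer apex leaves half-covered borders
  expect_equal(unname(annex(map)["32", "Nvy"]), 0.5, tolerance = 1e-9)
  # fractional borders propagate into the map
  frac <- placeCluster(tri$x, tri$pk, 4.6, tf = "Frac")
  mapf <- assembleCodeMap(list(frac))
  expect_equal(unname(membership(mapf)["18", "Frac"]), 0.8, tolerance = 1e-9)
  # empty input: all-zero map
  map0 <- assembleCodeMap(list(), tfs = "Jim")
  expect_true(all(membership(map0) == 0))
  # overlapping duplicate calls for one TF are rejected
  expect_error(assembleCodeMap(list(jim, jim)), "conflicting duplicate")
})

test_that("code-map comparison flags extensions and lost clusters", {
  tri <- triangle_peak()
  jim_a <- placeCluster(tri$x, tri$pk, 5, tf = "Jim")
  xx <- pmax(0, 0.9 - 0.06 * abs(1:40 - 24))
  pkx <- partitionRegions(findPeaks(xx), xx)
  jim_b <- placeCluster(xx, pkx, 12, tf = "Jim")       # extends to rank ~30
  x2 <- pmax(0, 0.8 - 0.1 * abs(1:40 - 8))
  pk2 <- partitionRegions(findPeaks(x2), x2)
  runx <- placeCluster(x2, pk2, 6, tf = "RunxA")

  map_a <- assembleCodeMap(list(jim_a, runx), condition = "control")
  map_b1 <- assembleCodeMap(list(jim_b, runx), condition = "perturbed",
                            tfs = c("Jim", "RunxA"))
  cmp <- compareCodeMaps(map_a, map_b1)
  expect_equal(cmp$Jim$delta_total, 7, tolerance = 1e-9)
  expect_gte(cmp$Jim$proximal_extension, 7)
  expect_length(cmp$RunxA$lost, 0)

  # dropping RunxA's cluster is reported as a loss
  map_b2 <- assembleCodeMap(list(jim_a), condition = "perturbed",
                            tfs = c("Jim", "RunxA"))
  cmp2 <- compareCodeMaps(map_a, map_b2)
  expect_length(cmp2$RunxA$lost, 1)
  expect_equal(cmp2$RunxA$delta_total, -6, tolerance = 1e-9)

  # identical maps: all deltas zero
  cmp3 <- compareCodeMaps(map_a, map_a)
  for (tf in names(cmp3)) {
    expect_equal(cmp3[[tf]]$delta_total, 0)
    expect_true(all(cmp3[[tf]]$delta_rank == 0))
    expect_length(cmp3[[tf]]$lost, 0)
    expect_length(cmp3[[tf]]$gained, 0)
  }
  # mismatched panels are refused
  map_c <- assembleCodeMap(list(jim_a), tfs = "Jim")
  expect_error(compareCodeMaps(map_a, map_c), "panel")
})
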