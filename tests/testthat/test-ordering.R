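test_that("normalization translates the reference cell to the origin", {
  sp <- toy_specimen()
  norm <- normalizeToReference(sp)
  cells <- cellTable(norm)
  expect_equal(unlist(cells[cells$cell_id == "nb", c("x_um", "y_um", "z_um")]),
               c(x_um = 0, y_um = 0, z_um = 0))
  expect_equal(unlist(cells[cells$cell_id == "m3", c("x_um", "y_um", "z_um")]),
               c(x_um = 10, y_um = 0, z_um = 0))
  # idempotent once at the origin
  expect_equal(cellTable(normalizeToReference(norm)), cells)
  # classes and calls untouched
  expect_identical(tfCalls(norm), tfCalls(sp))
})

test_that("normalization is an isometry (pairwise distances preserved)", {
  set.seed(7)
  coh <- generateCohort(generatorConfig(), 1, seed = 7)
  sp <- coh$set[[1]]
  d_before <- dist(cellTable(sp)[, c("x_um", "y_um", "z_um")])
  d_after <- dist(cellTable(normalizeToReference(sp))[, c("x_um", "y_um", "z_um")])
  expect_equal(as.numeric(d_after), as.numeric(d_before), tolerance = 1e-12)
})

test_that("distances to the reference follow the Euclidean norm", {
  sp <- toy_specimen()
  d <- distanceToReference(sp)
  expect_equal(unname(d["nb"]), 0)
  expect_equal(unname(d["m3"]), 10)       # (10, 0, 0)
  expect_equal(unname(d["gl"]), sqrt(5))  # (1, 2, 0)
  # random coordinates against an independent norm computation
  set.seed(11)
  coh <- generateCohort(generatorConfig(), 1, seed = 11)
  sp2 <- normalizeToReference(coh$set[[1]])
  cells <- cellTable(sp2)
  brute <- apply(as.matrix(cells[, c("x_um", "y_um", "z_um")]), 1,
                 function(v) sqrt(sum(v^2)))
  expect_equal(unname(distanceToReference(sp2)), unname(brute),
               tolerance = 1e-12)
})

test_that("a missing reference cell gives an actionable error", {
  cells <- data.frame(cell_id = c("m1", "m2"), cell_class = c("MN", "MN"),
                      x_um = c(1, 2), y_um = 0, z_um = 0)
  expect_error(Specimen("S1", cells), "reference")
  sp <- Specimen("S1", cells, reference_cell_id = "m1")
  expect_equal(unname(distanceToReference(sp)["m2"]), 1)
})

test_that("orderSequence ranks MNs by descending distance, rank 1 furthest", {
  sp <- toy_specimen()
  s <- orderSequence(sp, "Jim")
  expect_s4_class(s, "OrderedSequence")
  expect_equal(s@cellIds, c("m1", "m2", "m3"))   # 30, 20, 10 um
  expect_equal(s@calls, c(FALSE, TRUE, TRUE))
  expect_equal(s@distances, c(30, 20, 10))
  expect_error(orderSequence(sp, "Nvy"), "not stained")
})

test_that("distance ties break by ascending cell_id, deterministically", {
  cells <- data.frame(cell_id = c("nb", "b", "a"), cell_class = c("NB", "MN", "MN"),
                      x_um = c(0, 20, 20), y_um = 0, z_um = 0)
  calls <- matrix(c(NA, TRUE, FALSE), ncol = 1,
                  dimnames = list(cells$cell_id, "Jim"))
  sp <- Specimen("S1", cells, calls)
  s1 <- orderSequence(sp, "Jim")
  expect_equal(s1@cellIds, c("a", "b"))
  expect_identical(orderSequence(sp, "Jim")@cellIds, s1@cellIds)
})

test_that("ordering agrees with a brute-force stable sort on (-distance, id)", {
  set.seed(13)
  coh <- generateCohort(block_config(c(16, 23), p_in = 0.9, p_out = 0.02,
                                     jitter = 1L, pos_noise_sd = 3),
                        3, seed = 13)
  for (sp in specimens(coh$set)) {
    s <- orderSequence(sp, "X")
    cells <- cellTable(sp)
    mn <- cells$cell_id[cells$cell_class == "MN"]
    d <- distanceToReference(sp)[mn]
    expect_identical(s@cellIds, mn[order(-d, mn)])
    # permutation: every eligible cell exactly once
    expect_setequal(s@cellIds, mn)
    # monotone contract
    expect_true(all(diff(s@distances) <= 1e-9))
  }
})

test_that("non-MN cells and apoptotic cells never affect the MN ordering", {
  sp <- toy_specimen()
  base <- orderSequence(sp, "Jim")
  cells2 <- rbind(cellTable(sp),
                  data.frame(cell_id = c("g2", "ap"), cell_class = c("GMC", "apoptotic"),
                             x_um = c(28, 22), y_um = 5, z_um = 5))
  calls2 <- rbind(tfCalls(sp), matrix(c(TRUE, TRUE), ncol = 1,
                                      dimnames = list(c("g2", "ap"), "Jim")))
  sp2 <- Specimen("T1", cells2, calls2)
  expect_identical(orderSequence(sp2, "Jim")@cellIds, base@cellIds)
  # apoptotic cells can be pulled in explicitly
  withapo <- orderSequence(sp2, "Jim", include_apoptotic = TRUE)
  expect_true("ap" %in% withapo@cellIds)
})

test_that("a specimen with no eligible cells yields an empty sequence with a warning", {
  cells <- data.frame(cell_id = c("nb", "g1"), cell_class = c("NB", "glia"),
                      x_um = c(0, 1), y_um = 0, z_um = 0)
  calls <- matrix(c(NA, TRUE), ncol = 1, dimnames = list(cells$cell_id, "Jim"))
  sp <- Specimen("S1", cells, calls)
  expect_warning(s <- orderSequence(sp, "Jim"), "no eligible")
  expect_length(s@calls, 0)
})
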