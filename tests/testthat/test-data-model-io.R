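write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("long-format tables parse with per-specimen TF panels", {
  path <- write_lines_tmp(c(
    "specimen_id\tcell_id\tclass\tx_um\ty_um\tz_um\ttf\tcall",
    "S1\tnb\tNB\t0\t0\t0\t\t",
    "S1\tm1\tMN\t10\t0\t0\tJim\t1",
    "S1\tm2\tMN\t5\t0\t0\tJim\t0",
    "S2\tnb\tNB\t1\t1\t1\t\t",
    "S2\tm1\tMN\t8\t1\t1\tNvy\t1"
  ))
  set <- loadSpecimens(path)
  expect_equal(length(set), 2L)
  expect_equal(stainedTFs(set[["S1"]]), "Jim")
  expect_equal(stainedTFs(set[["S2"]]), "Nvy")
  # a TF absent from a specimen is not stained there -- not FALSE
  expect_false("Nvy" %in% stainedTFs(set[["S1"]]))
  expect_equal(unname(tfStainCounts(set)), c(1L, 1L))
  # the NB call field is empty: assessed-missing, never coerced to FALSE
  expect_true(is.na(tfCalls(set[["S1"]])["nb", "Jim"]))
  expect_identical(unname(tfCalls(set[["S1"]])[c("m1", "m2"), "Jim"]),
                   c(TRUE, FALSE))
})

test_that("duplicate and malformed rows are rejected with precise messages", {
  dup <- write_lines_tmp(c(
    "specimen_id\tcell_id\tclass\tx_um\ty_um\tz_um\ttf\tcall",
    "S1\tnb\tNB\t0\t0\t0\tJim\t",
    "S1\tc3\tMN\t10\t0\t0\tJim\t1",
    "S1\tc3\tMN\t10\t0\t0\tJim\t1"
  ))
  expect_error(loadSpecimens(dup), "duplicate cell_id c3 in S1")

  badnum <- write_lines_tmp(c(
    "specimen_id\tcell_id\tclass\tx_um\ty_um\tz_um\ttf\tcall",
    "S1\tnb\tNB\t0\t0\t0\tJim\t",
    "S1\tm1\tMN\ttwelve\t0\t0\tJim\t1"
  ))
  expect_error(loadSpecimens(badnum), "non-numeric coordinate.*row 3")

  badclass <- write_lines_tmp(c(
    "specimen_id\tcell_id\tclass\tx_um\ty_um\tz_um\ttf\tcall",
    "S1\tnb\tNB\t0\t0\t0\tJim\t",
    "S1\tm1\tmotoneuron\t1\t0\t0\tJim\t1"
  ))
  expect_error(loadSpecimens(badclass), "unknown cell class")

  missingcol <- write_lines_tmp(c("specimen_id\tcell_id", "S1\tnb"))
  expect_error(loadSpecimens(missingcol), "required column")
})

test_that("wide format is accepted; an all-empty TF column means not stained", {
  path <- write_lines_tmp(c(
    "specimen_id\tcell_id\tclass\tx_um\ty_um\tz_um\tJim\tNvy",
    "S1\tnb\tNB\t0\t0\t0\t\t",
    "S1\tm1\tMN\t10\t0\t0\t1\t",
    "S1\tm2\tMN\t5\t0\t0\t0\t",
    "S2\tnb\tNB\t0\t0\t0\t\t",
    "S2\tm1\tMN\t8\t0\t0\t1\t1"
  ))
  set <- loadSpecimens(path)
  expect_equal(stainedTFs(set[["S1"]]), "Jim")   # Nvy column empty in S1
  expect_setequal(stainedTFs(set[["S2"]]), c("Jim", "Nvy"))
})

test_that("write + load round-trips a cohort losslessly", {
  cfg <- genotypePreset("control")
  coh <- generateCohort(cfg, 3, seed = 5)
  # knock out one call to exercise assessed-missing serialization
  sp1 <- coh$set[[1]]
  sp1@calls[which(sp1@cells$cell_class == "MN")[1], "Jim"] <- NA
  set <- SpecimenSet(c(list(sp1), specimens(coh$set)[-1]),
                     provenance = coh$set@provenance)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cells.tsv")
  writeSpecimens(set, path)
  back <- loadSpecimens(path)
  expect_equal(specimenIds(back), specimenIds(set))
  for (id in specimenIds(set)) {
    expect_equal(cellTable(back[[id]]), cellTable(set[[id]]),
                 ignore_attr = TRUE)
    expect_identical(tfCalls(back[[id]]), tfCalls(set[[id]]))
    expect_equal(genotype(back[[id]]), genotype(set[[id]]))
    expect_equal(stage(back[[id]]), stage(set[[id]]))
    expect_equal(referenceCellId(back[[id]]), referenceCellId(set[[id]]))
  }
})

test_that("code maps serialize to a rank table and a JSON report that round-trips", {
  x <- pmax(0, 0.8 - 0.1 * abs(1:40 - 20))
  pk <- partitionRegions(findPeaks(x), x)
  cl <- placeCluster(x, pk, 8, tf = "Jim")   # bounds [16, 24]
  map <- assembleCodeMap(list(cl), condition = "control")
  dir <- withr::local_tempdir()
  paths <- writeCodeMap(map, file.path(dir, "codemap.tsv"))
  tab <- read.delim(paths[["table"]])
  expect_equal(tab$Jim[17:23], rep(1, 7))
  expect_equal(tab$Jim[c(16, 24)], c(0.5, 0.5))
  expect_equal(sum(tab$Jim), 8)
  back <- codeMapFromReport(paths[["report"]])
  expect_equal(membership(back), membership(map))
  expect_equal(annex(back), annex(map))
  expect_equal(back@condition, "control")
  # degenerate: empty map still writes a valid pair
  map0 <- assembleCodeMap(list(), tfs = "Jim")
  paths0 <- writeCodeMap(map0, file.path(dir, "empty.tsv"))
  rep0 <- readCodeMapReport(paths0[["report"]])
  expect_length(rep0$clusters, 0)
  expect_true(all(read.delim(paths0[["table"]])$Jim == 0))
})
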