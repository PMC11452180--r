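setMethod("show", "Specimen", function(object) {
  cls <- table(object@cells$cell_class)
  cat(sprintf("Specimen '%s' (%s, %s): %d cells [%s]\n",
              object@specimenId, object@genotype, object@stage,
              nrow(object@cells),
              paste(sprintf("%s:%d", names(cls), cls), collapse = " ")))
  cat(sprintf("  stained TFs: %s; reference cell: %s\n",
              if (ncol(object@calls)) paste(colnames(object@calls), collapse = ", ")
              else "<none>",
              object@referenceCellId))
})

setMethod("show", "SpecimenSet", function(object) {
  cat(sprintf("SpecimenSet with %d specimen(s)\n", length(object@specimens)))
  cnt <- tfStainCounts(object)
  if (length(cnt)) {
    cat("  specimens stained per TF:",
        paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), "\n")
  }
})

setMethod("show", "OrderedSequence", function(object) {
  cat(sprintf("OrderedSequence %s / %s, L = %d (rank 1 = furthest from NB)\n",
              object@specimenId, object@tf, length(object@calls)))
  if (length(object@calls)) {
    cat("  calls:", paste(as.integer(object@calls), collapse = ""), "\n")
  }
})

setMethod("show", "FrequencyProfile", function(object) {
  cat(sprintf("FrequencyProfile for %s: L_max = %d, N = %d sequences, mode = %s%s\n",
              object@tf, length(object@f), object@NTotal, object@mode,
              if (length(object@fSmooth)) ", smoothed" else ""))
})

setMethod("show", "ClusterCall", function(object) {
  if (!length(object@bounds)) {
    cat(sprintf("ClusterCall for %s: empty (n = %g)\n", object@tf, object@n))
  } else {
    core <- if (length(object@coreSpan)) {
      sprintf("[%d, %d]", object@coreSpan[1L], object@coreSpan[2L])
    } else "<none>"
    cat(sprintf("ClusterCall for %s: n = %.3f, core span %s, bounds [%.2f, %.2f]\n",
                object@tf, object@n, core, object@bounds[1L], object@bounds[2L]))
  }
})

setMethod("show", "TFCodeMap", function(object) {
  cat(sprintf("TFCodeMap (%s): birth orders 1-%d x %d TF(s)%s\n",
              object@condition, object@maxBirthOrder, ncol(object@membership),
              if (nrow(object@annex)) sprintf(", %d supernumerary rank(s) in annex",
                                              nrow(object@annex)) else ""))
  for (tf in colnames(object@membership)) {
    cov <- c(object@membership[, tf], object@annex[, tf])
    pos <- which(cov > 1e-9)
    cat(sprintf("  %s: total expected positives %.2f%s\n", tf, sum(cov),
                if (length(pos)) sprintf(", ranks %d-%d", min(pos), max(pos)) else ""))
  }
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf("GeneratorConfig (%s, %s): nMn = %g +/- %g, d0 = %g um, step = %g um, pos noise %g um\n",
              object@genotype, object@stage, object@nMn, object@countSd,
              object@d0, object@step, object@posNoiseSd))
  for (tf in names(object@tfSpecs)) {
    sp <- object@tfSpecs[[tf]]
    ivs <- vapply(sp$intervals, function(iv) sprintf("[%d,%d]", iv[1L], iv[2L]), character(1))
    cat(sprintf("  %s: intervals %s, p_in = %s, p_out = %g, jitter = %d\n",
                tf, paste(ivs, collapse = " "),
                paste(rep(sp$p_in, length.out = length(ivs)), collapse = "/"),
                sp$p_out, sp$jitter))
  }
})

setMethod("show", "PCCDResult", function(object) {
  cat(sprintf("PCCDResult: %d TF(s) processed\n", length(object@profiles)))
  for (tf in names(object@profiles)) {
    ncl <- length(object@clusters[[tf]])
    ns <- vapply(object@clusters[[tf]], function(cl) cl@n, numeric(1))
    cat(sprintf("  %s: N = %d, %d peak(s), n = %s\n", tf,
                object@profiles[[tf]]@NTotal, ncl,
                if (ncl) paste(sprintf("%.2f", ns), collapse = ", ") else "-"))
  }
  show(object@codeMap)
})
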