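#' Assemble cluster calls into a combinatorial TF code map
#'
#' Collects the coverage of every [ClusterCall-class] onto a common
#' birth-order axis.  Ranks 1..`max_birth_order` (default 29, the adult
#' survivor count of the lineage) form the main membership matrix; deeper
#' ranks — supernumerary, typically death-fated cells present in larval
#' cohorts — are kept in a separate annex rather than rescaled.
#'
#' @param calls list of [ClusterCall-class] from one cohort (possibly
#'   several per TF for multi-peak factors).
#' @param max_birth_order length of the main birth-order axis.
#' @param condition genotype/condition label of the cohort.
#' @param tfs optional character vector fixing the TF panel (columns);
#'   defaults to the TFs present in `calls`.
#' @return a [TFCodeMap-class].
#' @export
assembleCodeMap <- function(calls, max_birth_order = 29L,
                            condition = "unknown", tfs = NULL) {
  max_birth_order <- as.integer(max_birth_order)
  if (is.null(tfs)) tfs <- unique(vapply(calls, function(cl) cl@tf, character(1)))
  tfs <- as.character(tfs)
  ranks_used <- unlist(lapply(calls, function(cl) as.integer(names(cl@coverage))))
  n_annex <- max(0L, c(ranks_used, 0L) - max_birth_order)
  mem <- matrix(0, nrow = max_birth_order, ncol = length(tfs),
                dimnames = list(seq_len(max_birth_order), tfs))
  anx <- matrix(0, nrow = n_annex, ncol = length(tfs),
                dimnames = list(max_birth_order + seq_len(n_annex), tfs))
  for (cl in calls) {
    if (!cl@tf %in% tfs) stop("call for TF '", cl@tf, "' outside the fixed panel")
    rks <- as.integer(names(cl@coverage))
    for (k in seq_along(rks)) {
      r <- rks[k]
      tgt <- if (r <= max_birth_order) mem[r, cl@tf] else anx[r - max_birth_order, cl@tf]
      if (tgt > 1e-9) {
        stop(sprintf("conflicting duplicate calls for TF '%s' at rank %d", cl@tf, r))
      }
      if (r <= max_birth_order) mem[r, cl@tf] <- cl@coverage[k]
      else anx[r - max_birth_order, cl@tf] <- cl@coverage[k]
    }
  }
  new("TFCodeMap", membership = mem, annex = anx, condition = condition,
      maxBirthOrder = max_birth_order, calls = calls)
}

# full coverage matrix: main axis plus annex, padded to a common depth
.fullCoverage <- function(map, depth) {
  m <- rbind(map@membership, map@annex)
  if (nrow(m) < depth) {
    pad <- matrix(0, nrow = depth - nrow(m), ncol = ncol(m),
                  dimnames = list(nrow(m) + seq_len(depth - nrow(m)), colnames(m)))
    m <- rbind(m, pad)
  }
  rownames(m) <- seq_len(nrow(m))
  m
}

# spans (continuous bounds and core) of the calls of one TF in a map
.tfSpans <- function(map, tf) {
  calls <- Filter(function(cl) cl@tf == tf && length(cl@bounds), map@calls)
  lapply(calls, function(cl) list(bounds = cl@bounds, core = cl@coreSpan, n = cl@n))
}

.overlap <- function(b1, b2) max(0, min(b1[2L], b2[2L]) - max(b1[1L], b2[1L]))

#' Compare two TF code maps (e.g. control vs perturbation)
#'
#' For every TF of the shared panel, reports the total expected number of
#' positive cells (sum of coverage) in each condition, the per-rank
#' coverage delta, the cluster spans, and flags clusters that are lost or
#' gained in `b` relative to `a` (matched by span overlap) as well as
#' extensions of matched clusters towards the NB-proximal (last-born,
#' high-rank) end.
#'
#' @param a,b [TFCodeMap-class] objects over the same TF panel.
#' @param extension_min minimal shift (ranks) of a matched cluster's
#'   proximal end counted as an extension (default 2).
#' @return an object of class `pccdShift`: a list with one entry per TF
#'   (`total_a`, `total_b`, `delta_total`, `delta_rank`, `spans_a`,
#'   `spans_b`, `lost`, `gained`, `proximal_extension`) plus a `conditions`
#'   attribute.
#' @export
compareCodeMaps <- function(a, b, extension_min = 2) {
  stopifnot(is(a, "TFCodeMap"), is(b, "TFCodeMap"))
  pa <- colnames(a@membership)
  pb <- colnames(b@membership)
  if (!setequal(pa, pb)) {
    stop("TF panels differ: only in a: {",
         paste(setdiff(pa, pb), collapse = ", "), "}; only in b: {",
         paste(setdiff(pb, pa), collapse = ", "), "}")
  }
  depth <- max(nrow(a@membership) + nrow(a@annex),
               nrow(b@membership) + nrow(b@annex))
  ma <- .fullCoverage(a, depth)
  mb <- .fullCoverage(b, depth)[, colnames(ma), drop = FALSE]
  out <- list()
  for (tf in colnames(ma)) {
    sa <- .tfSpans(a, tf)
    sb <- .tfSpans(b, tf)
    matched_b <- rep(FALSE, length(sb))
    lost <- list()
    ext <- 0
    for (cl in sa) {
      ov <- vapply(sb, function(o) .overlap(cl$bounds, o$bounds), numeric(1))
      if (!length(ov) || max(ov) <= 0) {
        lost <- c(lost, list(cl))
      } else {
        j <- which.max(ov)
        matched_b[j] <- TRUE
        ext <- max(ext, sb[[j]]$bounds[2L] - cl$bounds[2L])
      }
    }
    out[[tf]] <- list(
      total_a = sum(ma[, tf]), total_b = sum(mb[, tf]),
      delta_total = sum(mb[, tf]) - sum(ma[, tf]),
      delta_rank = mb[, tf] - ma[, tf],
      spans_a = sa, spans_b = sb,
      lost = lost, gained = sb[!matched_b],
      proximal_extension = if (ext >= extension_min) ext else 0
    )
  }
  attr(out, "conditions") <- c(a = a@condition, b = b@condition)
  class(out) <- "pccdShift"
  out
}

#' @export
print.pccdShift <- function(x, ...) {
  cond <- attr(x, "conditions")
  cat(sprintf("TF code shift: %s -> %s\n", cond[["a"]], cond[["b"]]))
  for (tf in names(x)) {
    e <- x[[tf]]
    flags <- character(0)
    if (length(e$lost)) flags <- c(flags, sprintf("%d cluster(s) lost", length(e$lost)))
    if (length(e$gained)) flags <- c(flags, sprintf("%d cluster(s) gained", length(e$gained)))
    if (e$proximal_extension > 0) {
      flags <- c(flags, sprintf("extended %.1f ranks towards last-born end",
                                e$proximal_extension))
    }
    cat(sprintf("  %s: expected positives %.2f -> %.2f (%+.2f)%s\n",
                tf, e$total_a, e$total_b, e$delta_total,
                if (length(flags)) paste0(" [", paste(flags, collapse = "; "), "]") else ""))
  }
  invisible(x)
}
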