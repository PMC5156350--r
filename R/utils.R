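# internal helpers

# Evaluate expr under a local seed without disturbing the caller's RNG;
# seed = NULL/NA uses the current RNG stream.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), expr)
}

# half-open [t0, t1) window -> sample indices on a time axis starting at
# tStart with the given rate (1-based); sample index = round((t - tStart)*rate)
windowIndices <- function(t0, t1, tStart, rate) {
  i0 <- round((t0 - tStart) * rate)
  i1 <- round((t1 - tStart) * rate)
  if (i1 <= i0) stop("empty window [", t0, ", ", t1, ")")
  seq.int(i0 + 1L, i1)
}

stampProvenance <- function(x, step) {
  x@provenance <- c(x@provenance, step)
  x
}

chkLabels <- function(labels) {
  bad <- !labels %in% c("remembered", "forgotten") & !is.na(labels)
  if (any(bad))
    stop("labels must be 'remembered' or 'forgotten'")
  invisible(labels)
}
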