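# Independent brute-force oracles for the texture matrices, written as
# plain triple loops / line walks so they share no code with the
# package implementation.

bruteGLCM <- function(gray, offset, levels = 256L) {
  d <- dim(gray)
  counts <- matrix(0L, levels, levels)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    g1 <- gray[i, j, k]
    if (is.na(g1)) next
    p2 <- c(i, j, k) + offset
    if (any(p2 < 1) || any(p2 > d)) next
    g2 <- gray[p2[1], p2[2], p2[3]]
    if (is.na(g2)) next
    counts[g1 + 1L, g2 + 1L] <- counts[g1 + 1L, g2 + 1L] + 1L
  }
  counts
}

# Line-walk oracle: a run starts wherever the backward neighbour is
# absent or differently valued, then extends forward.
bruteGLRLM <- function(gray, offset, levels = 256L) {
  d <- dim(gray)
  runs <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    g <- gray[i, j, k]
    if (is.na(g)) next
    pb <- c(i, j, k) - offset
    prev <- if (any(pb < 1) || any(pb > d)) NA
            else gray[pb[1], pb[2], pb[3]]
    if (!is.na(prev) && prev == g) next  # not a run start
    len <- 1L
    p <- c(i, j, k) + offset
    while (!any(p < 1) && !any(p > d) && !is.na(gray[p[1], p[2], p[3]]) &&
           gray[p[1], p[2], p[3]] == g) {
      len <- len + 1L
      p <- p + offset
    }
    runs[[length(runs) + 1L]] <- c(g, len)
  }
  rmax <- max(vapply(runs, `[`, integer(1), 2L))
  counts <- matrix(0L, levels, rmax)
  for (r in runs)
    counts[r[1] + 1L, r[2]] <- counts[r[1] + 1L, r[2]] + 1L
  counts
}

# Random quantized ROI on a small grid; maskProb < 1 gives an irregular
# mask (NA outside).
randomGrayROI <- function(dims, levels = 8L, maskProb = 1) {
  g <- array(sample.int(levels, prod(dims), replace = TRUE) - 1L, dims)
  if (maskProb < 1) {
    drop <- array(stats::runif(prod(dims)) > maskProb, dims)
    # keep at least one voxel
    if (all(drop)) drop[1] <- FALSE
    g[drop] <- NA
  }
  g
}
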