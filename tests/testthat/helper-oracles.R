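# Independent brute-force oracles and small fixture builders used across the
# test files. The oracles deliberately avoid the package's own code paths.

# HiPix by literal definition: sort every ExpNucl pixel, average the top k,
# subtract the exact cell median.
oracle_hipix <- function(frame, expnucl, cell, k = 20) {
  v <- sort(frame[expnucl], decreasing = TRUE)
  mean(v[seq_len(min(k, length(v)))]) - median(frame[cell])
}

# ConnectedHiPix through EBImage: full-frame binary top-k mask, morphological
# opening with a diamond (cross) brush, 4-connected labelling upgraded to
# 8-connectivity by merging diagonally touching labels.
oracle_connected_hipix <- function(frame, expnucl, k = 20) {
  idx <- which(expnucl)
  v <- frame[idx]
  ord <- order(-v, idx)
  top <- idx[ord[seq_len(min(k, length(idx)))]]
  mask <- matrix(0, nrow(frame), ncol(frame))
  mask[top] <- 1
  opened <- EBImage::opening(EBImage::Image(mask), EBImage::makeBrush(3, "diamond"))
  opened <- matrix(as.numeric(opened) > 0.5, nrow(frame), ncol(frame))
  if (!any(opened)) return(NA_real_)
  lab <- matrix(as.integer(EBImage::bwlabel(opened)), nrow(frame), ncol(frame))
  # merge 4-connected labels that touch diagonally
  repeat {
    merged <- FALSE
    nr <- nrow(lab); nc <- ncol(lab)
    for (dr in c(-1, 1)) for (dc in c(-1, 1)) {
      r1 <- max(1, 1 + dr):min(nr, nr + dr)
      a <- lab[r1 - dr, max(1, 1 + dc):min(nc, nc + dc) - dc]
      b <- lab[r1, max(1, 1 + dc):min(nc, nc + dc)]
      pair <- a > 0 & b > 0 & a != b
      if (any(pair)) {
        i <- which(pair)[1]
        lab[lab == max(a[i], b[i])] <- min(a[i], b[i])
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  ids <- sort(unique(lab[lab > 0]))
  sizes <- vapply(ids, function(i) sum(lab == i), 0L)
  big <- ids[sizes == max(sizes)]
  if (length(big) > 1) {
    bright <- vapply(big, function(i) max(frame[lab == i]), 0)
    big <- big[which.max(bright)]
  }
  mean(frame[lab == big])
}

# Burst filtering by independent re-implementation: fresh full scans over a
# plain list of candidate indices, merging the first failing boundary and
# restarting, then the fifth-of-max prune.
oracle_filter_peaks <- function(cand_idx, y, time_min, start, end) {
  idx <- cand_idx
  while (length(idx) >= 2) {
    bad <- NULL
    for (i in seq_len(length(idx) - 1)) {
      a <- idx[i]; b <- idx[i + 1]
      between <- if (b - a >= 2) (a + 1):(b - 1) else c(a, b)
      tr <- min(y[between])
      if (!((y[a] - tr) > y[a] / 4 && (y[b] - tr) > tr / 3)) { bad <- i; break }
    }
    if (is.null(bad)) break
    a <- idx[bad]; b <- idx[bad + 1]
    keep <- if (y[b] > y[a]) b else a
    idx <- sort(c(setdiff(idx, c(a, b)), keep))
  }
  if (length(idx)) {
    win <- time_min >= start & time_min <= end
    idx <- idx[y[idx] >= max(y[win], na.rm = TRUE) / 5]
  }
  idx
}

# tidy trace table from intensity/observation matrices
traces_from_matrices <- function(hipix, connected, grid) {
  n <- nrow(hipix)
  data.frame(
    cell_id = rep(seq_len(n), each = grid$n_frames),
    frame = rep(seq_len(grid$n_frames), n),
    time_min = rep(grid$time_min, n),
    hipix = as.vector(t(hipix)),
    connected_hipix = as.vector(t(connected)),
    valid = TRUE
  )
}

# detection vector with given detected frame indices
detections_at <- function(frames, n = 100, value = 50) {
  x <- rep(NA_real_, n)
  x[frames] <- value
  x
}
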