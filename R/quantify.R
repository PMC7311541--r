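#' HiPix: brightest-pixel transcription-site statistic
#'
#' The mean of the `k` brightest pixels inside the expanded-nucleus region
#' minus the median pixel value of the whole cell. The statistic is close to
#' zero when no transcription site is present and rises by up to a few
#' hundred counts when nascent transcripts accumulate; subtracting the cell
#' median makes it invariant to adding a constant to the frame.
#'
#' @param frame projected image matrix.
#' @param expnucl logical mask (or label matrix == id) of the ExpNucl region.
#' @param cell logical mask of the whole cell.
#' @param k number of brightest pixels averaged.
#' @return scalar with attribute `flag` = "short" if the region held fewer
#'   than `k` pixels; `NA` with flag "empty" for an empty region.
#' @export
hipix <- function(frame, expnucl, cell, k = 20) {
  hipix_core(frame[expnucl], frame[cell], k)
}

hipix_core <- function(v_en, v_cell, k) {
  if (!length(v_en)) return(structure(NA_real_, flag = "empty"))
  top <- sort(v_en, decreasing = TRUE)[seq_len(min(k, length(v_en)))]
  out <- mean(top) - stats::median(v_cell)
  if (length(v_en) < k) attr(out, "flag") <- "short"
  out
}

# top-k pixel linear indices within idx, ordered by frame value (desc),
# ties by linear index (asc)
topk_idx <- function(frame, idx, k) {
  if (!length(idx)) return(integer())
  v <- frame[idx]
  ord <- order(-v, idx)
  idx[ord[seq_len(min(k, length(idx)))]]
}

# binary opening of a pixel set given as linear indices (H = image height);
# structuring element: 3x3 cross (4-neighbourhood) or 3x3 box. Opening is
# anti-extensive, so the result is a subset of the input set.
open_pixel_set <- function(idx, H, npix, se = c("cross", "box")) {
  se <- match.arg(se)
  if (!length(idx)) return(integer())
  row <- (idx - 1L) %% H + 1L
  inset <- logical(npix)
  inset[idx] <- TRUE
  has <- function(j, ok) ok & j >= 1L & j <= npix & inset[pmax(pmin(j, npix), 1L)]
  core <- has(idx - 1L, row > 1L) & has(idx + 1L, row < H) &
          has(idx - H, TRUE) & has(idx + H, TRUE)
  if (se == "box") {
    core <- core &
      has(idx - 1L - H, row > 1L) & has(idx - 1L + H, row > 1L) &
      has(idx + 1L - H, row < H) & has(idx + 1L + H, row < H)
  }
  eroded <- idx[core]
  if (!length(eroded)) return(integer())
  er <- (eroded - 1L) %% H + 1L
  nb <- c(eroded,
          eroded[er > 1L] - 1L, eroded[er < H] + 1L,
          eroded - H, eroded + H)
  if (se == "box")
    nb <- c(nb,
            eroded[er > 1L] - 1L - H, eroded[er > 1L] - 1L + H,
            eroded[er < H] + 1L - H, eroded[er < H] + 1L + H)
  nb <- nb[nb >= 1L & nb <= npix]
  sort(unique(nb[inset[nb]]))
}

# 8-connected components of a small pixel set (linear indices)
components8 <- function(idx, H) {
  n <- length(idx)
  if (!n) return(integer())
  row <- (idx - 1L) %% H + 1L
  col <- (idx - 1L) %/% H + 1L
  adj <- abs(outer(row, row, `-`)) <= 1L & abs(outer(col, col, `-`)) <= 1L
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nb <- which(adj[frontier[1], ] & comp == 0L)
      comp[nb] <- cur
      frontier <- c(frontier[-1], nb)
    }
  }
  comp
}

#' ConnectedHiPix: cluster-filtered transcription-site statistic
#'
#' Starting from the `k` brightest ExpNucl pixels, a binary morphological
#' opening removes isolated pixels, retaining only those that cluster
#' together; the statistic is the mean raw intensity of the pixels in the
#' largest 8-connected component that survives (ties broken towards the
#' component holding the brightest pixel). If nothing survives the opening —
#' the situation when no transcription site is present — the value is
#' missing (`NA`), which is the detection criterion used throughout.
#'
#' @param frame projected image matrix.
#' @param expnucl logical ExpNucl mask.
#' @param k number of brightest pixels considered.
#' @param se structuring element of the opening: `"cross"` (3x3
#'   4-neighbourhood, default) or `"box"` (3x3).
#' @return scalar, or `NA` when no pixel survives.
#' @export
connected_hipix <- function(frame, expnucl, k = 20, se = c("cross", "box")) {
  connected_hipix_core(frame, which(expnucl), k, match.arg(se))
}

connected_hipix_core <- function(frame, idx_en, k, se) {
  H <- nrow(frame)
  top <- topk_idx(frame, idx_en, k)
  if (!length(top)) return(NA_real_)
  surv <- open_pixel_set(top, H, length(frame), se)
  if (!length(surv)) return(NA_real_)
  comp <- components8(surv, H)
  sizes <- tabulate(comp)
  big <- which(sizes == max(sizes))
  if (length(big) > 1) {
    bright <- vapply(big, function(cid) max(frame[surv[comp == cid]]),
                     numeric(1))
    big <- big[order(-bright, big)][1]
  }
  mean(frame[surv[comp == big]])
}

#' Quantify transcription-site traces for a movie
#'
#' Applies the maximum projection, then [hipix()] and [connected_hipix()]
#' per tracked cell and frame, assembling tidy time-indexed traces on the
#' acquisition grid. Frames invalidated by the segmentation filters get
#' missing values for both statistics; gaps are never interpolated.
#'
#' @param gfp projected GFP array `[y, x, t]` (or 4D `[y, x, z, t]`, which is
#'   projected first).
#' @param frames list of `segmented_frame`s (recycled if of length 1, for
#'   static scenes).
#' @param tracks (filtered) track table from [filter_cells()]; if the
#'   validity columns are absent all frames count as valid.
#' @param grid the [frame_grid()].
#' @param k brightest-pixel count.
#' @param se structuring element for the opening.
#' @return data.frame: `cell_id`, `frame`, `time_min`, `hipix`,
#'   `connected_hipix`, `valid`.
#' @export
quantify_traces <- function(gfp, frames, tracks, grid, k = 20,
                            se = c("cross", "box")) {
  se <- match.arg(se)
  if (length(dim(gfp)) == 4) gfp <- max_project(gfp)
  if (is.null(tracks$valid)) tracks$valid <- TRUE
  cells <- sort(unique(tracks$cell_id))
  nf <- grid$n_frames
  n_cells <- length(cells)
  hip <- matrix(NA_real_, n_cells, nf)
  chip <- matrix(NA_real_, n_cells, nf)
  val <- matrix(FALSE, n_cells, nf)
  static <- length(frames) == 1
  px_cache <- NULL
  for (f in seq_len(nf)) {
    seg <- if (static) frames[[1]] else frames[[f]]
    if (is.null(seg)) next
    fr <- gfp[, , f]
    if (is.null(px_cache) || !static) {
      lab_en <- seg$expnucl_labels
      lab_cl <- seg$cell_labels
      px_cache <- list(
        en = split(which(lab_en > 0), lab_en[lab_en > 0]),
        cl = split(which(lab_cl > 0), lab_cl[lab_cl > 0])
      )
    }
    tr_f <- tracks[tracks$frame == (if (static) 1 else f), ]
    for (i in seq_len(nrow(tr_f))) {
      ci <- match(tr_f$cell_id[i], cells)
      lab <- as.character(tr_f$label[i])
      val[ci, f] <- tr_f$valid[i]
      if (!tr_f$valid[i]) next
      idx_en <- px_cache$en[[lab]]
      idx_cl <- px_cache$cl[[lab]]
      if (is.null(idx_en) || is.null(idx_cl)) next
      hip[ci, f] <- as.numeric(hipix_core(fr[idx_en], fr[idx_cl], k))
      chip[ci, f] <- connected_hipix_core(fr, idx_en, k, se)
    }
  }
  data.frame(
    cell_id = rep(cells, each = nf),
    frame = rep(seq_len(nf), n_cells),
    time_min = rep(grid$time_min, n_cells),
    hipix = as.vector(t(hip)),
    connected_hipix = as.vector(t(chip)),
    valid = as.vector(t(val))
  )
}
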