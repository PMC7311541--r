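#' Maximum-intensity projection over Z
#'
#' Collapses the Z dimension of a stack by the pixelwise maximum, the
#' standard reduction applied to the GFP Z-stacks before transcription-site
#' quantification.
#'
#' @param stack matrix (`[y, x]`, returned unchanged), 3D array `[y, x, z]`,
#'   or 4D array `[y, x, z, t]`.
#' @return matrix for 2D/3D input, `[y, x, t]` array for 4D input.
#' @export
max_project <- function(stack) {
  d <- dim(stack)
  if (is.null(d) || length(d) < 2) stop("stack must be a matrix or array")
  if (length(d) == 2) return(stack)
  if (length(d) == 3) {
    out <- stack[, , 1]
    for (z in seq_len(d[3])[-1]) out <- pmax(out, stack[, , z])
    return(out)
  }
  if (length(d) == 4) {
    out <- array(0, c(d[1], d[2], d[4]))
    for (f in seq_len(d[4])) out[, , f] <- max_project(stack[, , , f])
    return(out)
  }
  stop("stack must have 2 to 4 dimensions")
}

# Otsu threshold on an arbitrary-range image
otsu_threshold <- function(frame) {
  rng <- range(frame)
  if (diff(rng) == 0) return(rng[2] + 1)  # blank frame: nothing above
  z <- (frame - rng[1]) / diff(rng)
  EBImage::otsu(EBImage::Image(z)) * diff(rng) + rng[1]
}

#' Segment nuclei from the nuclear-marker channel
#'
#' Otsu threshold, hole filling, connected labelling and a minimum-area
#' filter. A blank frame yields zero labels.
#'
#' @param frame nuclear-marker image (`[y, x]`).
#' @param min_area smallest accepted nucleus, px.
#' @param threshold optional fixed threshold; default Otsu.
#' @return integer label matrix.
#' @export
segment_nuclei <- function(frame, min_area = 20, threshold = NULL) {
  th <- if (is.null(threshold)) otsu_threshold(frame) else threshold
  mask <- EBImage::fillHull(EBImage::Image(frame > th))
  lab <- EBImage::bwlabel(mask)
  if (max(lab) > 0 && min_area > 0) {
    areas <- tabulate(as.integer(lab[lab > 0]), nbins = max(lab))
    drop <- which(areas < min_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  relabel_consecutive(matrix(as.integer(lab), nrow(frame), ncol(frame)))
}

relabel_consecutive <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(lab)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  lab[lab > 0] <- map[lab[lab > 0]]
  lab
}

#' Segment cell bodies seeded by nuclei
#'
#' Voronoi-style region growing (EBImage `propagate`) from the nucleus seeds,
#' constrained to above-background cell-proxy signal; each cell inherits its
#' nucleus label. If the proxy channel carries no signal the cells fall back
#' to a fixed dilation of their nuclei and the result is flagged.
#'
#' @param proxy_frame cell-body proxy image.
#' @param nucleus_labels label matrix from [segment_nuclei()].
#' @param threshold optional fixed proxy threshold; default Otsu.
#' @param fallback_px dilation radius of the nucleus fallback.
#' @return list with `labels` (matrix) and `fallback` (logical flag).
#' @export
segment_cells <- function(proxy_frame, nucleus_labels, threshold = NULL,
                          fallback_px = 8) {
  stopifnot(all(dim(proxy_frame) == dim(nucleus_labels)))
  if (max(nucleus_labels) == 0)
    return(list(labels = matrix(0L, nrow(proxy_frame), ncol(proxy_frame)),
                fallback = FALSE))
  th <- if (is.null(threshold)) otsu_threshold(proxy_frame) else threshold
  mask <- proxy_frame > th
  # degenerate proxy: threshold separates nothing cell-like
  if (mean(mask) < 1e-4 || diff(range(proxy_frame)) == 0) {
    lab <- expand_labels(nucleus_labels, fallback_px)
    return(list(labels = lab, fallback = TRUE))
  }
  mask <- mask | nucleus_labels > 0  # seeds must lie inside the growth mask
  rng <- range(proxy_frame)
  z <- (proxy_frame - rng[1]) / diff(rng)
  lab <- EBImage::propagate(EBImage::Image(z),
                            seeds = EBImage::Image(nucleus_labels),
                            mask = EBImage::Image(mask))
  list(labels = matrix(as.integer(lab), nrow(proxy_frame), ncol(proxy_frame)),
       fallback = FALSE)
}

# grow every label by `n_px` (Euclidean), nearest-label assignment
expand_labels <- function(labels, n_px) {
  if (max(labels) == 0 || n_px <= 0) return(labels)
  d <- EBImage::distmap(EBImage::Image(labels == 0))
  vor <- EBImage::propagate(EBImage::Image(matrix(0, nrow(labels), ncol(labels))),
                            seeds = EBImage::Image(labels), lambda = 1e8)
  out <- matrix(as.integer(vor), nrow(labels), ncol(labels))
  out[matrix(as.numeric(d), nrow(labels), ncol(labels)) > n_px] <- 0L
  out
}

#' Expand nuclei within their cells
#'
#' Dilates every nucleus by `n_px` pixels with a Euclidean disk, clips the
#' expansion to the cell of the same label, and resolves collisions between
#' neighbouring expansions by nearest-nucleus assignment. The result is the
#' expanded-nucleus (ExpNucl) region in which the transcription site is
#' quantified; with `n_px = 0` it equals the nucleus.
#'
#' @param nucleus_labels,cell_labels consistent label matrices.
#' @param n_px expansion radius in pixels.
#' @return ExpNucl label matrix; always satisfies nucleus ⊆ ExpNucl ⊆ cell.
#' @export
expand_nucleus <- function(nucleus_labels, cell_labels, n_px = 5) {
  stopifnot(all(dim(nucleus_labels) == dim(cell_labels)), n_px >= 0)
  grown <- expand_labels(nucleus_labels, n_px)
  grown[grown != cell_labels] <- 0L          # clip to own cell
  grown[nucleus_labels > 0] <- nucleus_labels[nucleus_labels > 0]
  grown
}

#' Per-frame object features
#'
#' Area, centroid and second-moment eccentricity for every nucleus, plus the
#' cell area and the mean GFP intensity inside each cell.
#'
#' @param nucleus_labels,cell_labels label matrices.
#' @param gfp_frame projected GFP image (for the intensity feature); optional.
#' @return data.frame, one row per label.
#' @export
frame_features <- function(nucleus_labels, cell_labels, gfp_frame = NULL) {
  ids <- sort(unique(cell_labels[cell_labels > 0]))
  if (!length(ids))
    return(data.frame(label = integer(), x = numeric(), y = numeric(),
                      nucleus_area = numeric(), cell_area = numeric(),
                      eccentricity = numeric(), mean_gfp = numeric()))
  # moments need consecutive labels; sorted ids map to 1..n
  nuc_ids <- sort(unique(nucleus_labels[nucleus_labels > 0]))
  nuc_cons <- relabel_consecutive(nucleus_labels)
  mom <- EBImage::computeFeatures.moment(nuc_cons)
  sh <- EBImage::computeFeatures.shape(nuc_cons)
  row_of <- match(ids, nuc_ids)
  cell_area <- tabulate(cell_labels[cell_labels > 0], nbins = max(ids))
  mean_gfp <- rep(NA_real_, max(ids))
  if (!is.null(gfp_frame)) {
    sums <- rowsum(as.numeric(gfp_frame[cell_labels > 0]),
                   group = cell_labels[cell_labels > 0])
    mean_gfp[as.integer(rownames(sums))] <-
      sums[, 1] / cell_area[as.integer(rownames(sums))]
  }
  data.frame(
    label = ids,
    # matrices are [row = y, col = x]; EBImage m.cx runs along dim 1
    x = mom[row_of, "m.cy"],
    y = mom[row_of, "m.cx"],
    nucleus_area = sh[row_of, "s.area"],
    cell_area = cell_area[ids],
    eccentricity = mom[row_of, "m.eccentricity"],
    mean_gfp = mean_gfp[ids]
  )
}

#' Segment one timepoint
#'
#' Runs nucleus and cell segmentation, the nucleus expansion, and the feature
#' table for a single frame; asserts the mask hierarchy.
#'
#' @param nuc_frame,proxy_frame channel images.
#' @param gfp_frame projected GFP image (optional, for intensity features).
#' @param expand_px ExpNucl expansion radius.
#' @param min_area minimum nucleus area.
#' @return `segmented_frame` list: `nucleus_labels`, `cell_labels`,
#'   `expnucl_labels`, `features`, `fallback`.
#' @export
segment_frame <- function(nuc_frame, proxy_frame, gfp_frame = NULL,
                          expand_px = 5, min_area = 20) {
  nuc <- segment_nuclei(nuc_frame, min_area = min_area)
  cells <- segment_cells(proxy_frame, nuc)
  exp <- expand_nucleus(nuc, cells$labels, expand_px)
  stopifnot(all(cells$labels[nuc > 0] == nuc[nuc > 0]),
            all(exp[nuc > 0] == nuc[nuc > 0]),
            all(cells$labels[exp > 0] == exp[exp > 0]))
  structure(list(nucleus_labels = nuc, cell_labels = cells$labels,
                 expnucl_labels = exp,
                 features = frame_features(nuc, cells$labels, gfp_frame),
                 fallback = cells$fallback),
            class = "segmented_frame")
}

#' Build segmented frames directly from ground-truth masks
#'
#' Bypass mode: wraps simulator truth masks in the `segmented_frame`
#' structure so the downstream quantification can be tested independently of
#' segmentation quality.
#'
#' @param cell_mask,nucleus_mask truth label matrices (static over time).
#' @param gfp_frame projected GFP image (optional).
#' @param expand_px ExpNucl expansion radius.
#' @export
segment_from_truth <- function(cell_mask, nucleus_mask, gfp_frame = NULL,
                               expand_px = 5) {
  exp <- expand_nucleus(nucleus_mask, cell_mask, expand_px)
  structure(list(nucleus_labels = nucleus_mask, cell_labels = cell_mask,
                 expnucl_labels = exp,
                 features = frame_features(nucleus_mask, cell_mask, gfp_frame),
                 fallback = FALSE),
            class = "segmented_frame")
}

#' Track cells across frames
#'
#' Greedy nearest-centroid matching between consecutive frames with a
#' maximum-displacement gate. Unmatched objects start new tracks; a track
#' with no match in a frame simply has no row for that frame (gaps are
#' explicit, never interpolated).
#'
#' @param frames list of `segmented_frame`s in time order.
#' @param max_disp gate in pixels; defaults to one typical cell radius.
#' @return data.frame with `cell_id` (track), `frame`, `label`, `x`, `y`.
#' @export
track_cells <- function(frames, max_disp = 10) {
  tracks <- data.frame(cell_id = integer(), frame = integer(),
                       label = integer(), x = numeric(), y = numeric())
  last_pos <- data.frame(cell_id = integer(), x = numeric(), y = numeric())
  next_id <- 1L
  for (f in seq_along(frames)) {
    fe <- frames[[f]]$features
    if (!nrow(fe)) next
    assigned <- rep(NA_integer_, nrow(fe))
    if (nrow(last_pos)) {
      d <- outer(last_pos$x, fe$x, `-`)^2 + outer(last_pos$y, fe$y, `-`)^2
      ord <- order(d)
      used_tr <- rep(FALSE, nrow(last_pos))
      for (k in ord) {
        if (d[k] > max_disp^2) break
        i <- (k - 1) %% nrow(last_pos) + 1
        j <- (k - 1) %/% nrow(last_pos) + 1
        if (used_tr[i] || !is.na(assigned[j])) next
        assigned[j] <- last_pos$cell_id[i]
        used_tr[i] <- TRUE
      }
    }
    new <- which(is.na(assigned))
    if (length(new)) {
      assigned[new] <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
    }
    tracks <- rbind(tracks, data.frame(cell_id = assigned, frame = f,
                                       label = fe$label, x = fe$x, y = fe$y))
    # carry forward the latest known position of every live track
    upd <- data.frame(cell_id = assigned, x = fe$x, y = fe$y)
    keep <- !(last_pos$cell_id %in% upd$cell_id)
    last_pos <- rbind(last_pos[keep, ], upd)
  }
  tracks[order(tracks$cell_id, tracks$frame), ]
}

#' Validity filtering of tracked cells
#'
#' Two levels of filtering mirror the movie quality control: single frames
#' where the nucleus eccentricity exceeds `ecc_max` are invalidated (cells in
#' mitosis duplicate the locus signal), and whole tracks whose median cell
#' area or median GFP intensity falls outside the configured bounds are
#' removed as segmentation errors.
#'
#' @param tracks data.frame from [track_cells()].
#' @param frames the list of `segmented_frame`s.
#' @param ecc_max per-frame eccentricity cut (strictly greater excluded).
#' @param area_range,intensity_range acceptance intervals for the track
#'   medians.
#' @return `tracks` with logical columns `valid_frame`, `valid_track`,
#'   `valid`.
#' @export
filter_cells <- function(tracks, frames, ecc_max = 0.95,
                         area_range = c(40, Inf),
                         intensity_range = c(0, Inf)) {
  ecc <- area <- inten <- rep(NA_real_, nrow(tracks))
  for (f in unique(tracks$frame)) {
    fe <- frames[[f]]$features
    m <- match(paste(f, tracks$label[tracks$frame == f]),
               paste(f, fe$label))
    sel <- tracks$frame == f
    ecc[sel] <- fe$eccentricity[m]
    area[sel] <- fe$cell_area[m]
    inten[sel] <- fe$mean_gfp[m]
  }
  tracks$valid_frame <- is.na(ecc) | ecc <= ecc_max
  med_area <- tapply(area, tracks$cell_id, stats::median, na.rm = TRUE)
  med_int <- tapply(inten, tracks$cell_id, stats::median, na.rm = TRUE)
  ok_area <- med_area >= area_range[1] & med_area <= area_range[2]
  ok_int <- is.na(med_int) |
    (med_int >= intensity_range[1] & med_int <= intensity_range[2])
  track_ok <- ok_area & ok_int
  tracks$valid_track <- as.vector(track_ok[as.character(tracks$cell_id)])
  tracks$valid <- as.vector(tracks$valid_frame & tracks$valid_track)
  tracks
}
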