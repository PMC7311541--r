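g4 <- frame_grid(n_frames = 4, time_zero_frame = 4)

render_static <- function(n_cells, seed = 1, cfg = render_config()) {
  lay <- layout_cells(n_cells, cfg, seed = seed)
  render_field(lay, matrix(0, n_cells, 4), g4, cfg, seed = seed + 1)
}

iou_by_truth <- function(seg_lab, truth_lab, ids) {
  vapply(ids, function(id) {
    hit <- table(seg_lab[truth_lab == id])
    hit <- hit[names(hit) != "0"]
    if (!length(hit)) return(0)
    s <- as.integer(names(which.max(hit)))
    sum(seg_lab == s & truth_lab == id) / sum(seg_lab == s | truth_lab == id)
  }, numeric(1))
}

test_that("max projection obeys identity and max laws", {
  m <- matrix(runif(100), 10, 10)
  expect_identical(max_project(array(m, c(10, 10, 1))), m)
  st <- array(c(m, 2 * m), c(10, 10, 2))
  expect_identical(max_project(st), 2 * m)
  expect_error(max_project(1:5))
})

test_that("nuclei are segmented from the nuclear-marker channel", {
  rf <- render_static(3, seed = 11)
  lab <- segment_nuclei(rf$nuc[, , 1])
  expect_equal(max(lab), 3)
  iou <- iou_by_truth(lab, rf$nucleus_mask, 1:3)
  expect_true(all(iou > 0.7))

  blank <- matrix(0, 50, 50)
  expect_equal(max(segment_nuclei(blank)), 0)
})

test_that("touching nuclei produce a detectable count mismatch", {
  # two nuclei rendered closer than their diameters merge under Otsu
  cfg <- render_config()
  size <- 60
  lab_truth <- tsburst:::disk_labels(size, c(28, 34), c(30, 30), c(4, 4), 1:2)
  img <- matrix(cfg$bg_proxy, size, size)
  img[lab_truth > 0] <- cfg$nuc_level
  lab <- segment_nuclei(img)
  expect_lt(max(lab), 2)  # merged: fewer objects than truth, reportable
})

test_that("cells grow from nucleus seeds and contain them", {
  rf <- render_static(10, seed = 13)
  nuc <- segment_nuclei(rf$nuc[, , 1])
  cells <- segment_cells(rf$proxy[, , 1], nuc)
  expect_false(cells$fallback)
  expect_true(all(cells$labels[nuc > 0] == nuc[nuc > 0]))
  iou <- iou_by_truth(cells$labels, rf$cell_mask, 1:10)
  expect_gte(sum(iou > 0.6), 9)
})

test_that("absent proxy signal triggers the flagged dilation fallback", {
  rf <- render_static(2, seed = 15)
  nuc <- segment_nuclei(rf$nuc[, , 1])
  flat <- matrix(5, nrow(nuc), ncol(nuc))
  cells <- segment_cells(flat, nuc)
  expect_true(cells$fallback)
  expect_true(all(cells$labels[nuc > 0] == nuc[nuc > 0]))
})

test_that("nucleus expansion is Euclidean, clipped, and monotone", {
  # disk r=5 centred in a large cell: expansion by 5 gives a disk r=10
  nuc <- tsburst:::disk_labels(60, 30, 30, 5)
  cell <- tsburst:::disk_labels(60, 30, 30, 25)
  exp5 <- expand_nucleus(nuc, cell, 5)
  expect_lt(abs(sum(exp5 > 0) - pi * 100) / (pi * 100), 0.03)

  # flush against the cell border: strictly inside the cell
  cell_small <- tsburst:::disk_labels(60, 30, 30, 7)
  expf <- expand_nucleus(nuc, cell_small, 5)
  expect_true(all(cell_small[expf > 0] > 0))

  # n = 0 is the identity
  expect_identical(expand_nucleus(nuc, cell, 0), nuc)

  # monotone in the expansion radius
  e3 <- expand_nucleus(nuc, cell, 3)
  e4 <- expand_nucleus(nuc, cell, 4)
  expect_true(all(e4[e3 > 0] > 0))
})

test_that("mask hierarchy nucleus within ExpNucl within cell always holds", {
  rf <- render_static(10, seed = 17)
  sf <- segment_frame(rf$nuc[, , 1], rf$proxy[, , 1])
  nuc <- sf$nucleus_labels; ex <- sf$expnucl_labels; cl <- sf$cell_labels
  expect_true(all(ex[nuc > 0] == nuc[nuc > 0]))
  expect_true(all(cl[ex > 0] == ex[ex > 0]))
})

test_that("stationary cells are tracked through every frame", {
  rf <- render_static(5, seed = 19)
  frames <- lapply(1:4, function(f)
    segment_frame(rf$nuc[, , f], rf$proxy[, , f]))
  tr <- track_cells(frames)
  counts <- table(tr$cell_id)
  expect_equal(length(counts), 5)
  expect_true(all(counts == 4))
})

test_that("a disappearing cell ends its track at the right frame", {
  rf <- render_static(3, seed = 21)
  frames <- lapply(1:4, function(f)
    segment_frame(rf$nuc[, , f], rf$proxy[, , f]))
  # remove cell 2's object from frames 3-4
  gone <- frames[[1]]$features$label[2]
  for (f in 3:4) {
    fr <- frames[[f]]
    keep <- fr$features$label != gone
    fr$features <- fr$features[keep, ]
    frames[[f]] <- fr
  }
  tr <- track_cells(frames)
  ended <- tapply(tr$frame, tr$cell_id, max)
  expect_true(any(ended == 2))
  expect_equal(sum(ended == 4), 2)
})

test_that("objects jumping beyond the gate start new tracks, never swap", {
  mk <- function(x, y) {
    structure(list(features = data.frame(label = seq_along(x), x = x, y = y,
                                         nucleus_area = 50, cell_area = 300,
                                         eccentricity = 0.2, mean_gfp = 100)),
              class = "segmented_frame")
  }
  frames <- list(mk(c(10, 50), c(10, 10)), mk(c(50, 10), c(10, 10)))
  tr <- track_cells(frames, max_disp = 10)
  # the two frame-2 objects coincide with the *other* frame-1 positions:
  # matched at distance 0 to the original tracks, no displacement gate hit;
  # now move frame-2 objects far from both -> two new tracks
  frames2 <- list(mk(c(10, 50), c(10, 10)), mk(c(100, 140), c(80, 80)))
  tr2 <- track_cells(frames2, max_disp = 10)
  expect_equal(length(unique(tr2$cell_id)), 4)
  ended <- tapply(tr2$frame, tr2$cell_id, max)
  expect_equal(unname(sort(ended)), c(1, 1, 2, 2))
})

test_that("eccentric (mitotic) frames and speck tracks are filtered", {
  # circular nucleus kept, eccentricity 0.97 frame invalidated
  mk <- function(ecc, area) {
    structure(list(features = data.frame(label = 1L, x = 10, y = 10,
                                         nucleus_area = 40, cell_area = area,
                                         eccentricity = ecc, mean_gfp = 100)),
              class = "segmented_frame")
  }
  frames <- list(mk(0.1, 300), mk(0.97, 300), mk(0.3, 300))
  tr <- track_cells(frames)
  tr <- filter_cells(tr, frames)
  expect_equal(tr$valid_frame, c(TRUE, FALSE, TRUE))
  expect_true(all(tr$valid_track))
  expect_equal(tr$valid, c(TRUE, FALSE, TRUE))

  # a speck: area below the configured minimum in all frames
  speck <- list(mk(0.1, 10), mk(0.1, 12), mk(0.1, 9))
  trs <- filter_cells(track_cells(speck), speck, area_range = c(40, Inf))
  expect_true(all(!trs$valid_track))
})
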