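#' Write an image array as multi-page TIFF with a JSON sidecar
#'
#' Pages are written in T-major, Z-minor order for 4D `[y, x, z, t]` arrays
#' and frame order for 3D `[y, x, t]`; the sidecar records the dimension
#' order and the 16-bit integer scaling so the array round-trips exactly for
#' integer count data.
#'
#' @param arr 2D/3D/4D numeric array of camera counts.
#' @param path output `.tif` path; the sidecar is written at `path.json`.
#' @param scale full-scale count value mapped to 16-bit white.
#' @export
write_image_tiff <- function(arr, path, scale = 65535) {
  d <- dim(arr)
  pages <- switch(as.character(length(d)),
    "2" = list(arr),
    "3" = lapply(seq_len(d[3]), function(f) arr[, , f]),
    "4" = {
      out <- vector("list", d[3] * d[4])
      i <- 0
      for (f in seq_len(d[4])) for (z in seq_len(d[3])) {
        i <- i + 1
        out[[i]] <- arr[, , z, f]
      }
      out
    },
    stop("arr must have 2 to 4 dimensions"))
  pages <- lapply(pages, function(p) pmin(pmax(p, 0), scale) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  sidecar <- list(
    dims = as.list(d),
    dim_order = c("Y", "X", "Z", "T")[seq_along(d)],
    page_order = if (length(d) == 4) "T-major, Z within T" else "T",
    scale = scale
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a TIFF written by [write_image_tiff()]
#'
#' @param path `.tif` path with its `.json` sidecar.
#' @return numeric array in the original dimension order, counts scale.
#' @export
read_image_tiff <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stop("missing sidecar JSON for ", path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  d <- as.integer(unlist(sc$dims))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  expected <- if (length(d) >= 3) prod(d[-(1:2)]) else 1
  if (length(pages) != expected)
    stop(sprintf("TIFF has %d pages but sidecar declares %d (axes %s)",
                 length(pages), expected, paste(sc$dim_order, collapse = "-")))
  arr <- array(0, d)
  if (length(d) == 2) {
    arr <- pages[[1]] * sc$scale
  } else if (length(d) == 3) {
    for (f in seq_len(d[3])) arr[, , f] <- pages[[f]] * sc$scale
  } else {
    i <- 0
    for (f in seq_len(d[4])) for (z in seq_len(d[3])) {
      i <- i + 1
      arr[, , z, f] <- pages[[i]] * sc$scale
    }
  }
  round(arr)
}

#' Write a label mask as 16-bit TIFF
#' @param labels integer label matrix.
#' @param path output path.
#' @export
write_label_tiff <- function(labels, path) {
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a label mask written by [write_label_tiff()]
#' @param path TIFF path.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write/read tidy tables with missing values as empty cells
#'
#' @param df data.frame.
#' @param path CSV path.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, na.strings = "")
}
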