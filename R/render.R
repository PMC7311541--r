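#' Rendering configuration
#'
#' Geometry and noise model for synthetic movies. Defaults mirror the
#' acquisition used throughout: 6 Z-planes spaced 0.4 um spanning roughly
#' +/- 1.2 um around focus, one GFP stack every 15 s for 25 min, with
#' exponential photobleaching reaching 32% (GFP) and 26% (RFP) loss at the
#' last frame. Noise is Poisson shot noise plus Gaussian read noise.
#'
#' `counts_per_mRNA` is calibrated in HiPix units: a spot of truth amplitude
#' A is rendered with the integrated intensity that makes a noise-free,
#' in-focus HiPix measurement (mean of the `calib_k` brightest pixels minus
#' the cell median) recover A. With the default 12 counts per transcript a
#' typical convoy-loaded site sits 50-300 counts above background, so the
#' 7-count burst threshold is a meaningful fluctuation scale.
#'
#' @param n_z number of Z planes (the focal plane is included).
#' @param z_step um between planes.
#' @param psf_sigma lateral Gaussian PSF sigma, pixels.
#' @param psf_sigma_z axial attenuation sigma, um.
#' @param z_broaden um scale over which defocus broadens the lateral sigma.
#' @param counts_per_mRNA HiPix counts per resident transcript equivalent.
#' @param calib_k number of brightest pixels used in the calibration.
#' @param bg_out,bg_cell,nuc_level,proxy_level,bg_proxy background and
#'   channel levels in camera counts.
#' @param read_noise_sd Gaussian read noise sd, counts.
#' @param photons_per_count photon conversion factor of the camera: shot
#'   noise is Poisson at the photon level, so the count-scale noise sd is
#'   `sqrt(counts / photons_per_count)`. The default of 10 gives a ~4-count
#'   shot-noise sd on the cellular background, consistent with a
#'   brightest-pixel statistic that sits near zero in the absence of a
#'   transcription site and with a 7-count burst threshold being a
#'   meaningful fluctuation scale.
#' @param bleach_fraction_gfp,bleach_fraction_rfp total fractional signal
#'   loss over the movie in the GFP and nuclear-marker channels.
#' @param saturation detector full well, counts; brighter pixels are clipped
#'   with a warning.
#' @param cell_radius,nucleus_radius px.
#' @param tile px of the square tile holding one cell.
#' @param cells_per_field maximum cells laid out in one field of view.
#' @param spot_jitter_sd px per-frame jitter of the transcription-site locus.
#' @param spot_z_range um; the locus Z position is uniform in +/- this value.
#' @param noise,bleach logical toggles (disabled for oracle renders).
#' @return a `render_config` list.
#' @export
render_config <- function(n_z = 6, z_step = 0.4,
                          psf_sigma = 1.3, psf_sigma_z = 0.5, z_broaden = 0.8,
                          counts_per_mRNA = 12, calib_k = 20,
                          bg_out = 40, bg_cell = 150,
                          nuc_level = 300, proxy_level = 120, bg_proxy = 20,
                          read_noise_sd = 1.5,
                          photons_per_count = 10,
                          bleach_fraction_gfp = 0.32,
                          bleach_fraction_rfp = 0.26,
                          saturation = 65535,
                          cell_radius = 10, nucleus_radius = 4,
                          tile = 40, cells_per_field = 25,
                          spot_jitter_sd = 0.3, spot_z_range = 0.3,
                          noise = TRUE, bleach = TRUE) {
  stopifnot(n_z >= 1, counts_per_mRNA > 0,
            bleach_fraction_gfp >= 0, bleach_fraction_gfp < 1,
            bleach_fraction_rfp >= 0, bleach_fraction_rfp < 1,
            nucleus_radius < cell_radius, tile >= 2 * cell_radius)
  structure(as.list(environment()), class = "render_config")
}

# plane offsets in um; the focal plane (0) is always included
z_offsets <- function(cfg) {
  (seq_len(cfg$n_z) - (floor(cfg$n_z / 2) + 1)) * cfg$z_step
}

# pixel-integrated Gaussian kernel at subpixel offset (dx, dy), unit integral
gauss_kernel <- function(sigma, dx = 0, dy = 0, half = 6) {
  e <- seq(-half - 0.5, half + 0.5, by = 1)
  kx <- diff(stats::pnorm(e, mean = dx, sd = sigma))
  ky <- diff(stats::pnorm(e, mean = dy, sd = sigma))
  outer(kx, ky)
}

# mean of the calib_k brightest pixels of a unit-integral in-focus spot:
# converts HiPix counts to integrated spot counts
hipix_gain <- function(cfg) {
  k <- gauss_kernel(cfg$psf_sigma)
  mean(sort(as.vector(k), decreasing = TRUE)[seq_len(cfg$calib_k)])
}

#' Lay out cells in fields of view
#'
#' Cells are placed on a jittered grid, one per `tile`-pixel tile, at most
#' `cells_per_field` per field, so neighbouring cells never overlap.
#'
#' @param n_cells number of cells.
#' @param cfg a [render_config()].
#' @param seed integer seed for the jitter.
#' @return data.frame with `cell_id`, `field`, `x`, `y` (pixel centres,
#'   1-based) and the per-field image size as attributes.
#' @export
layout_cells <- function(n_cells, cfg = render_config(), seed = 1) {
  set.seed(seed)
  per <- cfg$cells_per_field
  side <- ceiling(sqrt(per))
  out <- vector("list", 0)
  placed <- 0
  field <- 0
  while (placed < n_cells) {
    field <- field + 1
    n_here <- min(per, n_cells - placed)
    slot <- seq_len(n_here) - 1
    gx <- slot %% side
    gy <- slot %/% side
    jit <- cfg$tile / 2 - cfg$cell_radius - 2
    out[[field]] <- data.frame(
      cell_id = placed + seq_len(n_here),
      field = field,
      x = gx * cfg$tile + cfg$tile / 2 + stats::runif(n_here, -jit, jit),
      y = gy * cfg$tile + cfg$tile / 2 + stats::runif(n_here, -jit, jit)
    )
    placed <- placed + n_here
  }
  res <- do.call(rbind, out)
  attr(res, "field_size") <- side * cfg$tile
  res
}

# label image with disks at (x, y) of given radius
disk_labels <- function(size, x, y, r, labels = seq_along(x)) {
  lab <- matrix(0L, size, size)
  cc <- seq_len(size)
  for (i in seq_along(x)) {
    rows <- pmax(1, floor(y[i] - r[i])):pmin(size, ceiling(y[i] + r[i]))
    cols <- pmax(1, floor(x[i] - r[i])):pmin(size, ceiling(x[i] + r[i]))
    d2 <- outer((rows - y[i])^2, (cols - x[i])^2, `+`)
    sel <- d2 <= r[i]^2
    lab[rows, cols][sel] <- labels[i]
  }
  lab
}

add_noise <- function(lambda, cfg) {
  if (!cfg$noise) return(lambda)
  g <- cfg$photons_per_count
  v <- stats::rpois(length(lambda), lambda * g) / g +
    stats::rnorm(length(lambda), 0, cfg$read_noise_sd)
  matrix(v, nrow(lambda), ncol(lambda))
}

#' Render one field of view
#'
#' Produces the three channels for the cells of one field: a GFP channel as
#' a Z-stack per frame carrying the transcription-site spots over diffuse
#' cellular background, a nuclear-marker channel, and a cell-proxy channel,
#' together with the ground-truth label masks. Matrices are indexed
#' `[row (y), col (x)]`.
#'
#' @param cells rows of [layout_cells()] for one field.
#' @param intensity cells x frames truth matrix (transcript units) for the
#'   same cells, in the same order.
#' @param grid the [frame_grid()].
#' @param cfg a [render_config()].
#' @param seed integer seed.
#' @return list with `gfp` (`[y, x, z, t]`), `nuc` and `proxy` (`[y, x, t]`),
#'   `cell_mask` and `nucleus_mask` (ground-truth label images, labels =
#'   cell_id), and the per-cell geometry table.
#' @export
render_field <- function(cells, intensity, grid, cfg = render_config(),
                         seed = 1) {
  stopifnot(nrow(cells) == nrow(intensity))
  set.seed(seed)
  size <- attr(cells, "field_size")
  if (is.null(size)) size <- max(ceiling(c(cells$x, cells$y))) + cfg$tile / 2
  nf <- grid$n_frames
  n <- nrow(cells)

  r_cell <- pmax(stats::rnorm(n, cfg$cell_radius, cfg$cell_radius * 0.08),
                 cfg$nucleus_radius + 2)
  r_nuc <- rep(cfg$nucleus_radius, n)
  cell_mask <- disk_labels(size, cells$x, cells$y, r_cell, cells$cell_id)
  nucleus_mask <- disk_labels(size, cells$x, cells$y, r_nuc, cells$cell_id)

  # fixed locus position inside each nucleus, plus its Z offset
  ang <- stats::runif(n, 0, 2 * pi)
  rad <- stats::runif(n, 0, pmax(r_nuc - 1.5, 0))
  spot_x <- cells$x + rad * cos(ang)
  spot_y <- cells$y + rad * sin(ang)
  spot_z <- stats::runif(n, -cfg$spot_z_range, cfg$spot_z_range)

  gain <- hipix_gain(cfg)
  zoff <- z_offsets(cfg)
  gfp_base <- matrix(cfg$bg_out, size, size)
  gfp_base[cell_mask > 0] <- cfg$bg_cell
  nuc_base <- matrix(cfg$bg_proxy, size, size)
  nuc_base[nucleus_mask > 0] <- cfg$nuc_level
  proxy_base <- matrix(cfg$bg_proxy, size, size)
  proxy_base[cell_mask > 0] <- cfg$proxy_level

  kg <- if (cfg$bleach) (1 - cfg$bleach_fraction_gfp)^(1 / max(nf - 1, 1)) else 1
  kr <- if (cfg$bleach) (1 - cfg$bleach_fraction_rfp)^(1 / max(nf - 1, 1)) else 1

  gfp <- array(0, c(size, size, cfg$n_z, nf))
  nuc <- array(0, c(size, size, nf))
  proxy <- array(0, c(size, size, nf))
  half <- 6
  clipped <- FALSE

  for (f in seq_len(nf)) {
    bf_g <- kg^(f - 1)
    bf_r <- kr^(f - 1)
    spot_planes <- vector("list", cfg$n_z)
    for (zi in seq_len(cfg$n_z)) spot_planes[[zi]] <- matrix(0, size, size)
    for (i in seq_len(n)) {
      a <- intensity[i, f] * cfg$counts_per_mRNA
      if (a <= 0) next
      sx <- spot_x[i] + if (cfg$noise) stats::rnorm(1, 0, cfg$spot_jitter_sd) else 0
      sy <- spot_y[i] + if (cfg$noise) stats::rnorm(1, 0, cfg$spot_jitter_sd) else 0
      px <- round(sx); py <- round(sy)
      rows <- (py - half):(py + half)
      cols <- (px - half):(px + half)
      ok_r <- rows >= 1 & rows <= size
      ok_c <- cols >= 1 & cols <= size
      for (zi in seq_len(cfg$n_z)) {
        dz <- zoff[zi] - spot_z[i]
        att <- exp(-dz^2 / (2 * cfg$psf_sigma_z^2))
        sig <- cfg$psf_sigma * sqrt(1 + (dz / cfg$z_broaden)^2)
        ker <- gauss_kernel(sig, dx = sy - py, dy = sx - px, half = half)
        spot_planes[[zi]][rows[ok_r], cols[ok_c]] <-
          spot_planes[[zi]][rows[ok_r], cols[ok_c]] +
          (a / gain) * att * ker[ok_r, ok_c]
      }
    }
    for (zi in seq_len(cfg$n_z)) {
      lam <- (gfp_base + spot_planes[[zi]]) * bf_g
      if (any(lam > cfg$saturation)) clipped <- TRUE
      gfp[, , zi, f] <- pmin(add_noise(lam, cfg), cfg$saturation)
    }
    nuc[, , f] <- pmin(add_noise(nuc_base * bf_r, cfg), cfg$saturation)
    proxy[, , f] <- pmin(add_noise(proxy_base, cfg), cfg$saturation)
  }
  if (clipped) warning("spot intensity exceeded detector saturation; clipped")

  list(gfp = gfp, nuc = nuc, proxy = proxy,
       cell_mask = cell_mask, nucleus_mask = nucleus_mask,
       geometry = data.frame(cell_id = cells$cell_id, x = cells$x,
                             y = cells$y, cell_radius = r_cell,
                             nucleus_radius = r_nuc,
                             spot_x = spot_x, spot_y = spot_y,
                             spot_z = spot_z))
}

#' Render a whole simulated experiment
#'
#' Convenience wrapper for small movies: lays out all cells and renders every
#' field. For large simulations prefer iterating [render_field()] field by
#' field to bound memory.
#'
#' @param sim result of [simulate_cells()].
#' @param cfg a [render_config()].
#' @param seed integer seed.
#' @return list of per-field render results plus the layout table.
#' @export
render_movie <- function(sim, cfg = render_config(), seed = 1) {
  lay <- layout_cells(nrow(sim$intensity), cfg, seed = derive_seed(seed, 0L))
  fields <- lapply(split(seq_len(nrow(lay)), lay$field), function(ix) {
    cells <- lay[ix, , drop = FALSE]
    attr(cells, "field_size") <- attr(lay, "field_size")
    render_field(cells, sim$intensity[ix, , drop = FALSE], sim$grid, cfg,
                 seed = derive_seed(seed, min(ix)))
  })
  list(fields = fields, layout = lay)
}
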