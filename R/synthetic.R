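#' Specification of one synthetic retinal field
#'
#' Describes everything needed to render one field of a synthetic retinal
#' whole-mount with exact ground truth: how many microglia-like cells to
#' plant, their soma and arbor geometry, the enforced inter-soma spacing
#' (mosaic regularity), the punctum count for the OPL-OS interface plane,
#' the green-channel (P2RY12-like) mean level, and the noise model.
#'
#' Geometry is drawn in micrometres on a square field of the standard
#' 0.1502 mm^2 area (side ~387.6 um); `field_px` sets the raster size and
#' hence the pixel size (the default 1024 px gives ~0.38 um/px).
#' Rasterization uses the pixel-centre-in-shape rule with binary
#' amplitudes (no sub-pixel blending), so every planted object's pixel
#' area is exactly recoverable from the image. Process strokes are floored
#' at a half-width of 0.72 px so they stay 8-connected at coarse rasters.
#'
#' @param layer One of `"OS"`, `"OPL"`, `"IPL"`, `"NFL_GCL"`, `"OPL_OS"`
#'   (the interface plane used for vertical-process puncta).
#' @param n_cells Number of cells to plant (>= 0).
#' @param soma_radius_um `c(mean, sd)` of soma radius in um.
#' @param arbor_radius_um `c(mean, sd)` of process-tip radius in um.
#' @param n_processes `c(min, max)` processes per cell.
#' @param min_spacing_um Enforced minimum inter-soma distance (mosaic).
#' @param allow_overlap If `TRUE` (dense NFL-GCL mode) the spacing applies
#'   only to somata and arbors may overlap freely; placement is still
#'   checked against `min_spacing_um`.
#' @param n_puncta Punctum count for [render_puncta_plane()].
#' @param punctum_radius_um Punctum radius in um.
#' @param punctum_spacing_um Minimum punctum separation in um.
#' @param intensity_mean Mean green-channel level (0-255), or `NA` for no
#'   green channel.
#' @param background_level Additive uniform background (0-255).
#' @param noise_sd SD of additive Gaussian noise (clipped to bit depth).
#' @param soma_amplitude,process_amplitude Rendered signal levels of soma
#'   and processes (soma brighter, as in Iba-1 staining).
#' @param process_width_um Stroke width of processes in um.
#' @param field_px Raster width/height in pixels.
#' @param n_z Number of z planes in the rendered stack.
#' @param seed RNG seed; identical specs render identical bytes.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(layer = "OPL",
                       n_cells = 16,
                       soma_radius_um = c(4, 0.4),
                       arbor_radius_um = c(17, 1.5),
                       n_processes = c(4, 6),
                       min_spacing_um = 45,
                       allow_overlap = FALSE,
                       n_puncta = 0,
                       punctum_radius_um = 2.5,
                       punctum_spacing_um = 12,
                       intensity_mean = NA_real_,
                       background_level = 8,
                       noise_sd = 5,
                       soma_amplitude = 200,
                       process_amplitude = 100,
                       process_width_um = 1.5,
                       field_px = 1024,
                       n_z = 4,
                       seed = 1) {
  layer <- match.arg(layer, c("OS", "OPL", "IPL", "NFL_GCL", "OPL_OS"))
  stopifnot(n_cells >= 0, min_spacing_um >= 0, n_puncta >= 0,
            field_px >= 16, n_z >= 1, noise_sd >= 0,
            background_level >= 0, soma_amplitude > 0)
  if (!is.na(intensity_mean) &&
      (intensity_mean < 0 || intensity_mean > 255)) {
    abort("intensity_mean must lie in [0, 255]")
  }
  side <- FIELD_SIDE_UM
  margin <- arbor_radius_um[1] + 3 * arbor_radius_um[2] + 2
  usable <- side - 2 * margin
  if (n_cells > 0 && min_spacing_um > 0) {
    cap <- (floor(usable / min_spacing_um) + 1)^2
    if (n_cells > cap) {
      abort(sprintf(
        "infeasible packing: %d cells cannot be placed %g um apart",
        n_cells, min_spacing_um))
    }
  }
  structure(
    list(layer = layer, n_cells = as.integer(n_cells),
         soma_radius_um = soma_radius_um, arbor_radius_um = arbor_radius_um,
         n_processes = as.integer(n_processes),
         min_spacing_um = min_spacing_um, allow_overlap = allow_overlap,
         n_puncta = as.integer(n_puncta),
         punctum_radius_um = punctum_radius_um,
         punctum_spacing_um = punctum_spacing_um,
         intensity_mean = intensity_mean,
         background_level = background_level, noise_sd = noise_sd,
         soma_amplitude = soma_amplitude,
         process_amplitude = process_amplitude,
         process_width_um = process_width_um,
         field_px = as.integer(field_px), n_z = as.integer(n_z),
         seed = as.integer(seed), side_um = side, margin_um = margin),
    class = "field_spec")
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf(
    "<field_spec> layer %s: %d cells (spacing >= %g um), %d puncta, %d px, seed %d\n",
    x$layer, x$n_cells, x$min_spacing_um, x$n_puncta, x$field_px, x$seed))
  invisible(x)
}

# Minimum-distance point placement: dart throwing with a jittered-grid
# fallback for dense packings. Coordinates in um within [margin, side-margin].
place_points <- function(n, min_spacing, side, margin) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  lo <- margin; hi <- side - margin
  if (hi <= lo) abort("margin leaves no usable field")
  pts <- matrix(NA_real_, n, 2)
  got <- 0L
  for (i in seq_len(n * 800L)) {
    p <- c(runif(1, lo, hi), runif(1, lo, hi))
    if (got == 0L ||
        min((pts[seq_len(got), 1] - p[1])^2 +
              (pts[seq_len(got), 2] - p[2])^2) >= min_spacing^2) {
      got <- got + 1L
      pts[got, ] <- p
      if (got == n) return(pts)
    }
  }
  # dense regime: jittered grid
  usable <- hi - lo
  k <- floor(usable / max(min_spacing, 1e-6)) + 1L
  if (k * k < n) abort("infeasible packing after rejection sampling")
  k <- max(2L, min(k, ceiling(sqrt(4 * n))))
  while (k * k < n) k <- k + 1L
  pitch <- usable / (k - 1)
  if (pitch < min_spacing) abort("infeasible packing after rejection sampling")
  jit <- max(0, (pitch - min_spacing) / 2.9)
  g <- expand.grid(y = lo + (0:(k - 1)) * pitch, x = lo + (0:(k - 1)) * pitch)
  sel <- sample.int(nrow(g), n)
  cbind(g$y[sel] + runif(n, -jit, jit), g$x[sel] + runif(n, -jit, jit))
}

# Draw a filled disc into a matrix (pixel-centre-in-disc), returning the
# indices drawn. Coordinates are um, zero-based pixel centres.
disc_indices <- function(cy, cx, r, s, nr, nc) {
  r0 <- max(1L, floor(cy / s - r / s) + 1L - 1L)
  r1 <- min(nr, ceiling(cy / s + r / s) + 1L + 1L)
  c0 <- max(1L, floor(cx / s - r / s) + 1L - 1L)
  c1 <- min(nc, ceiling(cx / s + r / s) + 1L + 1L)
  if (r1 < r0 || c1 < c0) return(cbind(integer(0), integer(0)))
  ys <- (r0:r1 - 1) * s - cy
  xs <- (c0:c1 - 1) * s - cx
  d2 <- outer(ys^2, xs^2, `+`)
  w <- which(d2 <= r^2, arr.ind = TRUE)
  cbind(w[, 1] + r0 - 1L, w[, 2] + c0 - 1L)
}

# Pixel indices within half-width of a segment (pixel-centre rule).
segment_indices <- function(y0, x0, y1, x1, halfw, s, nr, nc) {
  r0 <- max(1L, floor(min(y0, y1) / s - halfw / s) + 1L - 1L)
  r1 <- min(nr, ceiling(max(y0, y1) / s + halfw / s) + 1L + 1L)
  c0 <- max(1L, floor(min(x0, x1) / s - halfw / s) + 1L - 1L)
  c1 <- min(nc, ceiling(max(x0, x1) / s + halfw / s) + 1L + 1L)
  if (r1 < r0 || c1 < c0) return(cbind(integer(0), integer(0)))
  ys <- (r0:r1 - 1) * s
  xs <- (c0:c1 - 1) * s
  gy <- matrix(ys, length(ys), length(xs))
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  vy <- y1 - y0; vx <- x1 - x0
  L2 <- vy^2 + vx^2
  t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((gy - y0) * vy + (gx - x0) * vx) / L2))
  dy <- gy - (y0 + t * vy); dx <- gx - (x0 + t * vx)
  w <- which(dy^2 + dx^2 <= halfw^2, arr.ind = TRUE)
  cbind(w[, 1] + r0 - 1L, w[, 2] + c0 - 1L)
}

#' Render a synthetic field with exact ground truth
#'
#' Plants `n_cells` ramified cells (bright soma disc, dimmer radiating
#' process strokes to recorded tip positions) at mosaic spacing, assigns
#' each cell to a z plane, adds background and clipped Gaussian noise per
#' plane, and returns both the 8-bit [image_stack()] and a `ground_truth`
#' catalogue describing exactly what was drawn: soma centroids and
#' rasterized soma pixel areas, process-tip coordinates, convex-hull arbor
#' areas, the planted signal pixel fraction, and (when a green channel is
#' rendered) the realised mean intensity percentage of its max projection.
#'
#' Identical specs (including seed) render identical bytes.
#'
#' @param spec A [field_spec()].
#' @return List with elements `stack` ([image_stack()]) and `truth`
#'   (`ground_truth`).
#' @export
render_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  set.seed(spec$seed)
  npx <- spec$field_px
  s <- spec$side_um / npx
  halfw <- max(spec$process_width_um / 2, 0.72 * s)
  centres <- place_points(spec$n_cells, spec$min_spacing_um,
                          spec$side_um, spec$margin_um)
  nz <- spec$n_z
  planes <- replicate(nz, matrix(0, npx, npx), simplify = FALSE)
  signal <- matrix(0, npx, npx)

  cells <- NULL
  tips_all <- NULL
  if (spec$n_cells > 0) {
    nc <- spec$n_cells
    zs <- sample.int(nz, nc, replace = TRUE)
    v_soma_r <- v_soma_a <- v_arbor <- numeric(nc)
    v_k <- integer(nc)
    t_cell <- integer(0); t_y <- t_x <- numeric(0)
    for (i in seq_len(nc)) {
      cy <- centres[i, 1]; cx <- centres[i, 2]
      r_soma <- truncnorm1(spec$soma_radius_um[1], spec$soma_radius_um[2])
      k <- if (spec$n_processes[2] > spec$n_processes[1]) {
        sample(spec$n_processes[1]:spec$n_processes[2], 1)
      } else spec$n_processes[1]
      ang <- 2 * pi * (seq_len(k) - 1) / k +
        runif(1, 0, 2 * pi) + runif(k, -pi / (2 * k), pi / (2 * k))
      r_tip <- pmax(r_soma + 2,
                    pmin(truncnormk(k, spec$arbor_radius_um[1],
                                    spec$arbor_radius_um[2]),
                         spec$margin_um - 2))
      ty <- cy + r_tip * sin(ang)
      tx <- cx + r_tip * cos(ang)
      z <- zs[i]
      # processes first, soma on top (soma amplitude wins on overlap)
      for (j in seq_len(k)) {
        idx <- segment_indices(cy, cx, ty[j], tx[j], halfw, s, npx, npx)
        planes[[z]][idx] <- pmax(planes[[z]][idx], spec$process_amplitude)
        signal[idx] <- pmax(signal[idx], spec$process_amplitude)
      }
      di <- disc_indices(cy, cx, r_soma, s, npx, npx)
      planes[[z]][di] <- spec$soma_amplitude
      signal[di] <- spec$soma_amplitude
      v_soma_r[i] <- r_soma
      v_soma_a[i] <- nrow(di) * s^2
      v_k[i] <- k
      v_arbor[i] <- as.numeric(arbor_area(cbind(ty, tx)))
      t_cell <- c(t_cell, rep.int(i, k)); t_y <- c(t_y, ty); t_x <- c(t_x, tx)
    }
    cells <- tibble(
      cell = seq_len(nc), y_um = centres[, 1], x_um = centres[, 2],
      z = zs, soma_radius_um = v_soma_r, soma_area_um2 = v_soma_a,
      n_processes = v_k, arbor_area_um2 = v_arbor)
    tips_all <- tibble(cell = t_cell, y_um = t_y, x_um = t_x)
  } else {
    cells <- tibble(cell = integer(), y_um = double(), x_um = double(),
                    z = integer(), soma_radius_um = double(),
                    soma_area_um2 = double(), n_processes = integer(),
                    arbor_area_um2 = double())
    tips_all <- tibble(cell = integer(), y_um = double(), x_um = double())
  }
  true_fraction <- mean(signal > 0)

  red <- lapply(planes, function(p) {
    clip8(p + spec$background_level +
            if (spec$noise_sd > 0) rnorm(length(p), 0, spec$noise_sd) else 0)
  })
  red_arr <- array(0, dim = c(nz, npx, npx))
  for (z in seq_len(nz)) red_arr[z, , ] <- red[[z]]
  channels <- list(iba1 = red_arr)

  intensity_percent <- NA_real_
  if (!is.na(spec$intensity_mean)) {
    green <- lapply(seq_len(nz), function(z) {
      clip8(matrix(spec$intensity_mean, npx, npx) +
              if (spec$noise_sd > 0) {
                rnorm(npx * npx, 0, spec$noise_sd)
              } else 0)
    })
    garr <- array(0, dim = c(nz, npx, npx))
    for (z in seq_len(nz)) garr[z, , ] <- green[[z]]
    channels$p2ry12 <- garr
    proj <- do.call(pmax, green)
    intensity_percent <- 100 * mean(proj) / 255
  }

  stack <- image_stack(channels, pixel_size_um = s, z_step_um = 2,
                       bit_depth = 8,
                       id = sprintf("synthetic-%s-seed%d", spec$layer,
                                    spec$seed))
  truth <- structure(
    list(cells = cells, tips = tips_all,
         puncta = tibble(y_um = double(), x_um = double()),
         area_fraction = true_fraction,
         intensity_percent = intensity_percent,
         pixel_size_um = s, spec = spec),
    class = "ground_truth")
  list(stack = stack, truth = truth)
}

truncnorm1 <- function(mean, sd) {
  min(max(rnorm(1, mean, sd), mean - 2.5 * sd, 0.2 * mean), mean + 2.5 * sd)
}

truncnormk <- function(k, mean, sd) {
  pmin(pmax(rnorm(k, mean, sd), mean - 2.5 * sd), mean + 2.5 * sd)
}

clip8 <- function(m) {
  m <- round(m)
  m[m < 0] <- 0
  m[m > 255] <- 255
  if (!is.matrix(m)) m <- matrix(m, sqrt(length(m)))
  m
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d cells, %d puncta, signal fraction %.4f%s\n",
    nrow(x$cells), nrow(x$puncta), x$area_fraction,
    if (is.na(x$intensity_percent)) "" else
      sprintf(", green %.2f%%", x$intensity_percent)))
  invisible(x)
}

#' @rdname render_field
#' @param x A `ground_truth`.
#' @param ... Unused.
#' @return `tidy()` returns the per-cell catalogue as a tibble.
#' @export
tidy.ground_truth <- function(x, ...) x$cells

#' Render the OPL-OS interface plane with point-like vertical processes
#'
#' Vertical microglial processes crossing between the outer plexiform
#' layer and the outer segments appear as isolated bright puncta in the
#' plane between the layers. This renders `n_puncta` discs of
#' `punctum_radius_um` at `punctum_spacing_um` minimum separation plus
#' background and noise, and catalogues the planted centroids.
#'
#' @param spec A [field_spec()] (fields `n_puncta`, `punctum_*`, noise
#'   model and raster size are used; `layer` should be `"OPL_OS"`).
#' @return List with `image` ([field_image()]) and `truth`
#'   (`ground_truth` whose `puncta` tibble holds the planted centroids).
#' @export
render_puncta_plane <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  set.seed(spec$seed + 7919L)
  npx <- spec$field_px
  s <- spec$side_um / npx
  pr <- max(spec$punctum_radius_um, 0.9 * s)
  pts <- place_points(spec$n_puncta, spec$punctum_spacing_um,
                      spec$side_um, pr + 2)
  img <- matrix(0, npx, npx)
  if (spec$n_puncta > 0) {
    for (i in seq_len(nrow(pts))) {
      idx <- disc_indices(pts[i, 1], pts[i, 2], pr, s, npx, npx)
      img[idx] <- spec$soma_amplitude
    }
  }
  noisy <- clip8(img + spec$background_level +
                   if (spec$noise_sd > 0) {
                     rnorm(npx * npx, 0, spec$noise_sd)
                   } else 0)
  fi <- field_image(noisy, pixel_size_um = s, channel = "iba1",
                    provenance = sprintf("synthetic puncta plane seed %d",
                                         spec$seed))
  truth <- structure(
    list(cells = tibble(), tips = tibble(),
         puncta = tibble(y_um = pts[, 1], x_um = pts[, 2]),
         area_fraction = mean(img > 0), intensity_percent = NA_real_,
         pixel_size_um = s, spec = spec),
    class = "ground_truth")
  list(image = fi, truth = truth)
}
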