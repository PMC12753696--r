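#' Two-channel confocal-like image stack
#'
#' Container for a pair of 3-D voxel arrays (green, red) indexed
#' `[z, y, x]`, with acquisition metadata.  Intensities are integer counts
#' within the bit-depth range.  Indices follow the usual R convention
#' (1-based).
#'
#' @param green,red numeric arrays of identical dimension `c(nz, ny, nx)`.
#' @param z_step,slice_thickness axial step and optical slice thickness in
#'   micrometers (default 2 and 2).
#' @param bit_depth 8 or 16.
#' @param gain multiplicative factor applied at render time to map
#'   arbitrary-unit intensities into the bit-depth range; recorded so
#'   quantification can report generator units.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(green, red, z_step = 2, slice_thickness = 2,
                        bit_depth = 16, gain = 1) {
  if (!identical(dim(green), dim(red)) || length(dim(green)) != 3L) {
    stop("`green` and `red` must be 3-D arrays of identical dimension")
  }
  if (!bit_depth %in% c(8, 16)) stop("`bit_depth` must be 8 or 16")
  lim <- 2^bit_depth - 1
  if (min(green, red) < 0 || max(green, red) > lim) {
    stop("intensities must lie within the bit-depth range [0, ", lim, "]")
  }
  structure(list(green = green, red = red, z_step = z_step,
                 slice_thickness = slice_thickness, bit_depth = bit_depth,
                 gain = gain),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$green)
  cat(sprintf("<image_stack> %d z x %d y x %d x, %d-bit, z step %g um, gain %.4g\n",
              d[1], d[2], d[3], x$bit_depth, x$z_step, x$gain))
  invisible(x)
}

# smoothed spheroid profile: ~1 inside the nucleus, Gaussian-soft edge
nucleus_profile <- function(dz, dy, dx, radius, z_radius, edge_sigma) {
  d_norm <- sqrt((dx^2 + dy^2) / radius^2 + dz^2 / z_radius^2)
  stats::pnorm((1 - d_norm) * radius / edge_sigma)
}

#' Render a synthetic two-channel stack from per-cell measurements
#'
#' Each cell becomes a nucleus: a flat-top spheroid with a Gaussian-smoothed
#' edge, whose per-channel amplitude is calibrated by direct summation so
#' that the mean intensity over the nominal equatorial disk (radius
#' `radius`, at the nucleus centre plane) equals the cell's raw channel
#' value.  The flat-top profile makes the quantified mean robust to the
#' exact pixels a segmenter assigns to the nucleus, which is also how real
#' intestine nuclei (uniformly filled with freely diffusing fluorophore)
#' behave at this resolution.  Optional additive Gaussian read noise and
#' Poisson shot noise; intensities are quantized to integer counts at the
#' requested bit depth.
#'
#' @param cells data frame with columns `raw_green`, `raw_red` (one row per
#'   nucleus).
#' @param layout optional numeric matrix of nucleus centres, columns
#'   `(z, y, x)` in voxel coordinates; default places nuclei in a row along
#'   x at the stack midplane.
#' @param noise list: `read_sd` (Gaussian read-noise SD in counts, default
#'   0) and `shot` (logical, Poisson shot noise, default FALSE).
#' @param seed optional integer seed.
#' @param dim stack dimension `c(nz, ny, nx)`; `nx = NA` (default) sizes the
#'   x axis to fit the default layout.  An odd `nz` puts the default nucleus
#'   centre plane on a slice.
#' @param radius in-plane nucleus radius (pixels, default 4).
#' @param z_radius axial radius in slices (default 2).
#' @param edge_sigma edge softness in pixels (default 0.8).
#' @param bit_depth 8 or 16 (default 16).
#' @param spacing centre-to-centre spacing of the default layout (pixels).
#' @param background additive background level in counts (default 0).
#' @return An [image_stack()]; attribute `centers` holds the rendered
#'   nucleus centres (matrix, columns z, y, x) and attribute `truth` the
#'   input `cells`.
#' @export
render_animal_stack <- function(cells, layout = NULL,
                                noise = list(read_sd = 0, shot = FALSE),
                                seed = NULL, dim = c(15, 48, NA),
                                radius = 4, z_radius = 2, edge_sigma = 0.8,
                                bit_depth = 16, spacing = 16,
                                background = 0) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cells)
  nz <- dim[1]; ny <- dim[2]; nx <- dim[3]
  if (is.na(nx)) nx <- if (n > 0) spacing * n + spacing else 3 * spacing
  if (is.null(layout)) {
    layout <- cbind(z = rep((nz + 1) / 2, n),
                    y = rep((ny + 1) / 2, n),
                    x = spacing * (seq_len(n) - 0.5) + spacing / 2)
  }
  layout <- as.matrix(layout)
  if (n > 0) {
    pad_xy <- radius + 3 * edge_sigma
    pad_z <- z_radius + 2
    if (any(layout[, 1] < pad_z) || any(layout[, 1] > nz - pad_z + 1) ||
        any(layout[, 2] < pad_xy) || any(layout[, 2] > ny - pad_xy + 1) ||
        any(layout[, 3] < pad_xy) || any(layout[, 3] > nx - pad_xy + 1)) {
      stop("layout overflow: nucleus too close to the stack boundary")
    }
  }
  g <- array(background, c(nz, ny, nx))
  r <- array(background, c(nz, ny, nx))
  for (i in seq_len(n)) {
    cz <- layout[i, 1]; cy <- layout[i, 2]; cx <- layout[i, 3]
    zz <- max(1, floor(cz - z_radius - 3)):min(nz, ceiling(cz + z_radius + 3))
    yy <- max(1, floor(cy - radius - 4)):min(ny, ceiling(cy + radius + 4))
    xx <- max(1, floor(cx - radius - 4)):min(nx, ceiling(cx + radius + 4))
    dz <- array(rep(zz - cz, times = length(yy) * length(xx)),
                c(length(zz), length(yy), length(xx)))
    dy <- aperm(array(rep(yy - cy, times = length(zz) * length(xx)),
                      c(length(yy), length(zz), length(xx))), c(2, 1, 3))
    dx <- aperm(array(rep(xx - cx, times = length(zz) * length(yy)),
                      c(length(xx), length(zz), length(yy))), c(2, 3, 1))
    s <- nucleus_profile(dz, dy, dx, radius, z_radius, edge_sigma)
    # calibration: mean of the profile over the nominal equatorial disk
    eq_z <- which.min(abs(zz - cz))
    disk <- (dy[eq_z, , ]^2 + dx[eq_z, , ]^2) <= radius^2
    gmean <- mean(s[eq_z, , ][disk])
    g[zz, yy, xx] <- g[zz, yy, xx] + cells$raw_green[i] / gmean * s
    r[zz, yy, xx] <- r[zz, yy, xx] + cells$raw_red[i] / gmean * s
  }
  if (!is.null(noise$shot) && isTRUE(noise$shot)) {
    g[] <- stats::rpois(length(g), pmax(g, 0))
    r[] <- stats::rpois(length(r), pmax(r, 0))
  }
  if (!is.null(noise$read_sd) && noise$read_sd > 0) {
    g <- g + stats::rnorm(length(g), 0, noise$read_sd)
    r <- r + stats::rnorm(length(r), 0, noise$read_sd)
  }
  lim <- 2^bit_depth - 1
  peak <- max(g, r, 1)
  gain <- if (peak > 0.9 * lim) 0.8 * lim / peak else 1
  g <- pmin(pmax(round(g * gain), 0), lim)
  r <- pmin(pmax(round(r * gain), 0), lim)
  out <- image_stack(array(g, c(nz, ny, nx)), array(r, c(nz, ny, nx)),
                     bit_depth = bit_depth, gain = gain)
  attr(out, "centers") <- layout
  attr(out, "truth") <- cells
  out
}

#' Mean intensity over the nominal equatorial disk of a nucleus
#'
#' Direct-summation oracle for render calibration: the mean channel
#' intensity over the disk of the given radius at the nucleus centre plane,
#' in generator units (counts divided by the stack gain).
#'
#' @param stack an [image_stack()].
#' @param center numeric `(z, y, x)` nucleus centre.
#' @param radius disk radius in pixels.
#' @return Named numeric `c(green = ..., red = ...)`.
#' @export
equatorial_disk_mean <- function(stack, center, radius) {
  d <- dim(stack$green)
  z <- round(center[1])
  yy <- matrix(seq_len(d[2]) - center[2], d[2], d[3])
  xx <- matrix(rep(seq_len(d[3]) - center[3], each = d[2]), d[2], d[3])
  disk <- (yy^2 + xx^2) <= radius^2
  c(green = mean(stack$green[z, , ][disk]) / stack$gain,
    red = mean(stack$red[z, , ][disk]) / stack$gain)
}

# 6-connected component labeling of a 3-D logical array
label_components_3d <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  nzv <- which(mask)
  cur <- 0L
  for (start in nzv) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      co <- arrayInd(v, dims)
      for (axis in 1:3) {
        for (dd in c(-1L, 1L)) {
          nb <- co
          nb[axis] <- nb[axis] + dd
          if (nb[axis] < 1L || nb[axis] > dims[axis]) next
          li <- nb[1] + (nb[2] - 1L) * dims[1] + (nb[3] - 1L) * dims[1] * dims[2]
          if (mask[li] && lab[li] == 0L) {
            lab[li] <- cur
            queue <- c(queue, li)
          }
        }
      }
    }
  }
  lab
}

#' Segment nuclei in a two-channel stack
#'
#' Pipeline: Gaussian smoothing of the channel sum (per slice, plus a light
#' 1-2-1 axial filter), a single per-stack Otsu threshold, 3-D 6-connected
#' components, a size/shape filter, and choice of the equatorial slice as
#' the z index of maximal cross-section per component (ties broken toward
#' the lower z).  The reported equatorial mask is refined to the pixels at
#' or above half of the component's peak smoothed intensity (full width at
#' half maximum), so the quantified mean reflects the nucleus interior
#' rather than the soft boundary the global threshold happens to include.
#' Blank or saturated stacks yield an empty list rather than an error.
#'
#' @param stack an [image_stack()].
#' @param config list of parameters: `smooth_sigma` (pixels, default 1),
#'   `min_voxels`/`max_voxels` (component volume filter, defaults 20 and
#'   20000), `min_area`/`max_area` (equatorial area filter, defaults 5 and
#'   5000).
#' @return List of ROIs, each a list with `centroid` (z, y, x), `z_eq`,
#'   `mask` (logical ny-by-nx matrix at the equatorial slice), `area`
#'   (pixels), and `voxels` (linear indices of the 3-D component); ordered
#'   by centroid x.
#' @export
segment_nuclei <- function(stack, config = list()) {
  cfg <- utils::modifyList(
    list(smooth_sigma = 1, min_voxels = 20, max_voxels = 20000,
         min_area = 5, max_area = 5000),
    config
  )
  s <- stack$green + stack$red
  d <- dim(s)
  if (d[1] < 1L) stop("stack must have at least one slice")
  rng <- range(s)
  if (diff(rng) == 0) return(list())
  sm2d <- s
  for (z in seq_len(d[1])) {
    sm2d[z, , ] <- as.numeric(EBImage::gblur(EBImage::Image(s[z, , ]),
                                             sigma = cfg$smooth_sigma))
  }
  sm <- sm2d
  if (d[1] >= 3L) {
    for (z in 2:(d[1] - 1L)) {
      sm[z, , ] <- 0.25 * sm2d[z - 1, , ] + 0.5 * sm2d[z, , ] +
        0.25 * sm2d[z + 1, , ]
    }
  }
  lo <- min(sm); hi <- max(sm)
  if (hi - lo <= 0) return(list())
  # one global threshold for the whole stack: pool all voxels in one frame
  pooled <- EBImage::Image(matrix((sm - lo) / (hi - lo), ncol = 1L))
  thr <- EBImage::otsu(pooled, range = c(0, 1), levels = 256)
  thr <- lo + thr * (hi - lo)
  mask <- sm > thr
  if (!any(mask) || all(mask)) return(list())
  lab <- label_components_3d(mask)
  rois <- list()
  for (k in seq_len(max(lab))) {
    vox <- which(lab == k)
    if (length(vox) < cfg$min_voxels || length(vox) > cfg$max_voxels) next
    co <- arrayInd(vox, d)
    zcounts <- tabulate(co[, 1], nbins = d[1])
    z_eq <- which.max(zcounts)          # which.max takes the lowest z on ties
    # half-maximum mask in a local window around the component, so a dim
    # nucleus is not truncated by the single global threshold
    at <- co[co[, 1] == z_eq, , drop = FALSE]
    pad <- ceiling(2 * cfg$smooth_sigma + 2)
    ylo <- max(1, min(at[, 2]) - pad); yhi <- min(d[2], max(at[, 2]) + pad)
    xlo <- max(1, min(at[, 3]) - pad); xhi <- min(d[3], max(at[, 3]) + pad)
    half <- max(sm2d[vox]) / 2
    m <- matrix(FALSE, d[2], d[3])
    m[ylo:yhi, xlo:xhi] <- sm2d[z_eq, ylo:yhi, xlo:xhi] >= half
    # keep only this component's own blob: drop pixels claimed by another
    # component at this slice
    other <- lab[z_eq, , ]
    m <- m & (other == 0L | other == k)
    area <- sum(m)
    if (area < cfg$min_area || area > cfg$max_area) next
    rois[[length(rois) + 1L]] <- list(
      centroid = colMeans(co), z_eq = z_eq, mask = m,
      area = area, voxels = vox
    )
  }
  if (length(rois)) {
    rois <- rois[order(vapply(rois, function(r) r$centroid[3], 1))]
  }
  rois
}

#' Quantify segmented nuclei
#'
#' Per channel, the mean intensity over the ROI's equatorial mask minus a
#' background estimate, clipped at zero.  Background modes: `"global"` (the
#' median of all voxels outside every component) or `"annulus"` (the median
#' of an in-plane ring around the nucleus at its equatorial slice, excluding
#' component pixels).  Counts are converted back to generator units via the
#' stack gain.
#'
#' @param stack an [image_stack()].
#' @param rois ROI list from [segment_nuclei()] on the same stack.
#' @param background `"global"` or `"annulus"`.
#' @param annulus_width ring width in pixels (default 3).
#' @param annulus_gap gap between the nucleus mask and the inner edge of the
#'   ring (pixels, default 3), keeping the ring clear of the nucleus
#'   boundary.
#' @return Data frame, one row per ROI: centroid `z`, `y`, `x`, `area`,
#'   `raw_green`, `raw_red`, `bg_green`, `bg_red`, `background_mode`.
#' @export
quantify_nuclei <- function(stack, rois, background = c("global", "annulus"),
                            annulus_width = 3, annulus_gap = 3) {
  background <- match.arg(background)
  if (length(rois) == 0L) {
    return(data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                      area = numeric(0), raw_green = numeric(0),
                      raw_red = numeric(0), bg_green = numeric(0),
                      bg_red = numeric(0),
                      background_mode = character(0)))
  }
  d <- dim(stack$green)
  all_vox <- unique(unlist(lapply(rois, `[[`, "voxels")))
  bg_glob <- c(green = stats::median(stack$green[-all_vox]),
               red = stats::median(stack$red[-all_vox]))
  rows <- lapply(rois, function(roi) {
    if (!any(roi$mask)) stop("ROI with empty equatorial mask")
    gz <- stack$green[roi$z_eq, , ]
    rz <- stack$red[roi$z_eq, , ]
    if (background == "global") {
      bg <- bg_glob
    } else {
      br_in <- EBImage::makeBrush(2 * annulus_gap + 1, shape = "disc")
      br_out <- EBImage::makeBrush(2 * (annulus_gap + annulus_width) + 1,
                                   shape = "disc")
      img <- EBImage::Image(roi$mask * 1)
      dil <- (EBImage::dilate(img, br_out) > 0) & !(EBImage::dilate(img, br_in) > 0)
      excl <- matrix(FALSE, d[2], d[3])
      for (other in rois) {
        at <- arrayInd(other$voxels, d)
        at <- at[at[, 1] == roi$z_eq, , drop = FALSE]
        if (nrow(at)) excl[cbind(at[, 2], at[, 3])] <- TRUE
      }
      ring <- dil & !excl
      if (!any(ring)) {
        bg <- bg_glob
      } else {
        bg <- c(green = stats::median(gz[ring]), red = stats::median(rz[ring]))
      }
    }
    data.frame(z = roi$centroid[1], y = roi$centroid[2], x = roi$centroid[3],
               area = roi$area,
               raw_green = max(0, mean(gz[roi$mask]) - bg[["green"]]) / stack$gain,
               raw_red = max(0, mean(rz[roi$mask]) - bg[["red"]]) / stack$gain,
               bg_green = bg[["green"]], bg_red = bg[["red"]],
               background_mode = background,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a two-channel stack as multi-page TIFF
#'
#' Pages are channel-major (all green slices, then all red slices); a JSON
#' sidecar (`<path>.json`) records dimensions, metadata and gain so the
#' round trip is lossless at the stored bit depth.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   returns an [image_stack()].
#' @export
write_stack_tiff <- function(stack, path) {
  lim <- 2^stack$bit_depth - 1
  pages <- c(
    lapply(seq_len(dim(stack$green)[1]), function(z) stack$green[z, , ] / lim),
    lapply(seq_len(dim(stack$red)[1]), function(z) stack$red[z, , ] / lim)
  )
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  meta <- list(dim = dim(stack$green), z_step = stack$z_step,
               slice_thickness = stack$slice_thickness,
               bit_depth = stack$bit_depth, gain = stack$gain,
               channels = c("green", "red"), page_order = "channel-major")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- meta$dim[1]
  lim <- 2^meta$bit_depth - 1
  to_arr <- function(pp) {
    a <- array(0, meta$dim)
    for (z in seq_len(nz)) a[z, , ] <- round(pp[[z]] * lim)
    a
  }
  image_stack(to_arr(pages[seq_len(nz)]), to_arr(pages[nz + seq_len(nz)]),
              z_step = meta$z_step, slice_thickness = meta$slice_thickness,
              bit_depth = meta$bit_depth, gain = meta$gain)
}
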