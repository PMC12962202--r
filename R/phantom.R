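#' @keywords internal
new_phantom <- function(m0, pdff, t1w, t1f, r2star, psi, label_map,
                        vial_layout, matrix, fov_cm, kind) {
  structure(
    list(m0 = m0, pdff = pdff, t1_water_ms = t1w, t1_fat_ms = t1f,
         r2star_s = r2star, psi_hz = psi, label_map = label_map,
         vial_layout = vial_layout, matrix = matrix, fov_cm = fov_cm,
         voxel_cm = fov_cm / matrix, kind = kind),
    class = "fam_phantom"
  )
}

#' @export
print.fam_phantom <- function(x, ...) {
  cat("<fam_phantom> (", x$kind, ") ", x$matrix[1], "x", x$matrix[2],
      ", FOV ", x$fov_cm[1], "x", x$fov_cm[2], " cm, ",
      max(x$label_map), " labelled regions\n", sep = "")
  invisible(x)
}

# voxel-center coordinate grids in cm, origin at FOV center
phantom_grids <- function(matrix, fov_cm) {
  vx <- fov_cm / matrix
  x <- (seq_len(matrix[1]) - (matrix[1] + 1) / 2) * vx[1]
  y <- (seq_len(matrix[2]) - (matrix[2] + 1) / 2) * vx[2]
  list(x = outer(x, rep(1, matrix[2])), y = outer(rep(1, matrix[1]), y))
}

#' Digital PDFF x T1 vial phantom
#'
#' Builds the 16-vial digital phantom: a 4 x 4 grid of cylindrical vials
#' covering all combinations of PDFF (0, 10, 20, 30%) and water T1 (200, 600,
#' 1000, 1400 ms), with fat T1 fixed at 300 ms, a common R2* and zero field
#' offset by default. Vial edges taper over a two-voxel anti-aliasing band on
#' the proton-density map only; parameter maps are constant inside each vial,
#' so center ROIs never see the edge model. The construction is fully
#' deterministic.
#'
#' @param matrix Grid size `c(nx, ny)`.
#' @param fov_cm Field of view `c(x, y)` in cm.
#' @param pdff_values,t1w_values_ms Nominal grids (fractions; ms). PDFF varies
#'   along x, T1w along y.
#' @param t1_fat_ms Fat T1 (ms) everywhere (default 300).
#' @param r2star_s Common R2* inside vials (1/s; default 40).
#' @param psi_hz Field offset: a scalar (default 0) or a function
#'   `f(x_cm, y_cm)` evaluated on the voxel grid for a smooth background.
#' @param vial_radius_cm Vial radius (default 2.5 cm).
#' @param edge_voxels Width of the anti-aliased edge band (voxels).
#' @return A `fam_phantom` with a 16-row `vial_layout` tibble.
#' @export
make_pdff_t1_phantom <- function(matrix = c(144L, 144L), fov_cm = c(44, 44),
                                 pdff_values = c(0, 0.10, 0.20, 0.30),
                                 t1w_values_ms = c(200, 600, 1000, 1400),
                                 t1_fat_ms = 300, r2star_s = 40, psi_hz = 0,
                                 vial_radius_cm = 2.5, edge_voxels = 2) {
  matrix <- as.integer(matrix)
  fov_cm <- as.numeric(fov_cm)
  npx <- length(pdff_values); npy <- length(t1w_values_ms)
  cell <- c(fov_cm[1] / npx, fov_cm[2] / npy)
  if (2 * vial_radius_cm >= min(cell)) {
    stop("vials would overlap: 2 * vial_radius_cm must be below the grid cell size",
         call. = FALSE)
  }
  vx <- min(fov_cm / matrix)
  if (2 * vial_radius_cm / vx < 8) {
    stop("matrix too coarse: each vial must span at least 8 voxels", call. = FALSE)
  }
  g <- phantom_grids(matrix, fov_cm)
  dims <- matrix
  m0 <- array(0, dims); pdff <- array(0, dims)
  t1w <- array(1000, dims); t1f <- array(t1_fat_ms, dims)
  r2 <- array(0, dims); label <- array(0L, dims)
  psi <- if (is.function(psi_hz)) psi_hz(g$x, g$y) else array(psi_hz, dims)
  edge_cm <- edge_voxels * vx
  layout <- vector("list", npx * npy)
  id <- 0L
  for (jy in seq_len(npy)) {
    for (jx in seq_len(npx)) {
      id <- id + 1L
      cx <- (jx - (npx + 1) / 2) * cell[1]
      cy <- (jy - (npy + 1) / 2) * cell[2]
      r <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
      inside <- r <= vial_radius_cm
      # soft edge strictly inside the vial radius
      taper <- pmin(1, pmax(0, (vial_radius_cm - r) / edge_cm))
      m0[inside] <- taper[inside]
      pdff[inside] <- pdff_values[jx]
      t1w[inside] <- t1w_values_ms[jy]
      r2[inside] <- r2star_s
      label[inside] <- id
      layout[[id]] <- tibble::tibble(
        vial = id, cx_cm = cx, cy_cm = cy, radius_cm = vial_radius_cm,
        pdff = pdff_values[jx], t1w_ms = t1w_values_ms[jy]
      )
    }
  }
  new_phantom(m0, pdff, t1w, t1f, r2, psi, label,
              dplyr::bind_rows(layout), matrix, fov_cm, kind = "pdff_t1_vials")
}

#' Centered circular ROIs on phantom vials
#'
#' One circular ROI per vial, centered on the vial, with the given physical
#' diameter (default 1.4 cm, the conventional vial ROI size).
#'
#' @param phantom A vial phantom from [make_pdff_t1_phantom()].
#' @param diameter_cm ROI diameter (cm); must be smaller than the vial
#'   diameter.
#' @return A tibble with one row per vial: ids, nominal `pdff` and `t1w_ms`,
#'   center/radius in voxel units, a list-column `voxels` of linear map
#'   indices, and `n_vox`.
#' @export
vial_rois <- function(phantom, diameter_cm = 1.4) {
  stopifnot(inherits(phantom, "fam_phantom"))
  layout <- phantom$vial_layout
  if (is.null(layout)) stop("phantom has no vial layout", call. = FALSE)
  if (any(diameter_cm >= 2 * layout$radius_cm)) {
    stop("ROI diameter must be smaller than the vial diameter", call. = FALSE)
  }
  g <- phantom_grids(phantom$matrix, phantom$fov_cm)
  purrr::pmap_dfr(layout, function(vial, cx_cm, cy_cm, radius_cm, pdff, t1w_ms) {
    r <- sqrt((g$x - cx_cm)^2 + (g$y - cy_cm)^2)
    idx <- which(r <= diameter_cm / 2)
    tibble::tibble(
      roi = vial, pdff = pdff, t1w_ms = t1w_ms,
      cx_cm = cx_cm, cy_cm = cy_cm, radius_cm = diameter_cm / 2,
      voxels = list(idx), n_vox = length(idx)
    )
  })
}

#' Synthetic liver slice with nine-segment labels
#'
#' A schematic liver-like elliptical region partitioned into nine angular
#' sectors standing in for the Couinaud segments; only the nine-label
#' bookkeeping matters for whole-liver averaging. PDFF and R2* vary smoothly
#' (deterministic sinusoidal/linear fields) around the requested levels.
#'
#' @param matrix,fov_cm Grid and field of view.
#' @param pdff_level Mean PDFF (fraction in `[0, 0.4]`).
#' @param r2star_range R2* range (1/s) spanned linearly across the slice.
#' @param heterogeneity Peak-to-peak PDFF variation (fraction) superimposed
#'   on `pdff_level`; 0 gives a uniform liver.
#' @param t1_water_ms,t1_fat_ms Species T1 values (ms).
#' @return A `fam_phantom` whose `label_map` holds segments 1-9.
#' @export
make_synthetic_liver <- function(matrix = c(144L, 144L), fov_cm = c(44, 44),
                                 pdff_level = 0.1, r2star_range = c(30, 60),
                                 heterogeneity = 0, t1_water_ms = 800,
                                 t1_fat_ms = 300) {
  if (pdff_level < 0 || pdff_level > 0.4) {
    stop("pdff_level must lie in [0, 0.4]", call. = FALSE)
  }
  matrix <- as.integer(matrix); fov_cm <- as.numeric(fov_cm)
  g <- phantom_grids(matrix, fov_cm)
  a <- 0.38 * fov_cm[1]; b <- 0.28 * fov_cm[2]
  inside <- (g$x / a)^2 + (g$y / b)^2 <= 1
  theta <- atan2(g$y, g$x)                   # (-pi, pi]
  seg <- pmin(9L, 1L + as.integer(floor((theta + pi) / (2 * pi) * 9)))
  label <- array(0L, matrix); label[inside] <- seg[inside]
  pdff <- array(0, matrix)
  pdff[inside] <- pmax(0, pdff_level +
    heterogeneity / 2 * sin(2 * theta[inside]) * cos(pi * g$x[inside] / a))
  r2 <- array(0, matrix)
  xr <- (g$x / a + 1) / 2
  r2[inside] <- r2star_range[1] + (r2star_range[2] - r2star_range[1]) * xr[inside]
  m0 <- array(0, matrix); m0[inside] <- 1
  t1w <- array(t1_water_ms, matrix); t1f <- array(t1_fat_ms, matrix)
  new_phantom(m0, pdff, t1w, t1f, r2, array(0, matrix), label,
              vial_layout = NULL, matrix, fov_cm, kind = "synthetic_liver")
}

#' ROIs from a label map
#'
#' Builds an ROI tibble (same shape as [vial_rois()]) from the labelled
#' regions of a phantom, e.g. the nine liver segments.
#'
#' @param phantom A `fam_phantom`.
#' @return Tibble with `roi`, `voxels` list-column and `n_vox`.
#' @export
label_rois <- function(phantom) {
  stopifnot(inherits(phantom, "fam_phantom"))
  labs <- sort(unique(phantom$label_map[phantom$label_map > 0]))
  purrr::map_dfr(labs, function(l) {
    idx <- which(phantom$label_map == l)
    tibble::tibble(roi = l, voxels = list(idx), n_vox = length(idx))
  })
}
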