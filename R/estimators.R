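#' @title Single-kidney volume estimators
#' @description
#' Five estimators of single-kidney volume (SKV, ml) from sectioned data:
#' planimetry (Cavalieri sum of traced areas), stereology (grid point
#' counting), the mid-slice shortcut, the ellipsoid caliper formula, and
#' kidney length. All return a `kv_estimate` carrying the method tag, the
#' SKV in ml, and the intermediates sufficient to recompute it.
#' @name estimators
NULL

new_estimate <- function(method, skv_ml, side = NA_character_,
                         intermediates = list()) {
  structure(list(method = method, skv_ml = skv_ml, side = side,
                 intermediates = intermediates),
            class = "kv_estimate")
}

#' @export
print.kv_estimate <- function(x, ...) {
  cat(sprintf("<kv_estimate> %s: %.2f ml%s\n", x$method, x$skv_ml,
              if (is.na(x$side)) "" else paste0(" (", x$side, ")")))
  invisible(x)
}

#' Planimetry (Cavalieri) volume from traced outlines
#'
#' The reference method: SKV is the sum of the outline areas on all
#' contiguous slices, multiplied by the slice thickness. Areas are computed
#' with the shoelace formula.
#'
#' @param contours a [contour_stack()] result (or same-shaped object).
#' @return A `kv_estimate` with method `"polyline_planimetry"`;
#'   `intermediates$areas_mm2` holds the per-slice areas.
#' @export
planimetry_volume <- function(contours) {
  stopifnot(inherits(contours, "kv_contours"))
  if (length(contours$slices) < 1) stop("need at least one slice")
  areas <- vapply(seq_along(contours$slices), function(i) {
    v <- contours$slices[[i]]$vertices
    if (is_self_intersecting(v))
      stop(sprintf("self-intersecting polygon on slice %d",
                   contours$slices[[i]]$slice_index))
    polygon_area(v)
  }, numeric(1))
  t <- contours$geometry$slice_thickness
  new_estimate("polyline_planimetry", sum(areas) * t / 1000,
               intermediates = list(areas_mm2 = areas, slice_thickness = t))
}

# quick rejection: stack-native polygons are radial (angularly monotone
# about their centroid) and cannot self-intersect, so the O(n) angle check
# short-circuits; anything else gets the full segment-pair scan.
is_self_intersecting <- function(v) {
  ctr <- colMeans(v)
  ang <- atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])
  d <- diff(c(ang, ang[1]))
  d <- (d + pi) %% (2 * pi) - pi       # wrap steps into (-pi, pi]
  if (all(d > 0) || all(d < 0)) return(FALSE)
  segments_cross(v)
}

segments_cross <- function(v) {
  n <- nrow(v)
  a <- v; b <- rbind(v[-1, , drop = FALSE], v[1, ])
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]
    if (!length(js)) next
    if (any(seg_int(a[i, ], b[i, ], a[js, , drop = FALSE],
                    b[js, , drop = FALSE]))) return(TRUE)
  }
  FALSE
}

seg_int <- function(p1, p2, q1, q2) {
  d1 <- (p2[1] - p1[1]) * (q1[, 2] - p1[2]) - (p2[2] - p1[2]) * (q1[, 1] - p1[1])
  d2 <- (p2[1] - p1[1]) * (q2[, 2] - p1[2]) - (p2[2] - p1[2]) * (q2[, 1] - p1[1])
  d3 <- (q2[, 1] - q1[, 1]) * (p1[2] - q1[, 2]) - (q2[, 2] - q1[, 2]) * (p1[1] - q1[, 1])
  d4 <- (q2[, 1] - q1[, 1]) * (p2[2] - q1[, 2]) - (q2[, 2] - q1[, 2]) * (p2[1] - q1[, 1])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Stereology sampling grid
#'
#' A cross grid randomly positioned over the slice stack. Defaults follow
#' routine practice for kidney volumetry: 16 x 16 mm spacing with 16 mm
#' slice sampling on MR, 15 x 15 mm with 15 mm on CT. The in-plane offset
#' is uniform on the grid cell and the slice phase uniform over the slice
#' subsampling period.
#'
#' @param geom an [imaging_geometry()] (sets the modality defaults).
#' @param spacing length-2 grid spacing (gx, gy) mm.
#' @param grid_slice_thickness slice sampling period, mm.
#' @param seed integer; the random offset is drawn deterministically from it.
#' @param offset optional explicit offset `c(ox, oy, slice_phase)` with
#'   `0 <= ox < gx`, `0 <= oy < gy`, integer phase in `[0, step)`;
#'   overrides the random draw.
#' @return An object of class `kv_stereology_grid`.
#' @export
stereology_grid <- function(geom, spacing = NULL,
                            grid_slice_thickness = NULL, seed = 1L,
                            offset = NULL) {
  stopifnot(inherits(geom, "kv_geometry"))
  if (is.null(spacing))
    spacing <- if (geom$modality == "MR") c(16, 16) else c(15, 15)
  if (is.null(grid_slice_thickness))
    grid_slice_thickness <- if (geom$modality == "MR") 16 else 15
  if (any(spacing < geom$in_plane_spacing))
    stop("grid spacing must be at least the voxel spacing")
  step <- max(1L, as.integer(round(grid_slice_thickness /
                                     geom$slice_thickness)))
  if (is.null(offset)) {
    set.seed(child_seed(seed, "stereology-grid"))
    offset <- c(stats::runif(1, 0, spacing[1]),
                stats::runif(1, 0, spacing[2]),
                sample.int(step, 1) - 1L)
  } else {
    if (offset[1] < 0 || offset[1] >= spacing[1] ||
        offset[2] < 0 || offset[2] >= spacing[2] ||
        offset[3] < 0 || offset[3] >= step)
      stop("offset components must lie within their periods")
  }
  structure(list(spacing = spacing,
                 grid_slice_thickness = grid_slice_thickness,
                 slice_step = step, offset = offset, seed = as.integer(seed)),
            class = "kv_stereology_grid")
}

#' Stereology (point-counting) volume
#'
#' Counts grid crosses falling on foreground voxels, on slices sampled
#' every `round(grid_slice_thickness / slice_thickness)` slices with a
#' random phase; SKV = count x gx x gy x grid slice thickness. Unbiased
#' over uniform random grid offsets (Cavalieri/point-counting property).
#'
#' @param mask a `kv_mask`.
#' @param grid a [stereology_grid()].
#' @return A `kv_estimate` with method `"stereology"`; intermediates hold
#'   the point count and grid specification. Count 0 yields a zero
#'   estimate with a warning.
#' @export
stereology_volume <- function(mask, grid) {
  stopifnot(inherits(mask, "kv_mask"), inherits(grid, "kv_stereology_grid"))
  g <- mask$geometry
  m <- g$matrix_size
  half <- m * g$in_plane_spacing / 2
  # grid point coordinates across the FOV
  px <- seq(-half + grid$offset[1], half, by = grid$spacing[1])
  py <- seq(-half + grid$offset[2], half, by = grid$spacing[2])
  ix <- floor((px + half) / g$in_plane_spacing) + 1
  iy <- floor((py + half) / g$in_plane_spacing) + 1
  keep_x <- ix >= 1 & ix <= m
  keep_y <- iy >= 1 & iy <= m
  ix <- ix[keep_x]; iy <- iy[keep_y]
  # sampled slices: global slice index congruent to phase (mod step)
  sel <- which((mask$slice_index %% grid$slice_step) == grid$offset[3])
  count <- 0L
  for (si in sel)
    count <- count + sum(mask$voxels[ix, iy, si])
  if (count == 0)
    warning("stereology grid did not hit the object; estimate is 0")
  skv <- count * grid$spacing[1] * grid$spacing[2] *
    grid$grid_slice_thickness / 1000
  new_estimate("stereology", skv,
               intermediates = list(point_count = count,
                                    spacing = grid$spacing,
                                    grid_slice_thickness = grid$grid_slice_thickness,
                                    offset = grid$offset))
}

#' Mid-slice volume estimate
#'
#' The single-slice shortcut: SKV = mid-slice outline area x number of
#' slices covering the kidney x slice thickness x an empirical shape
#' factor (0.637 for the right kidney, 0.624 for the left). The mid-slice
#' is the slice at the floor midpoint of the covering slice-index range.
#'
#' @param contours a `kv_contours` object.
#' @param side `"right"` or `"left"` (selects the factor).
#' @return A `kv_estimate` with method `"midslice"`.
#' @export
midslice_volume <- function(contours, side = c("right", "left")) {
  stopifnot(inherits(contours, "kv_contours"))
  side <- match.arg(side)
  idx <- vapply(contours$slices, `[[`, numeric(1), "slice_index")
  mid_index <- floor((min(idx) + max(idx)) / 2)
  wh <- which(idx == mid_index)
  if (!length(wh)) wh <- which.min(abs(idx - mid_index))
  a_mid <- polygon_area(contours$slices[[wh[1]]]$vertices)
  n <- length(idx)
  t <- contours$geometry$slice_thickness
  k <- if (side == "right") 0.637 else 0.624
  new_estimate("midslice", a_mid * n * t * k / 1000, side = side,
               intermediates = list(mid_area_mm2 = a_mid, n_slices = n,
                                    slice_thickness = t, factor = k,
                                    mid_slice_index = mid_index))
}

#' Orthogonal caliper measurements of a kidney mask
#'
#' Automates the viewer measurements behind the ellipsoid method:
#' kidney length on the coronal and sagittal views is the maximal chord of
#' the mask silhouette projected onto the respective plane (computed from
#' the convex hull of projected voxel centres, plus one pixel pitch for
#' voxel extent); width (left-right) and depth (antero-posterior) are the
#' axis-aligned extents on the axial level with the largest cross-sectional
#' area (ties broken toward the inferior-most level).
#'
#' @param mask a `kv_mask` with at least one foreground voxel.
#' @return A list of class `kv_axes`: `length_coronal`, `length_sagittal`,
#'   `width`, `depth` (all mm).
#' @export
measure_axes <- function(mask) {
  pts <- voxel_world_coords(mask)
  if (nrow(pts) == 0) stop("empty mask")
  g <- mask$geometry
  # voxel extent along each world axis: slice thickness on the slicing
  # axis, pixel pitch in-plane — used to pad centre-to-centre distances
  pad <- rep(g$in_plane_spacing, 3)
  pad[slice_axis_index(g)] <- g$slice_thickness
  len_cor <- max_chord(pts[, c(1, 3), drop = FALSE]) + pad[3]
  len_sag <- max_chord(pts[, c(2, 3), drop = FALSE]) + pad[3]
  # axial level with largest area: bin z at the native z resolution
  zb <- round(pts[, 3], 6)
  counts <- table(zb)
  zvals <- as.numeric(names(counts))
  best <- zvals[counts == max(counts)]
  z0 <- min(best)                      # inferior-most on ties
  on <- zb == z0
  width <- diff(range(pts[on, 1])) + pad[1]
  depth <- diff(range(pts[on, 2])) + pad[2]
  structure(list(length_coronal = len_cor, length_sagittal = len_sag,
                 width = width, depth = depth),
            class = "kv_axes")
}

# world coordinates (n x 3, x/y/z mm) of foreground voxel centres
voxel_world_coords <- function(mask) {
  g <- mask$geometry
  ip <- in_plane_axes(g)
  sx <- slice_axis_index(g)
  uc <- pixel_centres(g)
  w <- which(mask$voxels, arr.ind = TRUE)
  pts <- matrix(0, nrow(w), 3)
  pts[, ip[1]] <- uc[w[, 1]]
  pts[, ip[2]] <- uc[w[, 2]]
  pts[, sx] <- mask$slice_z[w[, 3]]
  pts
}

# maximal pairwise distance of 2-D points, via convex hull
max_chord <- function(p2) {
  if (nrow(p2) == 1) return(0)
  h <- grDevices::chull(p2)
  hp <- p2[h, , drop = FALSE]
  max(stats::dist(hp))
}

#' Ellipsoid-method volume from caliper measurements
#'
#' SKV = mean(coronal, sagittal length) x width x depth x pi/6. Exact for
#' an axis-aligned ellipsoid; on irregular (cystic) kidneys it
#' systematically underestimates, because a lumpy body holds more volume
#' than the ellipsoid inscribed in its caliper box.
#'
#' @param axes a [measure_axes()] result (or list with the same fields).
#' @param side `"right"` or `"left"` (tag only).
#' @return A `kv_estimate` with method `"ellipsoid"`.
#' @export
ellipsoid_method_volume <- function(axes, side = c("right", "left")) {
  side <- match.arg(side)
  vals <- c(axes$length_coronal, axes$length_sagittal, axes$width, axes$depth)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all caliper measurements must be positive")
  L <- mean(c(axes$length_coronal, axes$length_sagittal))
  new_estimate("ellipsoid", L * axes$width * axes$depth * pi / 6 / 1000,
               side = side,
               intermediates = list(length_mean = L, width = axes$width,
                                    depth = axes$depth,
                                    length_coronal = axes$length_coronal,
                                    length_sagittal = axes$length_sagittal))
}

#' Kidney length
#'
#' The larger of the coronal and sagittal maximal-chord lengths, in cm —
#' the convention used when length is read off whichever view shows the
#' organ longest.
#'
#' @param mask a `kv_mask`.
#' @return Length in cm.
#' @export
kidney_length <- function(mask) {
  ax <- measure_axes(mask)
  max(ax$length_coronal, ax$length_sagittal) / 10
}
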