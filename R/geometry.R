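#' Imaging geometry of a tomographic acquisition
#'
#' Describes the sampling lattice a kidney is sectioned on: slicing axis,
#' slice thickness, in-plane pixel spacing and matrix size. The patient
#' frame is right-handed with x = left-right, y = antero-posterior,
#' z = superior-inferior (all mm). Coronal slices are stacked along y,
#' axial slices along z. Slice `i` (0-based) spans
#' `[origin_offset + i*t, origin_offset + (i+1)*t)` along the slicing axis
#' and is evaluated on its mid-plane.
#'
#' Defaults follow typical clinical protocols for polycystic kidney
#' volumetry: MR is acquired coronally at 4 mm slice thickness, CT axially
#' and resampled to 5 mm for volume computation.
#'
#' @param modality `"MR"` or `"CT"`. Sets defaults for the other arguments.
#' @param slicing_axis `"coronal"` or `"axial"`. Default: coronal for MR,
#'   axial for CT.
#' @param slice_thickness slice thickness in mm (> 0).
#' @param in_plane_spacing isotropic in-plane pixel size in mm (> 0).
#' @param matrix_size pixels per in-plane side; the field of view is
#'   `matrix_size * in_plane_spacing`, centred on the origin.
#' @param origin_offset position (mm) of the first slice boundary relative
#'   to the patient frame; shifting it by a fraction of the slice thickness
#'   moves the slice phase.
#' @return An object of class `kv_geometry`.
#' @examples
#' imaging_geometry("MR")
#' imaging_geometry("CT", slice_thickness = 5)
#' @export
imaging_geometry <- function(modality = c("MR", "CT"),
                             slicing_axis = NULL,
                             slice_thickness = NULL,
                             in_plane_spacing = NULL,
                             matrix_size = NULL,
                             origin_offset = 0) {
  modality <- match.arg(modality)
  if (is.null(slicing_axis))
    slicing_axis <- if (modality == "MR") "coronal" else "axial"
  slicing_axis <- match.arg(slicing_axis, c("coronal", "axial", "sagittal"))
  if (is.null(slice_thickness))
    slice_thickness <- if (modality == "MR") 4 else 5
  if (is.null(in_plane_spacing))
    in_plane_spacing <- if (modality == "MR") 1.5 else 0.8
  if (is.null(matrix_size))
    matrix_size <- if (modality == "MR") 256L else 512L
  if (slice_thickness <= 0) stop("slice_thickness must be > 0")
  if (in_plane_spacing <= 0) stop("in_plane_spacing must be > 0")
  matrix_size <- as.integer(matrix_size)
  if (matrix_size < 1) stop("matrix_size must be >= 1")
  structure(
    list(modality = modality, slicing_axis = slicing_axis,
         slice_thickness = slice_thickness,
         in_plane_spacing = in_plane_spacing,
         matrix_size = matrix_size, origin_offset = origin_offset),
    class = "kv_geometry")
}

#' @export
print.kv_geometry <- function(x, ...) {
  cat(sprintf("<kv_geometry> %s, %s slices, t = %g mm, %d x %d px @ %g mm\n",
              x$modality, x$slicing_axis, x$slice_thickness,
              x$matrix_size, x$matrix_size, x$in_plane_spacing))
  invisible(x)
}

# world-frame axis index the slices are stacked along (x=1, y=2, z=3)
slice_axis_index <- function(geom) {
  switch(geom$slicing_axis, sagittal = 1L, coronal = 2L, axial = 3L)
}

# the two in-plane world axes, in (u, v) order
in_plane_axes <- function(geom) {
  setdiff(1:3, slice_axis_index(geom))
}

# in-plane pixel-centre coordinates (centred FOV)
pixel_centres <- function(geom) {
  m <- geom$matrix_size
  (seq_len(m) - (m + 1) / 2) * geom$in_plane_spacing
}

# mid-plane position of slice index i (0-based)
slice_midplane <- function(geom, i) {
  geom$origin_offset + (i + 0.5) * geom$slice_thickness
}

# 0-based slice indices whose slab intersects [lo, hi] on the slicing axis
slice_range <- function(geom, lo, hi) {
  t <- geom$slice_thickness
  i0 <- floor((lo - geom$origin_offset) / t)
  i1 <- ceiling((hi - geom$origin_offset) / t) - 1
  seq.int(i0, max(i0, i1))
}

# intrinsic x-y-z Euler rotation matrix (radians)
rotation_matrix <- function(angles) {
  a <- angles[1]; b <- angles[2]; g <- angles[3]
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# deterministic child seed from a parent seed and a label, < 2^31
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
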