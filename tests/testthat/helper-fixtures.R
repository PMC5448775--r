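# Shared fixtures: small geometries and canonical phantoms, built in code.

# sphere of radius 60 mm (904.779 ml)
sphere60 <- function() kidney_phantom(ellipsoid_spec(c(60, 60, 60)))

# axis-aligned ellipsoid a = b = 50, c = 75 mm (785.398 ml)
ell5075 <- function(rotation = c(0, 0, 0))
  kidney_phantom(ellipsoid_spec(c(50, 50, 75), rotation = rotation))

# coarse test geometries (small matrices keep the suite fast)
geo_mr_coarse <- function(spacing = 2, matrix_size = 160L, offset = 0)
  imaging_geometry("MR", in_plane_spacing = spacing,
                   matrix_size = matrix_size, origin_offset = offset)

geo_ct_coarse <- function(spacing = 1, matrix_size = 160L, offset = 0)
  imaging_geometry("CT", in_plane_spacing = spacing,
                   matrix_size = matrix_size, origin_offset = offset)

# hand-built single-contour stack (square side `side` mm on one slice)
square_contours <- function(side = 100, thickness = 5) {
  geom <- imaging_geometry("CT", slice_thickness = thickness,
                           in_plane_spacing = 1, matrix_size = 256L)
  h <- side / 2
  verts <- rbind(c(-h, -h), c(h, -h), c(h, h), c(-h, h))
  structure(list(geometry = geom,
                 slices = list(list(slice_index = 0L,
                                    z_mm = thickness / 2,
                                    origin_uv = c(0, 0),
                                    vertices = verts))),
            class = "kv_contours")
}

# axis-aligned box mask: box half-sides (mm), lattice spacing/thickness
box_mask <- function(half = 80, spacing = 2, thickness = 16,
                     matrix_size = 100L, n_slices = 10L) {
  geom <- imaging_geometry("CT", slice_thickness = thickness,
                           in_plane_spacing = spacing,
                           matrix_size = matrix_size,
                           origin_offset = -half)
  uc <- (seq_len(matrix_size) - (matrix_size + 1) / 2) * spacing
  inside <- abs(uc) < half
  plane <- outer(inside, inside, "&")
  vox <- array(rep(plane, n_slices),
               dim = c(matrix_size, matrix_size, n_slices))
  idx <- seq_len(n_slices) - 1L
  structure(list(geometry = geom, voxels = vox, slice_index = idx,
                 slice_z = -half + (idx + 0.5) * thickness),
            class = "kv_mask")
}
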