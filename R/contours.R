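#' Per-slice contour stack of a phantom
#'
#' Emulates slice-by-slice outlining: for every slice whose mid-plane cuts
#' the phantom, a closed polygon is cast from the in-plane projection of
#' the phantom centre by radial ray/surface root finding, giving vertices
#' in slice-plane mm coordinates with counter-clockwise orientation.
#' Degenerate (zero-area) intersections, e.g. a tangent plane, are omitted.
#'
#' With the default 128 vertices the chord (inscribed-polygon) area deficit
#' for a circle is \eqn{1 - \mathrm{sinc}(2\pi/n) \approx 0.1\%} at n = 64
#' and 0.025% at n = 128.
#'
#' @param phantom a [kidney_phantom()].
#' @param geom an [imaging_geometry()].
#' @param n_vertices polygon vertices per contour (default 128).
#' @return An object of class `kv_contours`: list with `geometry`,
#'   `slices` — a list of `list(slice_index, z_mm, origin_uv, vertices)`
#'   where `vertices` is an `n x 2` matrix in (u, v) slice-plane mm.
#' @export
contour_stack <- function(phantom, geom, n_vertices = 128L) {
  stopifnot(inherits(phantom, "kv_phantom"), inherits(geom, "kv_geometry"))
  n_vertices <- as.integer(n_vertices)
  if (n_vertices < 8) stop("n_vertices must be >= 8")
  sx <- slice_axis_index(geom)
  ip <- in_plane_axes(geom)
  ctr <- phantom$base$center
  reach <- phantom_reach(phantom)
  idx <- slice_range(geom, ctr[sx] - reach, ctr[sx] + reach)
  psi <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  dirs <- cbind(cos(psi), sin(psi))
  slices <- list()
  for (i in idx) {
    z <- slice_midplane(geom, i)
    q <- ctr; q[sx] <- z           # ray origin: centre projected on plane
    if (!phantom_inside(phantom, matrix(q, 1))) next
    radii <- ray_radii(phantom, q, ip, dirs, reach * 2.5)
    if (any(!is.finite(radii)) || all(radii < 1e-6)) next
    verts <- cbind(q[ip[1]] + radii * dirs[, 1],
                   q[ip[2]] + radii * dirs[, 2])
    if (polygon_area(verts) <= 1e-9) next
    slices[[length(slices) + 1]] <-
      list(slice_index = i, z_mm = z,
           origin_uv = c(q[ip[1]], q[ip[2]]), vertices = verts)
  }
  if (length(slices) == 0)
    stop("phantom does not intersect any slice mid-plane")
  structure(list(geometry = geom, slices = slices), class = "kv_contours")
}

# boundary distance along in-plane rays from a point q known to be inside:
# vectorised bisection on f(t) = |p(t)|_local - R(u(t)) over all rays
ray_radii <- function(phantom, q, ip, dirs, tmax) {
  n <- nrow(dirs)
  fvals <- function(t) {
    pts <- matrix(rep(q, each = n), n, 3)
    pts[, ip[1]] <- q[ip[1]] + t * dirs[, 1]
    pts[, ip[2]] <- q[ip[2]] + t * dirs[, 2]
    loc <- to_local(phantom, pts)
    r <- sqrt(rowSums(loc^2))
    r - phantom_radius(phantom, loc / pmax(r, 1e-12))
  }
  lo <- rep(0, n)
  hi <- rep(tmax, n)
  bad <- fvals(hi) < 0
  if (any(bad)) return(rep(NA_real_, n))
  for (it in 1:45) {
    mid <- (lo + hi) / 2
    pos <- fvals(mid) > 0
    hi[pos] <- mid[pos]
    lo[!pos] <- mid[!pos]
  }
  (lo + hi) / 2
}

#' @export
print.kv_contours <- function(x, ...) {
  cat(sprintf("<kv_contours> %d slices (%s, t = %g mm), planimetry %.1f ml\n",
              length(x$slices), x$geometry$slicing_axis,
              x$geometry$slice_thickness,
              planimetry_volume(x)$skv_ml))
  invisible(x)
}

#' Shoelace area of a simple polygon
#'
#' @param vertices `n x 2` matrix of vertex coordinates (mm).
#' @return Absolute enclosed area (mm^2).
#' @export
polygon_area <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Emulated duplicate-tracing noise model
#'
#' Parameters of the boundary jitter used to emulate intra- and inter-rater
#' variability of manual tracing: a zero-mean radial displacement field,
#' correlated along the contour's arc length, plus a chance of missing the
#' partial-volume end slices of the stack. `boundary_sd = 0` and
#' `slice_miss_prob = 0` reproduce the input exactly.
#'
#' @param boundary_sd radial jitter standard deviation (mm).
#' @param correlation_length correlation length along the contour (mm).
#' @param slice_correlation fraction (0-1) of the jitter variance shared
#'   across all slices of one tracing — a rater's systematic tendency to
#'   trace wide or tight on a given side during a session. 0 makes slices
#'   independent.
#' @param slice_miss_prob probability of dropping each end slice.
#' @param caliper_cv relative standard deviation of each manual
#'   axis/caliper measurement (see [apply_caliper_noise()]); manual caliper
#'   placement on cystic kidneys is far noisier than contour tracing.
#' @param seed integer seed; same seed gives identical tracings.
#' @return An object of class `kv_rater_noise`.
#' @export
rater_noise_model <- function(boundary_sd = 1.5, correlation_length = 20,
                              slice_correlation = 0.5,
                              slice_miss_prob = 0.1, caliper_cv = 0.05,
                              seed = 1L) {
  if (boundary_sd < 0 || correlation_length <= 0 ||
      slice_correlation < 0 || slice_correlation > 1 ||
      slice_miss_prob < 0 || slice_miss_prob > 1 || caliper_cv < 0)
    stop("invalid rater noise parameters")
  structure(list(boundary_sd = boundary_sd,
                 correlation_length = correlation_length,
                 slice_correlation = slice_correlation,
                 slice_miss_prob = slice_miss_prob,
                 caliper_cv = caliper_cv,
                 seed = as.integer(seed)),
            class = "kv_rater_noise")
}

#' Apply caliper-placement noise to axis measurements
#'
#' Multiplies each of the four caliper measurements by an independent
#' mean-one lognormal factor with relative SD `model$caliper_cv`,
#' emulating the operator variability of placing axis lines on a viewer.
#' Deterministic for a fixed model seed; `caliper_cv = 0` is the identity.
#'
#' @param axes a [measure_axes()] result.
#' @param model a [rater_noise_model()].
#' @return A perturbed `kv_axes` object.
#' @export
apply_caliper_noise <- function(axes, model) {
  stopifnot(inherits(model, "kv_rater_noise"))
  cv <- model$caliper_cv
  if (cv == 0) return(axes)
  set.seed(child_seed(model$seed, "caliper"))
  sdl <- sqrt(log(1 + cv^2))
  f <- stats::rlnorm(4, -sdl^2 / 2, sdl)
  axes$length_coronal <- axes$length_coronal * f[1]
  axes$length_sagittal <- axes$length_sagittal * f[2]
  axes$width <- axes$width * f[3]
  axes$depth <- axes$depth * f[4]
  axes
}

#' Apply rater noise to a contour stack
#'
#' Displaces every vertex radially (about the contour's ray-cast origin) by
#' a smooth zero-mean Gaussian field correlated along arc length; radii are
#' clamped to stay positive, so the radial representation guarantees the
#' perturbed polygon remains simple. End slices may be dropped with
#' `slice_miss_prob`, emulating the ambiguous partial-volume poles of the
#' kidney. Deterministic for a fixed model seed.
#'
#' @param contours a [contour_stack()] result.
#' @param model a [rater_noise_model()].
#' @return A perturbed `kv_contours` object.
#' @export
apply_rater_noise <- function(contours, model) {
  stopifnot(inherits(contours, "kv_contours"),
            inherits(model, "kv_rater_noise"))
  if (model$boundary_sd == 0 && model$slice_miss_prob == 0)
    return(contours)
  set.seed(child_seed(model$seed, "rater-noise"))
  slices <- contours$slices
  if (model$slice_miss_prob > 0 && length(slices) > 2) {
    if (stats::runif(1) < model$slice_miss_prob) slices <- slices[-1]
    if (stats::runif(1) < model$slice_miss_prob)
      slices <- slices[-length(slices)]
  }
  if (model$boundary_sd > 0) {
    nv <- nrow(slices[[1]]$vertices)
    w <- sqrt(model$slice_correlation)
    z_shared <- stats::rnorm(nv)   # one systematic angular pattern / tracing
    slices <- lapply(slices, function(sl) {
      v <- sl$vertices
      rel <- sweep(v, 2, sl$origin_uv)
      r <- sqrt(rowSums(rel^2))
      seg <- sqrt(rowSums((rbind(v[-1, , drop = FALSE], v[1, ]) - v)^2))
      s <- cumsum(c(0, seg[-length(seg)]))
      zs <- if (nrow(v) == nv) z_shared else stats::rnorm(nrow(v))
      z <- w * zs + sqrt(1 - w^2) * stats::rnorm(nrow(v))
      d <- correlated_field(s, sum(seg), z, model$boundary_sd,
                            model$correlation_length)
      rnew <- pmax(r + d, 0.05 * r)
      sl$vertices <- sweep(rel * (rnew / r), 2, sl$origin_uv, "+")
      sl
    })
  }
  structure(list(geometry = contours$geometry, slices = slices),
            class = "kv_contours")
}

# zero-mean radial field with sd `sd`, Gaussian-correlated along arc length;
# s = vertex arc positions, P = perimeter, z = standard-normal innovations
correlated_field <- function(s, P, z, sd, corr_len) {
  ds <- abs(outer(s, s, "-"))
  ds <- pmin(ds, P - ds)
  W <- exp(-ds^2 / (2 * corr_len^2))
  W <- W / sqrt(rowSums(W^2))            # unit marginal variance
  as.numeric(W %*% z) * sd
}

#' Rasterise a contour stack into a segmentation mask
#'
#' Fills each slice polygon on the geometry's pixel lattice. Because the
#' stack's polygons are radial about their ray-cast origin, a pixel centre
#' is inside iff its distance to the origin is below the polygon radius
#' interpolated at its angle; this is exact for the star-shaped contours
#' produced by [contour_stack()] and [apply_rater_noise()].
#'
#' @param contours a `kv_contours` object.
#' @return A `kv_mask` on the same geometry.
#' @export
contours_to_mask <- function(contours) {
  geom <- contours$geometry
  m <- geom$matrix_size
  uc <- pixel_centres(geom)
  idx <- vapply(contours$slices, `[[`, numeric(1), "slice_index")
  vox <- array(FALSE, dim = c(m, m, length(idx)))
  for (si in seq_along(contours$slices)) {
    sl <- contours$slices[[si]]
    v <- sweep(sl$vertices, 2, sl$origin_uv)
    ang <- atan2(v[, 2], v[, 1])
    rad <- sqrt(rowSums(v^2))
    o <- order(ang)
    ang <- ang[o]; rad <- rad[o]
    # periodic linear interpolation of the boundary radius
    angx <- c(ang[length(ang)] - 2 * pi, ang, ang[1] + 2 * pi)
    radx <- c(rad[length(rad)], rad, rad[1])
    du <- rep(uc, times = m) - sl$origin_uv[1]
    dv <- rep(uc, each = m) - sl$origin_uv[2]
    pr <- sqrt(du^2 + dv^2)
    pa <- atan2(dv, du)
    rb <- stats::approx(angx, radx, xout = pa, rule = 2)$y
    vox[, , si] <- matrix(pr <= rb, m, m)
  }
  structure(list(geometry = geom, voxels = vox,
                 slice_index = as.integer(idx),
                 slice_z = vapply(contours$slices, `[[`, numeric(1), "z_mm")),
            class = "kv_mask")
}
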