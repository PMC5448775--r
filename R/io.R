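#' Write / read a contour stack as JSON
#'
#' One record per slice: `slice_index`, `z_mm`, `origin_uv` and the vertex
#' list `[[x, y], ...]` in slice-plane mm, plus a `geometry` header.
#'
#' @param contours a `kv_contours` object.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_contours_json <- function(contours, path) {
  stopifnot(inherits(contours, "kv_contours"))
  g <- contours$geometry
  payload <- list(
    geometry = list(modality = g$modality, slicing_axis = g$slicing_axis,
                    slice_thickness = g$slice_thickness,
                    in_plane_spacing = g$in_plane_spacing,
                    matrix_size = g$matrix_size,
                    origin_offset = g$origin_offset),
    slices = lapply(contours$slices, function(sl)
      list(slice_index = sl$slice_index, z_mm = sl$z_mm,
           origin_uv = sl$origin_uv,
           vertices = unname(apply(sl$vertices, 1, as.numeric,
                                   simplify = FALSE)))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contours_json
#' @param path JSON file written by [write_contours_json()].
#' @export
read_contours_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  g <- p$geometry
  geom <- imaging_geometry(g$modality, g$slicing_axis, g$slice_thickness,
                           g$in_plane_spacing, g$matrix_size,
                           g$origin_offset)
  slices <- lapply(p$slices, function(sl) {
    v <- do.call(rbind, lapply(sl$vertices, function(xy)
      c(xy[[1]], xy[[2]])))
    list(slice_index = sl$slice_index, z_mm = sl$z_mm,
         origin_uv = unlist(sl$origin_uv), vertices = v)
  })
  structure(list(geometry = geom, slices = slices), class = "kv_contours")
}

#' Write / read a contour stack as flat CSV
#'
#' Spreadsheet-friendly long format: one row per vertex with columns
#' `slice_index`, `z_mm`, `vertex`, `x_mm`, `y_mm` (geometry goes in a
#' JSON side-car header comment on the first line).
#'
#' @param contours a `kv_contours` object.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_contours_csv <- function(contours, path) {
  stopifnot(inherits(contours, "kv_contours"))
  g <- contours$geometry
  hdr <- jsonlite::toJSON(list(modality = g$modality,
                               slicing_axis = g$slicing_axis,
                               slice_thickness = g$slice_thickness,
                               in_plane_spacing = g$in_plane_spacing,
                               matrix_size = g$matrix_size,
                               origin_offset = g$origin_offset),
                          auto_unbox = TRUE)
  rows <- do.call(rbind, lapply(contours$slices, function(sl) {
    n <- nrow(sl$vertices)
    data.frame(slice_index = sl$slice_index, z_mm = sl$z_mm,
               origin_u = sl$origin_uv[1], origin_v = sl$origin_uv[2],
               vertex = seq_len(n), x_mm = sl$vertices[, 1],
               y_mm = sl$vertices[, 2])
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# geometry: ", hdr), con)
  utils::write.csv(rows, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  first <- readLines(path, n = 1)
  g <- jsonlite::fromJSON(sub("^# geometry: ", "", first))
  geom <- imaging_geometry(g$modality, g$slicing_axis, g$slice_thickness,
                           g$in_plane_spacing, g$matrix_size,
                           g$origin_offset)
  rows <- utils::read.csv(path, comment.char = "#")
  slices <- lapply(split(rows, rows$slice_index), function(df) {
    df <- df[order(df$vertex), ]
    list(slice_index = df$slice_index[1], z_mm = df$z_mm[1],
         origin_uv = c(df$origin_u[1], df$origin_v[1]),
         vertices = cbind(df$x_mm, df$y_mm))
  })
  slices <- slices[order(vapply(slices, `[[`, numeric(1), "slice_index"))]
  names(slices) <- NULL
  structure(list(geometry = geom, slices = slices), class = "kv_contours")
}

#' Write / read a segmentation mask as NIfTI-1
#'
#' Stores the binary lattice with voxel spacing in `pixdim`; slicing axis,
#' modality, origin offset and the first slice index travel in the NIfTI
#' description string so the mask round-trips exactly.
#'
#' @param mask a `kv_mask`.
#' @param path output `.nii` / `.nii.gz` file.
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "kv_mask"))
  g <- mask$geometry
  img <- RNifti::asNifti(array(as.integer(mask$voxels),
                               dim = dim(mask$voxels)))
  RNifti::pixdim(img) <- c(g$in_plane_spacing, g$in_plane_spacing,
                           g$slice_thickness)
  img$descrip <- sprintf("%s|%s|%g|%d", g$modality, g$slicing_axis,
                         g$origin_offset, mask$slice_index[1])
  attr(img, "kv_matrix") <- g$matrix_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  meta <- strsplit(RNifti::niftiHeader(img)$descrip, "\\|")[[1]]
  geom <- imaging_geometry(meta[1], meta[2], pd[3], pd[1], dim(img)[1],
                           as.numeric(meta[3]))
  first <- as.integer(meta[4])
  idx <- first + seq_len(dim(img)[3]) - 1L
  structure(list(geometry = geom, voxels = array(img[] > 0, dim(img)),
                 slice_index = idx, slice_z = slice_midplane(geom, idx)),
            class = "kv_mask")
}

#' Read a measurements table
#'
#' Long-format per-measurement CSV with columns `kidney_id`, `method`,
#' `rater`, `session`, `skv_ml` and optionally `time_min` — the shape the
#' duplicate-tracing experiment emits and that an external study export
#' can be supplied in.
#'
#' @param path CSV file.
#' @return A validated data.frame.
#' @export
read_measurements_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("kidney_id", "method", "rater", "session", "skv_ml")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing columns %s", path,
                 paste(miss, collapse = ", ")))
  if (anyDuplicated(df[c("kidney_id", "method", "rater", "session")]))
    stop("duplicate (kidney_id, method, rater, session) rows")
  df
}

#' Method-comparison statistics from a measurements table
#'
#' Computes, per method: intra-rater CV (session 1 vs 2, per rater),
#' inter-rater CV (rater means), and — against the reference method on
#' session-1 measurements of the first rater — mean percentage difference,
#' Bland-Altman limits and RMSE (ml and %).
#'
#' @param measurements data.frame as from [read_measurements_csv()].
#' @param reference reference method name (default
#'   `"polyline_planimetry"`).
#' @return List of data.frames `reproducibility` and `agreement`.
#' @export
compare_measurements <- function(measurements,
                                 reference = "polyline_planimetry") {
  df <- measurements
  methods <- unique(df$method)
  raters <- unique(df$rater)
  repro <- do.call(rbind, lapply(methods, function(me) {
    sub <- df[df$method == me, ]
    rows <- lapply(raters, function(ra) {
      s1 <- sub[sub$rater == ra & sub$session == 1, ]
      s2 <- sub[sub$rater == ra & sub$session == 2, ]
      key <- intersect(s1$kidney_id, s2$kidney_id)
      if (length(key) < 2) return(NULL)
      x <- s1$skv_ml[match(key, s1$kidney_id)]
      y <- s2$skv_ml[match(key, s2$kidney_id)]
      data.frame(method = me, scope = paste0("intra_", ra),
                 cv_pct = cv_repeated_measures(x, y),
                 mean_diff_ml = mean(y - x))
    })
    if (length(raters) >= 2) {
      a <- stats::aggregate(skv_ml ~ kidney_id,
                            sub[sub$rater == raters[1], ], mean)
      b <- stats::aggregate(skv_ml ~ kidney_id,
                            sub[sub$rater == raters[2], ], mean)
      key <- intersect(a$kidney_id, b$kidney_id)
      if (length(key) >= 2)
        rows <- c(rows, list(data.frame(
          method = me, scope = "inter",
          cv_pct = cv_repeated_measures(a$skv_ml[match(key, a$kidney_id)],
                                        b$skv_ml[match(key, b$kidney_id)]),
          mean_diff_ml = mean(b$skv_ml[match(key, b$kidney_id)] -
                                a$skv_ml[match(key, a$kidney_id)]))))
    }
    do.call(rbind, rows)
  }))
  r1 <- raters[1]
  ref <- df[df$method == reference & df$rater == r1 & df$session == 1, ]
  agree <- do.call(rbind, lapply(setdiff(methods, reference), function(me) {
    cmp <- df[df$method == me & df$rater == r1 & df$session == 1, ]
    key <- intersect(ref$kidney_id, cmp$kidney_id)
    if (length(key) < 2) return(NULL)
    x <- ref$skv_ml[match(key, ref$kidney_id)]
    y <- cmp$skv_ml[match(key, cmp$kidney_id)]
    ba <- bland_altman(x, y, percent = TRUE)
    data.frame(method = me, n = length(key),
               mean_diff_ml = mean(y - x), rmse_ml = rmse(x, y),
               mean_diff_pct = ba$mean_diff, sd_diff_pct = ba$sd_diff,
               loa_lower_pct = ba$lower, loa_upper_pct = ba$upper,
               rmse_pct = rmse(x, y, percent = TRUE))
  }))
  list(reproducibility = repro, agreement = agree)
}
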