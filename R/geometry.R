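#' LV blood-pool geometry: masks, orifices, surface labels
#'
#' Bundles the end-diastolic blood-pool segmentation, the segmentations at the
#' preceding and following end-systole, and the labelled boundary regions
#' (mitral orifice, aortic orifice, wall) the pathline quality control needs.
#' All masks share the velocity field's isotropic grid and affine
#' (voxel-centre convention, physical mm).
#'
#' The boundary labelling is realised as an integer volume over the whole
#' grid: `0` = blood pool (inside `ed_mask`), `1` = wall exterior, `2` =
#' mitral-orifice exterior, `3` = aortic-orifice exterior. A pathline leaving
#' the pool is attributed to the face it crossed via the label of the first
#' exterior voxel it enters.
#'
#' @param ed_mask Logical 3-D array: LV blood pool at end diastole.
#' @param es_mask_prev,es_mask_next Logical 3-D arrays: blood pool at the
#'   preceding / following end systole (for a periodic phantom these are the
#'   same mask).
#' @param spacing Voxel spacing, mm (scalar or length 3, isotropic for
#'   analysis grids).
#' @param origin mm coordinate of the centre of voxel `(1,1,1)`.
#' @param mitral_orifice,aortic_orifice Lists `list(center, normal, radius)`:
#'   orifice disk centre (mm, length 3), outward unit normal, radius (mm).
#' @param ed_frame,es_frame 1-based timeframe indices of end diastole and end
#'   systole in the companion velocity field (the phantom supplies these; for
#'   measured data use [find_es_frame()]).
#' @return An object of class `lv_geometry`.
#' @export
lv_geometry <- function(ed_mask, es_mask_prev, es_mask_next, spacing, origin,
                        mitral_orifice, aortic_orifice,
                        ed_frame = 1L, es_frame = NULL) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(is.array(ed_mask), length(dim(ed_mask)) == 3L)
  if (!any(ed_mask)) stop("ed_mask is empty")
  if (!any(es_mask_prev) || !any(es_mask_next)) stop("ES mask is empty")
  stopifnot(identical(dim(ed_mask), dim(es_mask_prev)),
            identical(dim(ed_mask), dim(es_mask_next)))
  for (o in list(mitral_orifice, aortic_orifice)) {
    stopifnot(length(o$center) == 3L, length(o$normal) == 3L, o$radius > 0)
    if (abs(sqrt(sum(o$normal^2)) - 1) > 1e-8)
      stop("orifice normal must be unit length")
  }
  geom <- structure(list(
    ed_mask = ed_mask, es_mask_prev = es_mask_prev, es_mask_next = es_mask_next,
    spacing = as.numeric(spacing), origin = as.numeric(origin),
    mitral_orifice = mitral_orifice, aortic_orifice = aortic_orifice,
    mitral_plane = list(point = as.numeric(mitral_orifice$center),
                        normal = as.numeric(mitral_orifice$normal)),
    ed_frame = as.integer(ed_frame),
    es_frame = if (is.null(es_frame)) NA_integer_ else as.integer(es_frame)),
    class = "lv_geometry")
  geom$surface_labels <- .label_exterior(geom)
  # exit events are detected against a one-voxel dilation of the pool, so the
  # jagged voxelised surface does not flag particles that merely graze it
  geom$ed_mask_dilated <- .dilate6(ed_mask)
  geom
}

## 6-connectivity binary dilation by one voxel
.dilate6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  sh <- function(m, ax, by) {
    r <- array(FALSE, dim = d)
    if (ax == 1) {
      if (by == 1) r[2:d[1], , ] <- m[1:(d[1] - 1), , ]
      else r[1:(d[1] - 1), , ] <- m[2:d[1], , ]
    } else if (ax == 2) {
      if (by == 1) r[, 2:d[2], ] <- m[, 1:(d[2] - 1), ]
      else r[, 1:(d[2] - 1), ] <- m[, 2:d[2], ]
    } else {
      if (by == 1) r[, , 2:d[3]] <- m[, , 1:(d[3] - 1)]
      else r[, , 1:(d[3] - 1)] <- m[, , 2:d[3]]
    }
    r
  }
  for (ax in 1:3) for (by in c(1, -1)) out <- out | sh(mask, ax, by)
  out
}

#' @export
print.lv_geometry <- function(x, ...) {
  vox <- prod(x$spacing)
  cat("lv_geometry on a ", paste(dim(x$ed_mask), collapse = "x"),
      " grid (", paste(x$spacing, collapse = "x"), " mm)\n", sep = "")
  cat(sprintf("  EDV %.1f mL, ESV %.1f mL (prev) / %.1f mL (next)\n",
              sum(x$ed_mask) * vox / 1000, sum(x$es_mask_prev) * vox / 1000,
              sum(x$es_mask_next) * vox / 1000))
  cat("  ED frame ", x$ed_frame, ", ES frame ", x$es_frame, "\n", sep = "")
  invisible(x)
}

## Label every voxel: 0 pool, 1 wall exterior, 2 mitral exterior, 3 aortic
## exterior.  Orifice exteriors are cylinders extending outward (and one voxel
## inward, for tolerance) along the orifice normal.
.label_exterior <- function(geom) {
  d <- dim(geom$ed_mask)
  lab <- array(1L, dim = d)
  lab[geom$ed_mask] <- 0L
  ctr <- .voxel_centers(d, geom$spacing, geom$origin)
  margin <- max(geom$spacing)
  for (code in c(2L, 3L)) {
    o <- if (code == 2L) geom$mitral_orifice else geom$aortic_orifice
    q <- sweep(ctr, 2, o$center, "-")
    s <- as.vector(q %*% o$normal)            # signed distance along normal
    radial2 <- rowSums(q^2) - s^2
    incyl <- s > -margin & radial2 <= (o$radius + margin / 2)^2
    sel <- incyl & !geom$ed_mask
    lab[array(sel, dim = d)] <- code
  }
  lab
}

.voxel_centers <- function(d, spacing, origin) {
  ix <- rep(seq_len(d[1]), times = d[2] * d[3])
  iy <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  iz <- rep(seq_len(d[3]), each = d[1] * d[2])
  cbind(origin[1] + (ix - 1) * spacing[1],
        origin[2] + (iy - 1) * spacing[2],
        origin[3] + (iz - 1) * spacing[3])
}

## Voxel-centre containment of points in a mask (points outside the grid are
## outside the mask).
points_in_mask <- function(p, mask, spacing, origin) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  d <- dim(mask)
  idx <- round(sweep(sweep(p, 2, origin, "-"), 2, spacing, "/")) + 1
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  res <- logical(nrow(p))
  if (any(ok)) {
    lin <- (idx[ok, 3] - 1) * d[1] * d[2] + (idx[ok, 2] - 1) * d[1] + idx[ok, 1]
    res[ok] <- mask[lin]
  }
  res
}

#' Resample a binary mask to an isotropic analysis grid
#'
#' Nearest-neighbour resampling with the voxel-centre convention: each target
#' voxel takes the value of the source voxel containing its centre. Used to
#' bring a segmentation onto the velocity field's isotropic grid before
#' seeding; total represented volume is preserved up to voxelisation.
#'
#' @param mask Logical 3-D array on the source grid.
#' @param from_spacing Source voxel spacing, mm (length 3 or scalar).
#' @param to_spacing Target isotropic spacing, mm (scalar).
#' @param from_origin,to_origin mm coordinates of the first voxel centres.
#' @param to_dim Target grid dimension; defaults to covering the source extent.
#' @return Logical array on the target grid.
#' @export
resample_mask <- function(mask, from_spacing, to_spacing,
                          from_origin = c(0, 0, 0), to_origin = NULL,
                          to_dim = NULL) {
  if (length(from_spacing) == 1L) from_spacing <- rep(from_spacing, 3L)
  stopifnot(length(to_spacing) == 1L, to_spacing > 0)
  d <- dim(mask)
  extent <- d * from_spacing
  if (is.null(to_dim)) to_dim <- pmax(1L, as.integer(ceiling(extent / to_spacing)))
  if (is.null(to_origin))
    to_origin <- from_origin - from_spacing / 2 + to_spacing / 2
  ctr <- .voxel_centers(to_dim, rep(to_spacing, 3), to_origin)
  inside <- points_in_mask(ctr, mask, from_spacing, from_origin)
  array(inside, dim = to_dim)
}

#' Find the end-systolic frame from a cavity-volume curve
#'
#' For measured data the end-systolic timeframe is the frame of minimum
#' cavity volume. The phantom generators record the frame explicitly instead.
#'
#' @param volumes_ml Cavity volume per timeframe, mL.
#' @return 1-based index of the minimum-volume frame (earliest on ties).
#' @export
find_es_frame <- function(volumes_ml) {
  stopifnot(length(volumes_ml) >= 2)
  which.min(volumes_ml)
}

#' Write / read an LV geometry as NIfTI masks + JSON metadata
#'
#' Writes `ed_mask.nii.gz`, `es_mask_prev.nii.gz`, `es_mask_next.nii.gz` and
#' `geometry.json` (spacing, origin, orifices, frame indices) into `dir`.
#'
#' @param geom An [lv_geometry()].
#' @param dir Output directory (created if needed).
#' @return `dir` / the geometry.
#' @export
write_geometry <- function(geom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mask(geom$ed_mask, file.path(dir, "ed_mask.nii.gz"))
  write_mask(geom$es_mask_prev, file.path(dir, "es_mask_prev.nii.gz"))
  write_mask(geom$es_mask_next, file.path(dir, "es_mask_next.nii.gz"))
  meta <- list(spacing_mm = geom$spacing, origin_mm = geom$origin,
               mitral_orifice = geom$mitral_orifice,
               aortic_orifice = geom$aortic_orifice,
               ed_frame = geom$ed_frame, es_frame = geom$es_frame)
  jsonlite::write_json(meta, file.path(dir, "geometry.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "geometry.json"),
                              simplifyVector = TRUE)
  fixo <- function(o) list(center = as.numeric(o$center),
                           normal = as.numeric(o$normal),
                           radius = as.numeric(o$radius))
  lv_geometry(read_mask(file.path(dir, "ed_mask.nii.gz")),
              read_mask(file.path(dir, "es_mask_prev.nii.gz")),
              read_mask(file.path(dir, "es_mask_next.nii.gz")),
              spacing = meta$spacing_mm, origin = meta$origin_mm,
              mitral_orifice = fixo(meta$mitral_orifice),
              aortic_orifice = fixo(meta$aortic_orifice),
              ed_frame = meta$ed_frame, es_frame = meta$es_frame)
}
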