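#' Time-resolved 3-D, three-directional velocity field
#'
#' Container for a cine phase-contrast (4D flow) velocity grid. Velocities are
#' stored in m/s on an isotropic voxel grid; positions are physical mm with the
#' voxel-centre convention (the centre of voxel `(1,1,1)` sits at `origin`).
#'
#' @param v Numeric array of dimension `X x Y x Z x 3 x T`: three velocity
#'   components (m/s) per voxel per timeframe.
#' @param spacing Voxel spacing in mm, length 3 (must be isotropic for
#'   analysis grids) or scalar.
#' @param frame_times Timeframe onsets in ms from cycle start (R-wave),
#'   strictly increasing, all `<= cycle_length`.
#' @param cycle_length Cardiac cycle length (R-R interval), ms.
#' @param venc Velocity-encoding limit in cm/s (the interface unit; stored
#'   internally in m/s). Synthetic fields satisfy `|v| <= venc` componentwise
#'   on the magnitude.
#' @param origin Physical mm coordinate of the centre of voxel `(1,1,1)`.
#' @param periodic Logical; if `TRUE` the field wraps in time (frame after the
#'   last is the first). Only synthetic phantoms set this; measured data must
#'   not assume periodicity.
#' @return An object of class `velocity_field`.
#' @seealso [read_field()], [write_field()], [make_lv_phantom()]
#' @export
velocity_field <- function(v, spacing, frame_times, cycle_length, venc = 100,
                           origin = c(0, 0, 0), periodic = FALSE) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(is.array(v), length(dim(v)) == 5L, dim(v)[4] == 3L)
  if (dim(v)[5] < 2L)
    stop("velocity_field needs at least 2 timeframes (pathline tracing needs >= 2)")
  if (!all(is.finite(v))) stop("velocity field contains non-finite values")
  if (!all(spacing > 0)) stop("spacing must be > 0")
  if (length(frame_times) != dim(v)[5])
    stop("frame_times length (", length(frame_times), ") does not match the ",
         dim(v)[5], " timeframes")
  if (any(diff(frame_times) <= 0)) stop("frame_times must be strictly increasing")
  if (any(frame_times > cycle_length) || any(frame_times < 0))
    stop("frame_times must lie in [0, cycle_length]")
  stopifnot(is.numeric(venc), venc > 0)
  structure(list(v = v, spacing = as.numeric(spacing),
                 frame_times = as.numeric(frame_times),
                 cycle_length = as.numeric(cycle_length),
                 venc = as.numeric(venc) / 100,  # m/s internally
                 origin = as.numeric(origin), periodic = isTRUE(periodic)),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$v)
  cat("velocity_field: ", d[1], "x", d[2], "x", d[3], " voxels, ", d[5],
      " frames\n", sep = "")
  cat("  spacing ", paste(x$spacing, collapse = " x "), " mm; cycle ",
      round(x$cycle_length, 1), " ms; VENC ", x$venc * 100, " cm/s",
      if (x$periodic) "; periodic" else "", "\n", sep = "")
  cat("  |v| range ", paste(signif(range(field_speed(x)), 3), collapse = " - "),
      " m/s\n", sep = "")
  invisible(x)
}

## Speed magnitude over all voxels/frames (m/s)
field_speed <- function(field) {
  d <- dim(field$v)
  vv <- field$v
  dim(vv) <- c(prod(d[1:3]), 3, d[5])
  sqrt(vv[, 1, ]^2 + vv[, 2, ]^2 + vv[, 3, ]^2)
}

## Physical mm -> fractional voxel index (1-based)
pos_to_index <- function(p, field) {
  sweep(sweep(p, 2, field$origin, "-"), 2, field$spacing, "/") + 1
}

index_to_pos <- function(idx, spacing, origin) {
  sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}

## Locate a time t (ms) in the frame grid.  Returns list(k1, k2, w): frames to
## blend and the weight of frame k2.  Periodic fields wrap modulo the cycle;
## non-periodic fields clamp at the ends (constant extrapolation).
.time_bracket <- function(t, field) {
  ft <- field$frame_times
  n <- length(ft)
  if (field$periodic) {
    tm <- t %% field$cycle_length
    k1 <- findInterval(tm, ft)
    k1[k1 == 0L] <- n  # tm < ft[1] only possible if ft[1] > 0
    k2 <- k1 %% n + 1L
    span <- ifelse(k1 == n, field$cycle_length - ft[n] + ft[1], ft[k1 + ifelse(k1 == n, 0L, 1L)] - ft[k1])
    # span for wrap interval: from ft[n] to cycle + ft[1]
    dtn <- field$cycle_length - ft[n] + ft[1]
    span <- ifelse(k1 == n, dtn, ft[pmin(k1 + 1L, n)] - ft[k1])
    w <- ifelse(span > 0, ((tm - ft[k1]) %% field$cycle_length) / span, 0)
  } else {
    k1 <- findInterval(t, ft)
    if (any(k1 == 0L)) { k1[k1 == 0L] <- 1L }
    k1 <- pmin(k1, n - 1L)
    k2 <- k1 + 1L
    w <- (t - ft[k1]) / (ft[k2] - ft[k1])
    w <- pmin(pmax(w, 0), 1)
  }
  list(k1 = k1, k2 = k2, w = w)
}

## Trilinear gather of one frame's velocity at fractional indices U (N x 3).
## Points outside the grid get zero velocity.
.trilinear_frame <- function(varr, U) {
  d <- dim(varr)  # X Y Z 3
  n <- nrow(U)
  out <- matrix(0, n, 3)
  inside <- U[, 1] >= 1 & U[, 1] <= d[1] & U[, 2] >= 1 & U[, 2] <= d[2] &
    U[, 3] >= 1 & U[, 3] <= d[3]
  if (!any(inside)) return(out)
  Ui <- U[inside, , drop = FALSE]
  i0 <- pmin(pmax(floor(Ui), 1), matrix(rep(d[1:3] - 1L, each = nrow(Ui)), ncol = 3))
  f <- Ui - i0
  i1 <- i0 + 1
  # weights for the 8 corners
  wx0 <- 1 - f[, 1]; wx1 <- f[, 1]
  wy0 <- 1 - f[, 2]; wy1 <- f[, 2]
  wz0 <- 1 - f[, 3]; wz1 <- f[, 3]
  acc <- matrix(0, nrow(Ui), 3)
  sx <- d[1]; sxy <- d[1] * d[2]; sxyz <- sxy * d[3]
  base <- function(ix, iy, iz) (iz - 1) * sxy + (iy - 1) * sx + ix
  for (cz in 0:1) {
    iz <- if (cz == 0) i0[, 3] else i1[, 3]
    wz <- if (cz == 0) wz0 else wz1
    for (cy in 0:1) {
      iy <- if (cy == 0) i0[, 2] else i1[, 2]
      wy <- if (cy == 0) wy0 else wy1
      for (cx in 0:1) {
        ix <- if (cx == 0) i0[, 1] else i1[, 1]
        wx <- if (cx == 0) wx0 else wx1
        w <- wx * wy * wz
        idx <- base(ix, iy, iz)
        acc[, 1] <- acc[, 1] + w * varr[idx]
        acc[, 2] <- acc[, 2] + w * varr[idx + sxyz]
        acc[, 3] <- acc[, 3] + w * varr[idx + 2 * sxyz]
      }
    }
  }
  out[inside, ] <- acc
  out
}

#' Sample the velocity field at arbitrary positions and time
#'
#' Trilinear interpolation in space, linear in time (the interpolation model
#' used for pathline integration). Positions outside the image volume return
#' zero velocity.
#'
#' @param field A [velocity_field()].
#' @param p Numeric matrix `N x 3` of positions, mm.
#' @param t Time, ms (scalar). Periodic fields wrap modulo the cycle length.
#' @return `N x 3` matrix of velocities, m/s.
#' @export
field_velocity_at <- function(field, p, t) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  U <- pos_to_index(p, field)
  br <- .time_bracket(t, field)
  v1 <- .trilinear_frame(field$v[, , , , br$k1, drop = TRUE], U)
  if (br$w == 0) return(v1)
  v2 <- .trilinear_frame(field$v[, , , , br$k2, drop = TRUE], U)
  (1 - br$w) * v1 + br$w * v2
}

#' Write / read a velocity field as NIfTI + JSON sidecar
#'
#' The grid is written as a 5-D NIfTI volume (`X x Y x Z x T x 3`, velocities
#' in m/s, float64 so round-trips are bit-exact) and the timing/encoding
#' metadata (`frame_times`, `cycle_length`, `venc`, `origin`, `periodic`,
#' units) as a JSON sidecar next to it.
#'
#' @param field A [velocity_field()].
#' @param path Output path for the NIfTI file (`.nii` or `.nii.gz`); the
#'   sidecar gets the same stem with `.json`.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  arr <- aperm(field$v, c(1, 2, 3, 5, 4))  # X Y Z T 3 on disk
  RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = "double")
  meta <- list(spacing_mm = field$spacing, frame_times_ms = field$frame_times,
               cycle_length_ms = field$cycle_length, venc_cm_s = field$venc * 100,
               origin_mm = field$origin, periodic = field$periodic,
               velocity_units = "m/s")
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  sc <- .sidecar_path(path)
  if (!file.exists(sc))
    stop("missing JSON sidecar ", sc, " (required fields: frame_times_ms, ",
         "cycle_length_ms, venc_cm_s)")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (fld in c("frame_times_ms", "cycle_length_ms", "venc_cm_s", "spacing_mm"))
    if (is.null(meta[[fld]]))
      stop("sidecar is missing required timing/encoding field '", fld, "'")
  if (is.unsorted(meta$frame_times_ms, strictly = TRUE))
    stop("sidecar frame_times_ms are not strictly increasing")
  arr <- array(as.numeric(RNifti::readNifti(path)),
               dim = dim(RNifti::readNifti(path)))
  if (length(dim(arr)) == 4L) dim(arr) <- c(dim(arr), 1L)
  if (dim(arr)[5] != 3L)
    stop("expected a 5-D volume with 3 velocity components in dimension 5")
  units <- meta$velocity_units
  v <- aperm(arr, c(1, 2, 3, 5, 4))
  if (!is.null(units) && identical(units, "cm/s")) v <- v / 100
  velocity_field(v, spacing = meta$spacing_mm, frame_times = meta$frame_times_ms,
                 cycle_length = meta$cycle_length_ms, venc = meta$venc_cm_s,
                 origin = if (is.null(meta$origin_mm)) c(0, 0, 0) else meta$origin_mm,
                 periodic = isTRUE(meta$periodic))
}

#' Write / read a binary mask volume as NIfTI
#'
#' @param mask Logical or 0/1 3-D array.
#' @param path NIfTI path.
#' @return `path` / logical array.
#' @export
write_mask <- function(mask, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim = dim(mask))),
                     path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.vector(img) != 0, dim = dim(img))
}
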