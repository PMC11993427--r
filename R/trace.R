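#' Pathline tracing configuration
#'
#' @param substeps_per_frame Runge-Kutta substeps per frame interval (>= 1).
#'   The default (4) is validated against a 20-substep reference integration;
#'   doubling it changes no component label on the LV phantom at default
#'   resolution.
#' @param qc_invalid_fraction_max Fraction of QC-invalid pathlines above which
#'   a dataset is flagged FAIL.
#' @return An object of class `trace_config`. Interpolation is trilinear in
#'   space and linear in time (the scheme the integrator assumes).
#' @export
trace_config <- function(substeps_per_frame = 4L, qc_invalid_fraction_max = 0.05) {
  stopifnot(substeps_per_frame >= 1, qc_invalid_fraction_max >= 0,
            qc_invalid_fraction_max <= 1)
  structure(list(substeps_per_frame = as.integer(substeps_per_frame),
                 interpolation = c("trilinear-space", "linear-time"),
                 qc_invalid_fraction_max = qc_invalid_fraction_max),
            class = "trace_config")
}

## Recording times for an integration t0 -> t1: the field's frame times
## falling strictly between them (shifted by whole cycles for periodic
## fields), plus both endpoints.
.record_times <- function(field, t0, t1) {
  ft <- field$frame_times
  if (field$periodic) {
    lo <- min(t0, t1); hi <- max(t0, t1)
    shifts <- seq(floor(lo / field$cycle_length) - 1,
                  ceiling(hi / field$cycle_length) + 1)
    ft <- sort(unique(as.vector(outer(ft, shifts * field$cycle_length, "+"))))
  }
  inner <- ft[ft > min(t0, t1) + 1e-9 & ft < max(t0, t1) - 1e-9]
  if (t1 >= t0) c(t0, inner, t1) else c(t0, rev(inner), t1)
}

## Vectorised RK4 advection of N particles from t0 to t1 (either direction),
## recording positions at frame times and, when `geom` is given, boundary
## events: first blood-pool exit (with crossed-face label), first mitral-plane
## crossing, and field-of-view exits.
.advect <- function(field, P0, t0, t1, substeps, geom = NULL) {
  N <- nrow(P0)
  rec <- .record_times(field, t0, t1)
  nrec <- length(rec)
  pos <- array(NA_real_, dim = c(N, nrec, 3))
  pos[, 1, ] <- P0
  d <- dim(field$v)[1:3]
  bb_lo <- field$origin - 0.5 * field$spacing
  bb_hi <- field$origin + (d - 0.5) * field$spacing

  track <- !is.null(geom)
  if (track) {
    exit_mask <- if (!is.null(geom$ed_mask_dilated)) geom$ed_mask_dilated else geom$ed_mask
    inside_prev <- points_in_mask(P0, exit_mask, geom$spacing, geom$origin)
    exit_label <- integer(N); exit_t <- rep(NA_real_, N)
    pl <- geom$mitral_plane
    s_prev <- as.vector(sweep(P0, 2, pl$point, "-") %*% pl$normal)
    cross_t <- rep(NA_real_, N)
    left_fov <- logical(N)
  }
  P <- P0
  for (j in seq_len(nrec - 1)) {
    ta <- rec[j]; tb <- rec[j + 1]
    dt <- (tb - ta) / substeps
    for (s in seq_len(substeps)) {
      t <- ta + (s - 1) * dt
      k1 <- field_velocity_at(field, P, t)
      k2 <- field_velocity_at(field, P + k1 * (dt / 2), t + dt / 2)
      k3 <- field_velocity_at(field, P + k2 * (dt / 2), t + dt / 2)
      k4 <- field_velocity_at(field, P + k3 * dt, t + dt)
      Pn <- P + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
      if (track) {
        out_fov <- Pn[, 1] < bb_lo[1] | Pn[, 1] > bb_hi[1] |
          Pn[, 2] < bb_lo[2] | Pn[, 2] > bb_hi[2] |
          Pn[, 3] < bb_lo[3] | Pn[, 3] > bb_hi[3]
        left_fov <- left_fov | out_fov
        inside_new <- points_in_mask(Pn, exit_mask, geom$spacing, geom$origin)
        exited <- which(inside_prev & !inside_new & exit_label == 0L)
        if (length(exited)) {
          idx <- round(sweep(Pn[exited, , drop = FALSE], 2, geom$origin, "-") /
                         rep(geom$spacing, each = length(exited))) + 1
          idx <- pmin(pmax(idx, 1), matrix(rep(d, each = length(exited)), ncol = 3))
          lin <- (idx[, 3] - 1) * d[1] * d[2] + (idx[, 2] - 1) * d[1] + idx[, 1]
          lab <- geom$surface_labels[lin]
          lab[lab == 0L] <- 1L   # landed in pool-labelled voxel: treat as wall
          exit_label[exited] <- lab
          exit_t[exited] <- t + dt
        }
        s_new <- as.vector(sweep(Pn, 2, pl$point, "-") %*% pl$normal)
        crossed <- which(is.na(cross_t) & (sign(s_prev) != sign(s_new)) &
                           abs(s_new - s_prev) > 0)
        if (length(crossed)) {
          w <- s_prev[crossed] / (s_prev[crossed] - s_new[crossed])
          pc <- P[crossed, , drop = FALSE] +
            (Pn[crossed, , drop = FALSE] - P[crossed, , drop = FALSE]) * w
          q <- sweep(pc, 2, pl$point, "-")
          sq <- as.vector(q %*% pl$normal)
          rad2 <- rowSums(q^2) - sq^2
          hit <- rad2 <= (1.3 * geom$mitral_orifice$radius)^2
          cross_t[crossed[hit]] <- t + w[hit] * dt
        }
        inside_prev <- inside_new
        s_prev <- s_new
      }
      P <- Pn
    }
    pos[, j + 1, ] <- P
  }
  out <- list(positions = pos, times = rec)
  if (track)
    out <- c(out, list(exit_label = exit_label, exit_t = exit_t,
                       plane_cross_t = cross_t, left_fov = left_fov))
  out
}

#' Seed pathlines from the end-diastolic segmentation
#'
#' One seed at the centre of each voxel of the (isotropic, field-matched)
#' end-diastolic mask; each seed represents one voxel volume of blood, so the
#' seed set represents the full end-diastolic volume. Volumes are attached
#' here and never rescaled.
#'
#' @param geom An [lv_geometry()] whose `ed_mask` is on the field's grid.
#' @param field The companion [velocity_field()].
#' @return List with `centers` (N x 3 mm), `linear` (voxel linear indices),
#'   `volume_mm3` (per-seed represented volume).
#' @export
seed_pathlines <- function(geom, field) {
  if (!identical(dim(geom$ed_mask), dim(field$v)[1:3]))
    stop("ed_mask must be resampled to the velocity field's grid ",
         "(see resample_mask())")
  if (max(abs(geom$spacing - field$spacing)) > 1e-9 ||
      max(abs(geom$origin - field$origin)) > 1e-9)
    stop("geometry and field do not share one affine")
  lin <- which(geom$ed_mask)
  if (!length(lin)) stop("ed_mask is empty: no seeds")
  d <- dim(geom$ed_mask)
  iz <- (lin - 1) %/% (d[1] * d[2])
  iy <- ((lin - 1) %% (d[1] * d[2])) %/% d[1]
  ix <- (lin - 1) %% d[1]
  centers <- cbind(geom$origin[1] + ix * geom$spacing[1],
                   geom$origin[2] + iy * geom$spacing[2],
                   geom$origin[3] + iz * geom$spacing[3])
  list(centers = centers, linear = lin, volume_mm3 = prod(geom$spacing))
}

#' Integrate a single pathline between two times
#'
#' Fixed-step fourth-order Runge-Kutta with trilinear spatial and linear
#' temporal velocity interpolation; `t_end` may precede `t_start` (backward
#' tracing). Positions are recorded at every frame time; velocities are
#' sampled at the recorded positions.
#'
#' @param field A [velocity_field()].
#' @param seed Numeric length-3 start position, mm (must lie inside the image
#'   volume).
#' @param t_start,t_end Integration times, ms.
#' @param config A [trace_config()].
#' @return An object of class `pathline`: list with `positions` (F x 3, mm),
#'   `velocities` (F x 3, m/s), `times` (ms), `qc_status`.
#' @export
integrate_pathline <- function(field, seed, t_start, t_end,
                               config = trace_config()) {
  seed <- matrix(as.numeric(seed), ncol = 3)
  d <- dim(field$v)[1:3]
  U <- pos_to_index(seed, field)
  if (any(U < 0.5) || any(U > d + 0.5))
    stop("seed lies outside the field domain")
  res <- .advect(field, seed, t_start, t_end, config$substeps_per_frame)
  pos <- matrix(res$positions[1, , ], ncol = 3)
  vel <- t(vapply(seq_along(res$times), function(j)
    field_velocity_at(field, pos[j, , drop = FALSE], res$times[j])[1, ],
    numeric(3)))
  lo <- field$origin - 0.5 * field$spacing
  hi <- field$origin + (d - 0.5) * field$spacing
  fov <- any(pos[, 1] < lo[1] | pos[, 1] > hi[1] | pos[, 2] < lo[2] |
               pos[, 2] > hi[2] | pos[, 3] < lo[3] | pos[, 3] > hi[3])
  structure(list(positions = pos, velocities = vel, times = res$times,
                 qc_status = if (fov) "left_fov" else "valid"),
            class = "pathline")
}

#' Trace the full end-diastolic blood pool through one cycle
#'
#' Every end-diastolic seed is traced backward to the preceding end-systole
#' and forward to the following end-systole, so the pathline set covers the
#' complete end-diastolic volume over one cycle.
#'
#' @param field A [velocity_field()].
#' @param geom An [lv_geometry()] with `ed_frame`/`es_frame` set (the phantom
#'   records them; for measured data use [find_es_frame()]).
#' @param config A [trace_config()].
#' @return An object of class `pathline_set`.
#' @export
trace_cycle <- function(field, geom, config = trace_config()) {
  if (is.na(geom$es_frame)) stop("geometry does not record the ES frame")
  ft <- field$frame_times
  t_ed <- ft[geom$ed_frame]
  t_es_next <- ft[geom$es_frame]
  if (t_es_next <= t_ed) t_es_next <- t_es_next + field$cycle_length
  t_es_prev <- t_es_next - field$cycle_length
  if (!field$periodic && (t_es_prev < ft[1] - 1e-9))
    stop("backward tracing to the preceding ES needs data before the first ",
         "frame; only periodic (phantom) fields support this")
  seeds <- seed_pathlines(geom, field)
  N <- nrow(seeds$centers)
  bwd <- .advect(field, seeds$centers, t_ed, t_es_prev,
                 config$substeps_per_frame, geom)
  fwd <- .advect(field, seeds$centers, t_ed, t_es_next,
                 config$substeps_per_frame, geom)
  nb <- length(bwd$times)
  times <- c(rev(bwd$times), fwd$times[-1])
  pos <- array(NA_real_, dim = c(N, length(times), 3))
  pos[, seq_len(nb), ] <- bwd$positions[, nb:1, , drop = FALSE]
  pos[, nb - 1L + seq_along(fwd$times), ] <- fwd$positions
  vel <- array(NA_real_, dim = dim(pos))
  for (j in seq_along(times))
    vel[, j, ] <- field_velocity_at(field, pos[, j, ], times[j])
  qc <- rep("valid", N)
  qc[bwd$left_fov | fwd$left_fov] <- "left_fov"
  # a wall exit precedes any later field-of-view exit: it takes precedence
  qc[bwd$exit_label == 1L | fwd$exit_label == 1L] <- "exited_wall"
  structure(list(
    positions = pos, velocities = vel, times = times,
    volume_mm3 = rep(seeds$volume_mm3, N),
    seed_linear = seeds$linear, seed_centers = seeds$centers,
    qc_status = qc,
    exit_bwd_label = bwd$exit_label, exit_bwd_t = bwd$exit_t,
    exit_fwd_label = fwd$exit_label, exit_fwd_t = fwd$exit_t,
    mitral_cross_t = bwd$plane_cross_t,
    component = rep(NA_character_, N),
    inflow_phase = rep("none", N),
    ed_index = nb, ed_frame = geom$ed_frame, es_frame = geom$es_frame,
    cycle_length = field$cycle_length,
    config = config), class = "pathline_set")
}

#' @export
print.pathline_set <- function(x, ...) {
  n <- length(x$volume_mm3)
  cat("pathline_set: ", n, " pathlines x ", length(x$times), " timeframes (",
      sprintf("%.1f", min(x$times)), " to ", sprintf("%.1f", max(x$times)),
      " ms)\n", sep = "")
  cat("  represented volume ", sprintf("%.1f", sum(x$volume_mm3) / 1000),
      " mL; QC: ", sum(x$qc_status == "valid"), " valid, ",
      sum(x$qc_status != "valid"), " invalid\n", sep = "")
  if (!all(is.na(x$component))) print(table(x$component, useNA = "ifany"))
  invisible(x)
}

#' @export
length.pathline_set <- function(x) length(x$volume_mm3)

#' Quality control of a traced pathline set
#'
#' A pathline may leave the blood pool only through a face labelled as the
#' mitral or aortic orifice; pathlines that exited through wall-labelled
#' faces (including the apex) indicate data errors and are marked
#' `exited_wall`. The report gives the invalid fraction and a PASS/FAIL
#' verdict against the configured threshold. QC reports — it never raises.
#'
#' @param pathlines A `pathline_set` from [trace_cycle()].
#' @param geom The [lv_geometry()] used for tracing.
#' @param qc_invalid_fraction_max Override of the threshold recorded in the
#'   set's trace configuration.
#' @return List with `pathlines` (statuses set) and `report`
#'   (`n_total`, `n_invalid`, `fraction`, `verdict`).
#' @export
qc_pathlines <- function(pathlines, geom, qc_invalid_fraction_max = NULL) {
  thr <- if (is.null(qc_invalid_fraction_max))
    pathlines$config$qc_invalid_fraction_max else qc_invalid_fraction_max
  n <- length(pathlines$volume_mm3)
  invalid <- pathlines$qc_status != "valid"
  frac <- sum(invalid) / n
  report <- list(n_total = n, n_invalid = sum(invalid), fraction = frac,
                 verdict = if (frac > thr) "FAIL" else "PASS")
  list(pathlines = pathlines, report = report)
}

#' Pathlines as a long-format data frame / CSV
#'
#' Columns: `pathline_id`, `frame`, `t_ms`, `x_mm`, `y_mm`, `z_mm`,
#' `vx_m_s`, `vy_m_s`, `vz_m_s`.
#'
#' @param x A `pathline_set`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return data.frame in deterministic order (pathline, then frame).
#' @export
as.data.frame.pathline_set <- function(x, row.names = NULL, optional = FALSE, ...) {
  N <- length(x$volume_mm3); Fn <- length(x$times)
  data.frame(pathline_id = rep(seq_len(N), each = Fn),
             frame = rep(seq_len(Fn), N),
             t_ms = rep(x$times, N),
             x_mm = as.vector(t(x$positions[, , 1])),
             y_mm = as.vector(t(x$positions[, , 2])),
             z_mm = as.vector(t(x$positions[, , 3])),
             vx_m_s = as.vector(t(x$velocities[, , 1])),
             vy_m_s = as.vector(t(x$velocities[, , 2])),
             vz_m_s = as.vector(t(x$velocities[, , 3])))
}

#' @rdname as.data.frame.pathline_set
#' @param pathlines A `pathline_set`.
#' @param path CSV path.
#' @export
write_pathlines <- function(pathlines, path) {
  utils::write.csv(as.data.frame(pathlines), path, row.names = FALSE)
  invisible(path)
}

#' @rdname as.data.frame.pathline_set
#' @export
read_pathlines <- function(path) {
  df <- utils::read.csv(path)
  need <- c("pathline_id", "frame", "t_ms", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("pathline CSV is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}
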