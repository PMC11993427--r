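COMPONENTS <- c("direct", "retained_inflow", "delayed_ejection", "residual")

#' Classify pathlines into the four functional flow components
#'
#' A pathline's location relative to the ventricle at the preceding and the
#' following end-systole (voxel-centre containment in the ES segmentations)
#' determines its component:
#' \itemize{
#'   \item outside at preceding ES, outside at following ES: \strong{direct}
#'     flow (entered during diastole, ejected during systole);
#'   \item outside, inside: \strong{retained inflow};
#'   \item inside, outside: \strong{delayed ejection} flow;
#'   \item inside, inside: \strong{residual} volume.
#' }
#' QC-invalid pathlines stay unassigned.
#'
#' @param pathlines A `pathline_set` traced over the full cycle.
#' @param geom The [lv_geometry()] (supplies `es_mask_prev`, `es_mask_next`).
#' @return The pathline set with `component` filled in.
#' @export
classify_pathlines <- function(pathlines, geom) {
  ps <- pathlines
  Fn <- length(ps$times)
  at_prev <- points_in_mask(ps$positions[, 1, ], geom$es_mask_prev,
                            geom$spacing, geom$origin)
  at_next <- points_in_mask(ps$positions[, Fn, ], geom$es_mask_next,
                            geom$spacing, geom$origin)
  comp <- ifelse(!at_prev & !at_next, "direct",
                 ifelse(!at_prev & at_next, "retained_inflow",
                        ifelse(at_prev & !at_next, "delayed_ejection",
                               "residual")))
  comp[ps$qc_status != "valid"] <- NA_character_
  ps$component <- comp
  ps
}

#' Component, inflow and ejection volumes of a classified pathline set
#'
#' Volumes are sums of the represented volumes attached at seeding; the four
#' components partition the end-diastolic volume, inflow = direct + retained
#' inflow, ejected = direct + delayed ejection.
#'
#' @param pathlines A classified `pathline_set`.
#' @return List (class `component_volumes`) with `volumes_ml` (named, the four
#'   components), `edv_ml`, `inflow_ml`, `ejected_ml`, `unassigned_ml`.
#' @export
component_volumes <- function(pathlines) {
  if (all(is.na(pathlines$component)))
    stop("no classified pathlines; run classify_pathlines() first")
  v <- pathlines$volume_mm3
  vols <- vapply(COMPONENTS, function(k)
    sum(v[!is.na(pathlines$component) & pathlines$component == k]) / 1000,
    numeric(1))
  structure(list(volumes_ml = vols,
                 edv_ml = sum(v) / 1000,
                 inflow_ml = vols[["direct"]] + vols[["retained_inflow"]],
                 ejected_ml = vols[["direct"]] + vols[["delayed_ejection"]],
                 unassigned_ml = sum(v[is.na(pathlines$component)]) / 1000),
            class = "component_volumes")
}

#' Kinetic energy of one pathline at one timepoint
#'
#' `KE = 1/2 * rho * V_pathline * v_pathline^2`, with the blood density
#' `rho` (kg/m^3), the represented volume `V` (converted mm^3 to m^3) and the
#' pathline speed at the requested frame time (m/s); returned in uJ.
#'
#' @param p A `pathline` (from [integrate_pathline()]) or a list with
#'   `velocities` (F x 3, m/s), `times` (ms) and `volume_mm3`.
#' @param t A recorded frame time of the pathline, ms.
#' @param constants [blood_constants()].
#' @param volume_mm3 Represented volume; defaults to `p$volume_mm3`.
#' @return Kinetic energy in uJ.
#' @export
pathline_ke <- function(p, t, constants = blood_constants(),
                        volume_mm3 = p$volume_mm3) {
  j <- which(abs(p$times - t) < 1e-6)
  if (!length(j)) stop("t = ", t, " ms is not a recorded frame time")
  if (is.null(volume_mm3)) stop("pathline has no represented volume")
  sp2 <- sum(p$velocities[j[1], ]^2)
  0.5 * constants$rho * (volume_mm3 * 1e-9) * sp2 * 1e6
}

## KE of every pathline at every frame (N x F matrix, uJ)
.ke_matrix <- function(ps, constants) {
  sp2 <- ps$velocities[, , 1]^2 + ps$velocities[, , 2]^2 + ps$velocities[, , 3]^2
  0.5 * constants$rho * 1e-3 * ps$volume_mm3 * sp2
}

#' Kinetic-energy time series per flow component
#'
#' The KE of a component at each frame is the sum of the KE of its pathlines;
#' it is also normalised by the component's volume (uJ/mL). Components with no
#' pathlines are absent from the output (not reported as zero).
#'
#' @param pathlines A classified `pathline_set`.
#' @param constants [blood_constants()].
#' @return data.frame with `component`, `frame`, `t_ms`, `ke_total_uJ`,
#'   `ke_per_ml_uJ`.
#' @export
component_ke_timeseries <- function(pathlines, constants = blood_constants()) {
  ke <- .ke_matrix(pathlines, constants)
  vols <- component_volumes(pathlines)$volumes_ml
  out <- list()
  for (k in COMPONENTS) {
    sel <- !is.na(pathlines$component) & pathlines$component == k
    if (!any(sel)) next
    tot <- colSums(ke[sel, , drop = FALSE])
    out[[k]] <- data.frame(component = k, frame = seq_along(pathlines$times),
                           t_ms = pathlines$times, ke_total_uJ = tot,
                           ke_per_ml_uJ = tot / vols[[k]])
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Find the mid-diastole frame (diastasis)
#'
#' The diastolic frame interval with the fewest pathline crossings of the
#' mitral valve plane is taken as mid-diastole, splitting diastole into its
#' early (E-wave) and late (A-wave) phases; ties break toward the earlier
#' frame.
#'
#' @param pathlines A traced `pathline_set` (mitral crossings are recorded
#'   during tracing).
#' @param geom The [lv_geometry()].
#' @return 1-based index into the pathline set's recorded times marking the
#'   start of the mid-diastole frame interval, with attributes `time_ms` (its
#'   time), `cycle_frame` (the corresponding cine frame) and `counts` (the
#'   per-interval crossing counts).
#' @export
find_mid_diastole <- function(pathlines, geom) {
  ps <- pathlines
  nd <- ps$ed_index - 1L       # diastolic frame intervals: ES_prev -> ED
  if (nd < 3) stop("fewer than 3 diastolic frames; cannot locate diastasis")
  counts <- integer(nd)
  ct <- ps$mitral_cross_t[!is.na(ps$mitral_cross_t)]
  for (k in seq_len(nd))
    counts[k] <- sum(ct >= ps$times[k] & ct < ps$times[k + 1])
  k_min <- which.min(counts)   # which.min takes the earliest on ties
  n_frames <- round(ps$cycle_length / mean(diff(ps$times)))
  cyc <- ((ps$es_frame - 1L + k_min - 1L) %% n_frames) + 1L
  structure(as.integer(k_min), time_ms = ps$times[k_min],
            cycle_frame = cyc, counts = counts)
}

#' Split inflow into early (E) and late (A) diastolic fractions
#'
#' Direct-flow and retained-inflow pathlines are labelled `early` if they
#' crossed the mitral plane before the mid-diastole frame and `late`
#' otherwise, so early + late volumes sum to each component's volume and the
#' early and late direct-flow ratios to total inflow add up to the overall
#' direct-flow/inflow ratio. Inflow pathlines with no detectable mitral
#' crossing are counted by their first entry into the LV mask, with a
#' warning.
#'
#' @param pathlines A classified `pathline_set`.
#' @param mid Result of [find_mid_diastole()].
#' @return List with `pathlines` (`inflow_phase` filled), `split` (early/late
#'   volumes in mL for direct flow and retained inflow) and `ratios`
#'   (early, late and total direct-flow fractions of total inflow).
#' @export
split_direct_flow <- function(pathlines, mid) {
  ps <- pathlines
  t_mid <- attr(mid, "time_ms")
  if (is.null(t_mid)) t_mid <- ps$times[as.integer(mid)]
  inflow <- !is.na(ps$component) & ps$component %in% c("direct", "retained_inflow")
  ct <- ps$mitral_cross_t
  nocross <- inflow & is.na(ct)
  if (any(nocross)) {
    fallback <- ps$exit_bwd_t[nocross]   # first departure from the LV mask,
    ct[nocross] <- fallback              # traced backward = entry time
    if (any(is.na(ct[nocross]))) {
      warning(sum(is.na(ct[nocross])), " inflow pathline(s) with no ",
              "detectable mitral crossing or mask entry; counted as early")
      ct[nocross & is.na(ct)] <- -Inf
    } else {
      warning(sum(nocross), " inflow pathline(s) with no detectable mitral ",
              "crossing; counted per first entry into the LV mask")
    }
  }
  phase <- rep("none", length(ps$volume_mm3))
  phase[inflow] <- ifelse(ct[inflow] < t_mid, "early", "late")
  ps$inflow_phase <- phase
  v <- ps$volume_mm3 / 1000
  vol_of <- function(comp, ph)
    sum(v[inflow & ps$component == comp & phase == ph])
  split <- list(direct = c(early = vol_of("direct", "early"),
                           late = vol_of("direct", "late")),
                retained_inflow = c(early = vol_of("retained_inflow", "early"),
                                    late = vol_of("retained_inflow", "late")))
  total_inflow <- sum(v[inflow])
  ratios <- c(early = unname(split$direct["early"]) / total_inflow,
              late = unname(split$direct["late"]) / total_inflow,
              direct_to_inflow = sum(split$direct) / total_inflow)
  list(pathlines = ps, split = split, ratios = ratios)
}

#' LV flow-component analysis of a velocity field
#'
#' The full pathline analysis in one call: seed the end-diastolic blood pool,
#' trace every seed backward and forward to the adjacent end-systoles, apply
#' quality control, classify the four functional flow components, accumulate
#' kinetic energy per component, locate mid-diastole and split the inflow
#' into its early/late diastolic fractions.
#'
#' @param field A [velocity_field()].
#' @param geom An [lv_geometry()] on the same grid.
#' @param config A [trace_config()].
#' @param constants [blood_constants()].
#' @return An object of class `lv_flow`; see [component_result()] for the
#'   result table, and `print()`, `summary()`, `coef()`, `plot()` methods.
#' @examples
#' \donttest{
#' ph <- make_lv_phantom(phantom_params(), ground_truth = FALSE)
#' fit <- lv_flow(ph$field, ph$geometry)
#' fit
#' }
#' @export
lv_flow <- function(field, geom, config = trace_config(),
                    constants = blood_constants()) {
  ps <- trace_cycle(field, geom, config)
  qc <- qc_pathlines(ps, geom)
  ps <- classify_pathlines(qc$pathlines, geom)
  vols <- component_volumes(ps)
  ke_ts <- component_ke_timeseries(ps, constants)
  mid <- tryCatch(find_mid_diastole(ps, geom), error = function(e) NULL)
  split <- NULL
  if (!is.null(mid)) {
    sp <- split_direct_flow(ps, mid)
    ps <- sp$pathlines
    split <- sp[c("split", "ratios")]
  }
  ed_row <- ke_ts[ke_ts$frame == ps$ed_index, , drop = FALSE]
  ke_ed <- stats::setNames(ed_row$ke_per_ml_uJ, ed_row$component)
  structure(list(pathlines = ps, qc = qc$report, volumes = vols,
                 ke_timeseries = ke_ts, ke_per_ml_at_ed = ke_ed,
                 mid_diastole = mid, direct_flow_split = split,
                 constants = constants, config = config),
            class = "lv_flow")
}

#' Assemble the component-result table of an LV flow analysis
#'
#' @param fit An `lv_flow` object.
#' @return Object of class `component_result`: per-component volumes (mL) and
#'   end-diastolic KE/mL (uJ/mL), plus EDV, inflow and ejected volumes and the
#'   early/late direct-flow split.
#' @export
component_result <- function(fit) {
  stopifnot(inherits(fit, "lv_flow"))
  structure(list(volumes_ml = fit$volumes$volumes_ml,
                 ke_per_ml_at_ed_uJ = fit$ke_per_ml_at_ed,
                 edv_ml = fit$volumes$edv_ml,
                 inflow_ml = fit$volumes$inflow_ml,
                 ejected_ml = fit$volumes$ejected_ml,
                 direct_flow_split = fit$direct_flow_split),
            class = "component_result")
}

#' @export
print.lv_flow <- function(x, ...) {
  cat("LV flow-component analysis\n")
  cat(sprintf("  EDV %.1f mL; inflow %.1f mL; ejected %.1f mL\n",
              x$volumes$edv_ml, x$volumes$inflow_ml, x$volumes$ejected_ml))
  v <- x$volumes$volumes_ml
  for (k in names(v))
    cat(sprintf("  %-17s %6.1f mL (%4.1f%% of EDV)%s\n", k, v[[k]],
                100 * v[[k]] / x$volumes$edv_ml,
                if (!is.na(x$ke_per_ml_at_ed[k]))
                  sprintf("; KE at ED %.2f uJ/mL", x$ke_per_ml_at_ed[[k]])
                else ""))
  if (!is.null(x$direct_flow_split))
    cat(sprintf("  direct/inflow %.1f%% (early %.1f%% + late %.1f%%)\n",
                100 * x$direct_flow_split$ratios[["direct_to_inflow"]],
                100 * x$direct_flow_split$ratios[["early"]],
                100 * x$direct_flow_split$ratios[["late"]]))
  cat(sprintf("  QC: %d/%d invalid (%.2f%%) -> %s\n", x$qc$n_invalid,
              x$qc$n_total, 100 * x$qc$fraction, x$qc$verdict))
  invisible(x)
}

#' @export
summary.lv_flow <- function(object, ...) {
  res <- component_result(object)
  print(object)
  if (!is.null(object$mid_diastole))
    cat("  mid-diastole at cine frame ",
        attr(object$mid_diastole, "cycle_frame"), " (",
        sprintf("%.0f", attr(object$mid_diastole, "time_ms") %% object$pathlines$cycle_length),
        " ms)\n", sep = "")
  invisible(res)
}

#' @export
coef.lv_flow <- function(object, ...) object$volumes$volumes_ml

#' @export
plot.lv_flow <- function(x, which = c("ke", "volumes"), ...) {
  which <- match.arg(which)
  if (which == "volumes") {
    graphics::barplot(x$volumes$volumes_ml, ylab = "volume (mL)",
                      main = "LV flow components", col = "grey70", ...)
  } else {
    ts <- x$ke_timeseries
    comps <- unique(ts$component)
    cols <- grDevices::hcl.colors(max(4, length(comps)), "Dark 3")
    graphics::plot(range(ts$t_ms), range(ts$ke_total_uJ), type = "n",
                   xlab = "time from preceding ES (ms)", ylab = "KE (uJ)",
                   main = "Component kinetic energy", ...)
    for (i in seq_along(comps)) {
      s <- ts[ts$component == comps[i], ]
      graphics::lines(s$t_ms, s$ke_total_uJ, col = cols[i], lwd = 2)
    }
    graphics::abline(v = x$pathlines$times[x$pathlines$ed_index], lty = 3)
    graphics::legend("topleft", comps, col = cols[seq_along(comps)],
                     lwd = 2, bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' @export
print.component_result <- function(x, ...) {
  cat("Component result: EDV", sprintf("%.1f", x$edv_ml), "mL\n")
  df <- data.frame(component = names(x$volumes_ml),
                   volume_ml = round(unname(x$volumes_ml), 1),
                   ke_ed_uJ_per_ml = round(unname(
                     x$ke_per_ml_at_ed_uJ[names(x$volumes_ml)]), 3))
  print(df, row.names = FALSE)
  invisible(x)
}
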