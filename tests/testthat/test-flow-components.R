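# Minimal hand-built pathline set: two frames, four pathlines, one per
# classification case.  The "ventricle" is a 3-voxel bar; points at +-100 are
# far outside it.
mini_set <- function() {
  mask <- array(FALSE, dim = c(5, 3, 3)); mask[2:4, 2, 2] <- TRUE
  geom <- lv_geometry(mask, mask, mask, spacing = 3, origin = c(0, 0, 0),
                      mitral_orifice = list(center = c(-1.5, 3, 3),
                                            normal = c(-1, 0, 0), radius = 5),
                      aortic_orifice = list(center = c(10.5, 3, 3),
                                            normal = c(1, 0, 0), radius = 5),
                      ed_frame = 1L, es_frame = 2L)
  inside <- c(6, 3, 3); outside <- c(100, 100, 100)
  pos <- array(NA_real_, dim = c(4, 2, 3))
  pos[1, 1, ] <- outside; pos[1, 2, ] <- outside   # entered & ejected
  pos[2, 1, ] <- outside; pos[2, 2, ] <- inside    # entered & kept
  pos[3, 1, ] <- inside;  pos[3, 2, ] <- outside   # resided & ejected
  pos[4, 1, ] <- inside;  pos[4, 2, ] <- inside    # resided & kept
  ps <- structure(list(
    positions = pos, velocities = array(0, dim = c(4, 2, 3)),
    times = c(-100, 100), volume_mm3 = rep(27, 4), seed_linear = 1:4,
    seed_centers = pos[, 1, ], qc_status = rep("valid", 4),
    exit_bwd_label = integer(4), exit_bwd_t = rep(NA_real_, 4),
    exit_fwd_label = integer(4), exit_fwd_t = rep(NA_real_, 4),
    mitral_cross_t = rep(NA_real_, 4), component = rep(NA_character_, 4),
    inflow_phase = rep("none", 4), ed_index = 1L, ed_frame = 1L,
    es_frame = 2L, cycle_length = 200, config = trace_config()),
    class = "pathline_set")
  list(ps = ps, geom = geom)
}

test_that("end-systolic positions map onto the four component definitions", {
  m <- mini_set()
  ps <- classify_pathlines(m$ps, m$geom)
  expect_identical(unname(ps$component),
                   c("direct", "retained_inflow", "delayed_ejection",
                     "residual"))
  # QC-invalid pathlines stay unassigned
  m$ps$qc_status[1] <- "exited_wall"
  ps2 <- classify_pathlines(m$ps, m$geom)
  expect_true(is.na(ps2$component[1]))
})

test_that("component volumes partition the EDV with the stated identities", {
  ps <- lv_pathlines_default()
  cv <- component_volumes(ps)
  expect_equal(sum(cv$volumes_ml), cv$edv_ml, tolerance = 1e-12)
  expect_equal(cv$inflow_ml,
               cv$volumes_ml[["direct"]] + cv$volumes_ml[["retained_inflow"]])
  expect_equal(cv$ejected_ml,
               cv$volumes_ml[["direct"]] + cv$volumes_ml[["delayed_ejection"]])
  expect_true(all(cv$volumes_ml >= 0))
  expect_true(all(cv$volumes_ml > 0))  # all four populated on the LV phantom
  unc <- mini_set()$ps
  expect_error(component_volumes(unc), "classify")
})

test_that("pathline kinetic energy follows 1/2 rho V v^2 in uJ", {
  p <- list(velocities = matrix(c(1, 0, 0), 1, 3), times = 0, volume_mm3 = 27)
  # 0.5 * 1060 kg/m^3 * 2.7e-8 m^3 * (1 m/s)^2 = 1.431e-5 J = 14.31 uJ
  expect_equal(pathline_ke(p, 0), 14.31)
  p0 <- list(velocities = matrix(0, 1, 3), times = 0, volume_mm3 = 27)
  expect_equal(pathline_ke(p0, 0), 0)
  p2 <- list(velocities = matrix(c(2, 0, 0), 1, 3), times = 0, volume_mm3 = 27)
  expect_equal(pathline_ke(p2, 0), 4 * pathline_ke(p, 0))
  expect_error(pathline_ke(p, 17), "not a recorded frame time")
})

test_that("component KE is additive over its pathlines at every frame", {
  ps <- lv_pathlines_default()
  ke_ts <- component_ke_timeseries(ps)
  ke_mat <- cardioflow:::.ke_matrix(ps, blood_constants())
  for (k in unique(ke_ts$component)) {
    sel <- !is.na(ps$component) & ps$component == k
    manual <- colSums(ke_mat[sel, , drop = FALSE])
    expect_equal(ke_ts$ke_total_uJ[ke_ts$component == k], unname(manual))
  }
  expect_true(all(ke_ts$ke_total_uJ >= 0))
  # normalisation: ke_per_ml * volume = ke_total
  vols <- component_volumes(ps)$volumes_ml
  expect_equal(ke_ts$ke_per_ml_uJ * vols[ke_ts$component],
               ke_ts$ke_total_uJ, ignore_attr = TRUE)
})

test_that("an all-stationary field carries zero kinetic energy", {
  d0 <- make_duct_phantom(v = 0)
  ps <- classify_pathlines(trace_cycle(d0$field, d0$geometry), d0$geometry)
  ke <- component_ke_timeseries(ps)
  expect_true(all(ke$ke_total_uJ == 0))
  # empty components are absent, not zero
  expect_identical(unique(ke$component), "residual")
})

test_that("mid-diastole lands in the diastasis gap found by brute force", {
  ps <- lv_pathlines_default()
  ph <- lv_phantom_default()
  mid <- find_mid_diastole(ps, ph$geometry)
  # brute-force oracle: count sign changes of the plane coordinate within the
  # mitral disk, per recorded frame interval, directly from the positions
  pl <- ph$geometry$mitral_plane
  z <- ps$positions[, , 3]
  nd <- ps$ed_index - 1L
  brute <- integer(nd)
  for (k in seq_len(nd)) {
    crossed <- (z[, k] >= pl$point[3]) != (z[, k + 1] >= pl$point[3])
    xy <- ps$positions[, k, 1:2]
    rad <- sqrt((xy[, 1] - pl$point[1])^2 + (xy[, 2] - pl$point[2])^2)
    brute[k] <- sum(crossed & rad <= 1.5 * ph$geometry$mitral_orifice$radius)
  }
  expect_equal(as.integer(mid), which.min(brute))
  # the detected frame sits in a zero-crossing plateau between E and A waves
  expect_equal(attr(mid, "counts")[as.integer(mid)], 0L)
  expect_gt(attr(mid, "counts")[1], 0L)
  expect_gt(attr(mid, "counts")[nd], 0L)
})

test_that("mid-diastole detection needs at least 3 diastolic frames", {
  m <- mini_set()
  expect_error(find_mid_diastole(m$ps, m$geom), "diastolic frames")
})

test_that("early and late inflow fractions add up to the direct-flow ratio", {
  ps <- lv_pathlines_default()
  ph <- lv_phantom_default()
  mid <- find_mid_diastole(ps, ph$geometry)
  sp <- suppressWarnings(split_direct_flow(ps, mid))
  expect_equal(unname(sp$ratios["early"] + sp$ratios["late"]),
               unname(sp$ratios["direct_to_inflow"]), tolerance = 1e-12)
  cv <- component_volumes(ps)
  expect_equal(sum(sp$split$direct), cv$volumes_ml[["direct"]])
  expect_equal(sum(sp$split$retained_inflow),
               cv$volumes_ml[["retained_inflow"]])
  # phases assigned exactly to inflow pathlines
  inflow <- sp$pathlines$component %in% c("direct", "retained_inflow")
  expect_true(all(sp$pathlines$inflow_phase[inflow] %in% c("early", "late")))
  expect_true(all(sp$pathlines$inflow_phase[!inflow] == "none"))
})

test_that("single-wave inflow puts no volume in the late fraction", {
  # essentially all inflow in the E wave (lower EF keeps the jet below VENC)
  ph <- make_lv_phantom(phantom_params(ef = 0.30, e_a_ratio = 1e6),
                        ground_truth = FALSE)
  ps <- classify_pathlines(
    qc_pathlines(trace_cycle(ph$field, ph$geometry), ph$geometry)$pathlines,
    ph$geometry)
  mid <- find_mid_diastole(ps, ph$geometry)
  sp <- suppressWarnings(split_direct_flow(ps, mid))
  expect_equal(unname(sp$split$direct[["late"]]), 0)
  expect_equal(unname(sp$split$retained_inflow[["late"]]), 0)
  expect_gt(sp$split$direct[["early"]], 0)
})

test_that("equal E and A volumes give an approximately even inflow split", {
  ph <- make_lv_phantom(phantom_params(e_a_ratio = 1), ground_truth = FALSE)
  ps <- classify_pathlines(
    qc_pathlines(trace_cycle(ph$field, ph$geometry), ph$geometry)$pathlines,
    ph$geometry)
  mid <- find_mid_diastole(ps, ph$geometry)
  sp <- suppressWarnings(split_direct_flow(ps, mid))
  early <- sp$split$direct[["early"]] + sp$split$retained_inflow[["early"]]
  late <- sp$split$direct[["late"]] + sp$split$retained_inflow[["late"]]
  expect_lt(abs(early - late) / (early + late), 0.15)
})

test_that("the assembled lv_flow fit is internally consistent", {
  ph <- lv_phantom_default()
  fit <- suppressWarnings(lv_flow(ph$field, ph$geometry))
  expect_s3_class(fit, "lv_flow")
  expect_equal(sum(coef(fit)), fit$volumes$edv_ml)
  expect_identical(fit$qc$verdict, "PASS")
  res <- component_result(fit)
  expect_s3_class(res, "component_result")
  expect_equal(res$edv_ml, fit$volumes$edv_ml)
  expect_output(print(fit), "LV flow-component analysis")
  expect_output(print(fit), "direct/inflow")
})
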