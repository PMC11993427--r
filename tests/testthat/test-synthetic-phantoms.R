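test_that("zero-velocity duct leaves every pathline stationary and residual", {
  d0 <- make_duct_phantom(v = 0)
  ps <- trace_cycle(d0$field, d0$geometry)
  expect_equal(max(abs(sweep(ps$positions, c(1, 3), ps$seed_centers, "-"))), 0)
  ps <- classify_pathlines(ps, d0$geometry)
  expect_true(all(ps$component == "residual"))
  expect_true(all(d0$truth$true_component == "residual"))
})

test_that("duct pathlines follow the closed form x0 + v t exactly", {
  d <- duct_default()  # v = 0.1 m/s
  dt <- diff(d$field$frame_times)[1]
  seed <- c(15, 15, 15)
  pl <- integrate_pathline(d$field, seed, 0, 5 * dt)
  disp <- diff(pl$positions[, 1])
  expect_equal(disp, rep(0.1 * dt, 5), tolerance = 1e-12)
  expect_equal(pl$positions[, 2], rep(15, 6))
  # 100 ms at 0.1 m/s -> exactly 10 mm (RK4 exact for a constant field)
  pl2 <- integrate_pathline(d$field, seed, 0, 100)
  expect_equal(pl2$positions[nrow(pl2$positions), 1] - 15, 10, tolerance = 1e-12)
})

test_that("a 10x10x10-voxel duct at 3 mm holds 27 mL and seeds carry it all", {
  d <- duct_default()  # extent 30 mm
  expect_equal(sum(d$geometry$ed_mask), 1000)
  seeds <- seed_pathlines(d$geometry, d$field)
  expect_equal(nrow(seeds$centers), 1000)
  expect_equal(seeds$volume_mm3, 27)
  expect_equal(nrow(seeds$centers) * seeds$volume_mm3 / 1000, 27)
})

test_that("duct speed beyond VENC is rejected", {
  expect_error(make_duct_phantom(v = 1.2), "VENC")
})

test_that("rotation phantom is rigid: circles, constant speed, constant KE", {
  r <- rotation_default()  # omega = 8 rad/s
  ps <- trace_cycle(r$field, r$geometry)
  r0 <- sqrt(ps$seed_centers[, 1]^2 + ps$seed_centers[, 2]^2)
  rad <- sqrt(ps$positions[, , 1]^2 + ps$positions[, , 2]^2)
  expect_lt(max(abs(rad - r0)), 1e-4)            # analytic circle
  sp <- sqrt(ps$velocities[, , 1]^2 + ps$velocities[, , 2]^2)
  expect_equal(sp, matrix(8 * r0 / 1000, nrow(sp), ncol(sp)),
               tolerance = 1e-6)                  # speed = omega * r
  ps <- classify_pathlines(ps, r$geometry)
  ke <- component_ke_timeseries(ps)
  expect_lt(diff(range(ke$ke_total_uJ)) / max(ke$ke_total_uJ), 0.01)
  expect_error(make_rotation_phantom(omega = 40), "VENC")
})

test_that("rotation and duct oracle labels equal the closed-form labels", {
  r <- rotation_default()
  ps <- classify_pathlines(
    qc_pathlines(trace_cycle(r$field, r$geometry), r$geometry)$pathlines,
    r$geometry)
  expect_identical(unname(ps$component), r$truth$true_component)
  d <- duct_default()
  psd <- classify_pathlines(
    qc_pathlines(trace_cycle(d$field, d$geometry), d$geometry)$pathlines,
    d$geometry)
  expect_identical(unname(psd$component), d$truth$true_component)
})

test_that("LV phantom hits the prescribed EDV within one voxel and ejects ~EF*EDV", {
  ph <- lv_phantom_default()
  vox <- prod(ph$geometry$spacing)
  edv <- sum(ph$geometry$ed_mask) * vox / 1000
  expect_lt(abs(edv - 179), vox / 1000 + 1e-9)
  cv <- component_volumes(lv_pathlines_default())
  expect_equal(cv$edv_ml, edv)
  expect_lt(abs(cv$ejected_ml - 0.42 * 179) / (0.42 * 179), 0.05)
  expect_lt(abs(cv$inflow_ml - 0.42 * 179) / (0.42 * 179), 0.05)
})

test_that("LV phantom regeneration under a fixed seed is bit-identical", {
  a <- make_lv_phantom(phantom_params(seed = 5L), ground_truth = FALSE)
  b <- make_lv_phantom(phantom_params(seed = 5L), ground_truth = FALSE)
  expect_identical(a$field$v, b$field$v)
  expect_identical(a$geometry$ed_mask, b$geometry$ed_mask)
})

test_that("parameter combinations that exceed VENC are refused with advice", {
  expect_error(make_lv_phantom(phantom_params(heart_rate = 140, ef = 0.75,
                                              e_a_ratio = 40),
                               ground_truth = FALSE),
               "VENC")
})

test_that("the prescribed volume curve is periodic, biphasic and EF-consistent", {
  cyc <- 60000 / 61
  tt <- seq(0, cyc, length.out = 2001)
  cv <- lv_volume_curve(tt, edv = 179, ef = 0.42, cycle_length = cyc,
                        es_time = 0.35 * cyc, e_a_ratio = 1.5)
  expect_equal(cv$v[1], 179)
  expect_equal(cv$v[length(tt)], 179, tolerance = 1e-9)
  expect_equal(min(cv$v), 179 * 0.58, tolerance = 1e-4)
  # diastasis: a zero-rate plateau strictly between the E and A waves
  dias <- tt > 0.75 * cyc & tt < 0.78 * cyc
  expect_equal(max(abs(cv$vdot[dias])), 0)
  # E/A volume split
  e_win <- cv$vdot > 0 & tt < 0.75 * cyc
  a_win <- cv$vdot > 0 & tt > 0.75 * cyc
  ev <- sum(cv$vdot[e_win]) * diff(tt)[1]
  av <- sum(cv$vdot[a_win]) * diff(tt)[1]
  expect_equal(ev / av, 1.5, tolerance = 0.01)
})

test_that("boundary fluxes reproduce the prescribed volume curve within 2%", {
  ph <- lv_phantom_default()
  f <- ph$field
  d <- dim(f$v)[1:3]
  zc <- f$origin[3] + (seq_len(d[3]) - 1) * f$spacing[3]
  iztop <- max(which(zc <= 0 & zc > -81))
  area <- prod(f$spacing[1:2])
  flux <- vapply(seq_along(f$frame_times), function(k)
    sum(f$v[, , iztop, 3, k]) * area, numeric(1))        # mm^3/ms upward
  n <- length(flux)
  dtf <- f$cycle_length / n
  vint <- cumsum((flux + c(flux[-1], flux[1])) / 2) * dtf / 1000
  vol_from_flux <- -c(0, vint[-n])
  p <- phantom_params()
  cv <- lv_volume_curve(f$frame_times, p$edv, p$ef, f$cycle_length,
                        f$frame_times[ph$geometry$es_frame], p$e_a_ratio)
  expect_lt(max(abs(vol_from_flux - (cv$v - cv$v[1]))), 0.02 * p$edv)
})

test_that("diastolic mitral flux balances systolic aortic flux (mass conservation)", {
  ph <- lv_phantom_default()
  f <- ph$field
  d <- dim(f$v)[1:3]
  zc <- f$origin[3] + (seq_len(d[3]) - 1) * f$spacing[3]
  iztop <- max(which(zc <= 0 & zc > -81))
  area <- prod(f$spacing[1:2])
  dtf <- f$cycle_length / length(f$frame_times)
  flux <- vapply(seq_along(f$frame_times), function(k)
    sum(f$v[, , iztop, 3, k]) * area, numeric(1))
  out_vol <- sum(flux[flux > 0]) * dtf / 1000    # systolic ejection, mL
  in_vol <- -sum(flux[flux < 0]) * dtf / 1000    # diastolic filling, mL
  expect_equal(out_vol, in_vol, tolerance = 0.02)
  expect_equal(out_vol, 0.42 * 179, tolerance = 0.03)
})

test_that("phantom parameter validation enforces the documented ranges", {
  expect_error(phantom_params(ef = 1.2))
  expect_error(phantom_params(ef = 0))
  expect_error(phantom_params(n_frames = 4))
  expect_error(phantom_params(e_a_ratio = 0))
  expect_error(phantom_params(edv = -1))
})
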