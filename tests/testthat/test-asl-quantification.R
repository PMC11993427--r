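test_that("polar resampling averages per angular bin and flags empty bins", {
  geo <- asl_ring_geometry()
  img <- matrix(42, geo$n, geo$n)
  pm <- polar_resample(img, geo$mask, geo$center, pixel_mm = geo$pixel_mm)
  expect_equal(pm$values, rep(42, 60))
  # half-ring: bins on the missing side are NA, never interpolated
  n <- geo$n
  coords <- (seq_len(n) - (n + 1) / 2) * geo$pixel_mm
  Y <- matrix(coords, n, n, byrow = TRUE)
  half <- geo$mask & (Y >= 0)
  pm2 <- polar_resample(img, half, geo$center, pixel_mm = geo$pixel_mm)
  expect_true(any(is.na(pm2$values)))
  expect_true(all(is.na(pm2$values[31:60])))     # angles in (pi, 2pi)
  expect_true(all(pm2$values[2:29] == 42))
  expect_error(polar_resample(img, geo$mask, center = c(1e4, 0),
                              pixel_mm = geo$pixel_mm), "outside")
})

test_that("a doubled wedge doubles exactly the covered bins", {
  geo <- asl_ring_geometry()
  n <- geo$n
  coords <- (seq_len(n) - (n + 1) / 2) * geo$pixel_mm
  X <- matrix(coords, n, n); Y <- matrix(coords, n, n, byrow = TRUE)
  ang <- atan2(Y, X) %% (2 * pi)
  img <- matrix(100, n, n)
  img[ang < pi / 3] <- 200                       # wedge over bins 1..10
  pm <- polar_resample(img, geo$mask, geo$center, pixel_mm = geo$pixel_mm)
  expect_equal(pm$values[1:10], rep(200, 10))
  expect_equal(pm$values[11:60], rep(100, 50))
})

test_that("the angular filter is a wrapped boxcar with the stated limits", {
  pm <- polar_resample(matrix(1, 96, 96), asl_ring_geometry()$mask,
                       pixel_mm = 2.5)
  set.seed(11)
  pm$values <- rnorm(60)
  # full-circle filter: every bin equals the global mean
  f <- spatiotemporal_filter(pm, 2 * pi)
  expect_equal(f$values, rep(mean(pm$values), 60))
  # one-bin width: identity
  f1 <- spatiotemporal_filter(pm, pm$bin_width)
  expect_identical(f1$values, pm$values)
  # impulse response: flat at 1/k over the window, wrapping across 0
  imp <- pm; imp$values <- c(1, rep(0, 59))
  fi <- spatiotemporal_filter(imp, pi / 3)        # k = 10 bins
  expect_equal(sum(fi$values > 0), 10)
  expect_equal(max(fi$values), 1 / 10)
  expect_true(fi$values[60] > 0)                  # wrapped support
  expect_error(spatiotemporal_filter(pm, 0), "positive")
  expect_error(spatiotemporal_filter(pm, 7), "2pi")
})

test_that("the Buxton quantification matches the hand-computed value", {
  # invert the forward model by hand: 2*1000*1000*exp(-1000/1650)*(1.2/60000)
  dC <- 2 * 1000 * 1000 * exp(-1000 / 1650) * 1.2 / 60000
  expect_equal(dC, 21.82, tolerance = 1e-3)
  expect_equal(quantify_mbf(1000 + dC, 1000, M0 = 1000, TI = 1000), 1.20)
  expect_equal(quantify_mbf(1000, 1000, 1000, 1000), 0)
  # linearity in the control-tag difference
  expect_equal(quantify_mbf(1000 + 3 * dC, 1000, 1000, 1000), 3.6)
  expect_error(quantify_mbf(10, 5, M0 = 0, TI = 1000), "M0")
  expect_error(quantify_mbf(10, 5, M0 = 1000, TI = -1), "TI")
  neg <- quantify_mbf(990, 1000, 1000, 1000)
  expect_lt(neg, 0)
  expect_true(attr(neg, "negative"))
})

test_that("a septal perfusion deficit lowers septal segments and spares lateral ones", {
  s <- asl_clean()
  geo <- s$geometry
  ti <- s$protocol$rr_interval
  m0e <- mean(s$baseline[geo$mask])
  dm <- 2 * m0e * ti * exp(-ti / 1650) * 1.20 / 60000
  n <- geo$n
  coords <- (seq_len(n) - (n + 1) / 2) * geo$pixel_mm
  X <- matrix(coords, n, n); Y <- matrix(coords, n, n, byrow = TRUE)
  ang <- atan2(Y, X) %% (2 * pi)
  septal <- ang >= pi / 2 & ang < 3 * pi / 2
  deficit <- ifelse(septal, 0.5, 1)              # half perfusion in the septum
  for (k in seq_len(s$protocol$n_pairs))
    s$tagged[, , k] <- s$controls[, , k] - dm * deficit * geo$mask
  fit <- mbf_segments(s)
  # the middle septal segment's 2pi/3 filter window lies wholly inside the
  # septal half and reads the pure deficit; the outer septal segments blend
  # across the border and sit between the deficit and normal perfusion
  expect_equal(unname(fit$septal_mbf[2]), 0.60, tolerance = 0.02)
  expect_true(all(fit$septal_mbf < 0.9))
  expect_true(all(fit$septal_mbf >= 0.58))
  expect_equal(unname(fit$regional_mbf[1]), 1.20, tolerance = 1e-6)
  expect_lt(fit$global_mbf, 1.20)
  expect_gt(fit$global_mbf, 0.6)
})

test_that("segment means are equivariant under half-turn rotation of the scene", {
  s <- asl_clean()
  geo <- s$geometry
  dm <- 2 * mean(s$baseline[geo$mask]) * s$protocol$rr_interval *
    exp(-s$protocol$rr_interval / 1650) * 1.20 / 60000
  n <- geo$n
  coords <- (seq_len(n) - (n + 1) / 2) * geo$pixel_mm
  X <- matrix(coords, n, n); Y <- matrix(coords, n, n, byrow = TRUE)
  ang <- atan2(Y, X) %% (2 * pi)
  grad <- 1 + 0.3 * cos(ang)                     # asymmetric perfusion
  for (k in seq_len(s$protocol$n_pairs))
    s$tagged[, , k] <- s$controls[, , k] - dm * grad * geo$mask
  fit <- mbf_segments(s)
  rot <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]
  s2 <- s
  s2$baseline <- rot(s$baseline)
  for (k in seq_len(s$protocol$n_pairs)) {
    s2$controls[, , k] <- rot(s$controls[, , k])
    s2$tagged[, , k] <- rot(s$tagged[, , k])
  }
  s2$geometry$mask <- rot(geo$mask)
  fit2 <- mbf_segments(s2)
  # a 180-degree rotation shifts the six segments by three
  expect_equal(unname(fit2$regional_mbf),
               unname(fit$regional_mbf[c(4, 5, 6, 1, 2, 3)]), tolerance = 1e-6)
  expect_equal(fit2$global_mbf, fit$global_mbf, tolerance = 1e-9)
})

test_that("noise decomposition follows the quadrature contract", {
  fit <- mbf_segments(asl_clean())
  series0 <- asl_clean()
  # hand-computed: per-pair spread with zero thermal noise
  fit$per_pair_mbf <- c(1.0, 1.1, 0.9, 1.05, 0.95, 1.0)
  ns <- estimate_noise(fit, series0)
  expect_equal(unname(ns["tn"]), 0)
  expect_equal(unname(ns["pn"]), stats::sd(fit$per_pair_mbf) / sqrt(6))
  expect_equal(unname(ns["pn"]), 0.02886751, tolerance = 1e-6)
  # clamped at zero when temporal variance <= thermal variance
  s <- simulate_asl_series(asl_protocol(),
                           asl_truth(1.2, motion_amplitude = 0,
                                     thermal_sd = 30, seed = 2L))
  fit2 <- mbf_segments(s)
  fit2$per_pair_mbf <- rep(1.2, 6)
  ns2 <- estimate_noise(fit2, s)
  expect_gt(ns2[["tn"]], 0)
  expect_equal(ns2[["pn"]], 0)
  fit1 <- fit; fit1$n_pairs <- 1L
  expect_error(estimate_noise(fit1, series0), "at least 2")
})

test_that("the thermal-noise floor matches the propagated closed form", {
  pr <- asl_protocol()
  geo <- asl_ring_geometry()
  pp <- unlist(lapply(1:50, function(s)
    mbf_segments(simulate_asl_series(
      pr, asl_truth(1.2, motion_amplitude = 0, thermal_sd = 30,
                    seed = s)))$per_pair_mbf))
  s1 <- simulate_asl_series(pr, asl_truth(1.2, 0, 30, seed = 1L))
  m0e <- mean(s1$baseline[geo$mask])
  closed <- 30 * sqrt(2 / sum(geo$mask)) /
    (2 * m0e * pr$rr_interval * exp(-pr$rr_interval / 1650)) * 60000
  expect_lt(abs(stats::sd(pp) - closed) / closed, 0.10)
  # and the tn estimator agrees with the same closed form
  f1 <- mbf_segments(s1)
  expect_lt(abs(f1$tn - closed / sqrt(6)) / (closed / sqrt(6)), 0.15)
})

test_that("single-pair series quantify but refuse noise estimation", {
  s <- simulate_asl_series(asl_protocol(n_pairs = 1L),
                           asl_truth(1.2, 0, 0))
  fit <- mbf_segments(s)
  expect_equal(fit$global_mbf, 1.2, tolerance = 1e-12)
  expect_true(is.na(fit$pn))
  expect_error(estimate_noise(fit, s), "at least 2")
})
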