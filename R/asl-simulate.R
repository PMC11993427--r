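#' FAIR-ASL acquisition protocol
#'
#' Defaults reproduce the reference cardiac FAIR protocol: 96 phase-encode
#' lines at TR 3.2 ms (a 307 ms acquisition window), 133 ms of fat-saturation
#' and flip-angle ramp overhead (440 ms total imaging window), inversion at
#' 77% of the R-R interval, post-labelling delay TI equal to the R-R
#' interval, one baseline/noise breath-hold followed by six control/tag
#' pairs. The accelerated protocol is the same with `sense_factor = 2`
#' (153 ms window, 286 ms total).
#'
#' @param matrix_lines Acquired k-space lines (must be divisible by
#'   `sense_factor`).
#' @param tr Readout repetition time, ms.
#' @param sense_factor Parallel-imaging reduction factor (1 or 2).
#' @param overhead Non-readout time inside the imaging window
#'   (fat saturation + flip-angle ramp), ms.
#' @param rr_interval R-R interval, ms (also the post-labelling delay TI).
#' @param inversion_fraction Inversion-pulse timing as a fraction of R-R.
#' @param n_pairs Control/tag pairs.
#' @param breath_hold_s Breath-hold length per pair acquisition, s.
#' @return Object of class `asl_protocol`.
#' @export
asl_protocol <- function(matrix_lines = 96L, tr = 3.2, sense_factor = 1L,
                         overhead = 133, rr_interval = 60000 / 61,
                         inversion_fraction = 0.77, n_pairs = 6L,
                         breath_hold_s = 12) {
  stopifnot(matrix_lines %% sense_factor == 0, tr > 0,
            inversion_fraction > 0, inversion_fraction < 1,
            n_pairs >= 1, rr_interval > 0, overhead >= 0)
  structure(list(matrix_lines = as.integer(matrix_lines), tr = tr,
                 sense_factor = as.integer(sense_factor), overhead = overhead,
                 rr_interval = rr_interval,
                 inversion_fraction = inversion_fraction,
                 n_pairs = as.integer(n_pairs), breath_hold_s = breath_hold_s),
            class = "asl_protocol")
}

#' Acquisition and total imaging windows of an ASL protocol
#'
#' The acquisition window is the readout time per image,
#' `floor(matrix_lines / sense_factor * tr)` in integer ms (307 ms for the
#' reference protocol, 153 ms accelerated); the total imaging window adds the
#' fat-saturation/ramp overhead (440 / 286 ms).
#'
#' @param protocol An [asl_protocol()].
#' @return Window length, ms.
#' @export
acquisition_window <- function(protocol) {
  floor(protocol$matrix_lines / protocol$sense_factor * protocol$tr)
}

#' @rdname acquisition_window
#' @export
total_window <- function(protocol) {
  acquisition_window(protocol) + protocol$overhead
}

#' Ground-truth settings of a simulated ASL series
#'
#' @param mbf_true True myocardial blood flow, ml/g/min.
#' @param motion_amplitude Effective in-plane displacement scale (mm, standard
#'   deviation per image) at the reference acquisition window; the simulator
#'   scales it by `acquisition_window / reference_window`. The default is
#'   calibrated so the reference protocol's physiological noise is about
#'   0.20 ml/g/min (see the methods vignette).
#' @param thermal_sd Additive Gaussian noise standard deviation in signal
#'   units (inflated by `sqrt(sense_factor)` under acceleration).
#' @param seed Integer seed (series are bit-identical under a fixed seed).
#' @return Object of class `asl_truth`.
#' @export
asl_truth <- function(mbf_true = 1.20, motion_amplitude = 1.0,
                      thermal_sd = 30, seed = 1L) {
  stopifnot(mbf_true >= 0, motion_amplitude >= 0, thermal_sd >= 0)
  structure(list(mbf_true = mbf_true, motion_amplitude = motion_amplitude,
                 thermal_sd = thermal_sd, seed = as.integer(seed)),
            class = "asl_truth")
}

#' Annular myocardium geometry for the ASL simulator/quantifier
#'
#' A single mid-ventricular short-axis slice: square matrix, centred annular
#' myocardium between `r_endo` and `r_epi`.
#'
#' @param n Matrix size (pixels per side).
#' @param fov Field of view, mm.
#' @param r_endo,r_epi Endocardial / epicardial radii, mm.
#' @param center Ring centre, mm (default image centre).
#' @return List with `mask` (logical n x n), `center` (mm), `pixel_mm`, radii.
#' @export
asl_ring_geometry <- function(n = 96L, fov = 240, r_endo = 28, r_epi = 40,
                              center = c(0, 0)) {
  stopifnot(r_epi > r_endo, r_endo > 0, fov > 0)
  px <- fov / n
  coords <- (seq_len(n) - (n + 1) / 2) * px
  X <- matrix(coords, n, n)
  Y <- matrix(coords, n, n, byrow = TRUE)
  r2 <- (X - center[1])^2 + (Y - center[2])^2
  mask <- r2 >= r_endo^2 & r2 <= r_epi^2
  if (!any(mask)) stop("myocardial ring mask is empty")
  list(mask = mask, center = center, pixel_mm = px, n = as.integer(n),
       r_endo = r_endo, r_epi = r_epi)
}

## Anatomical scene sampled with the anatomy displaced by `delta` (mm):
## bright ventricular blood pool, myocardium at the equilibrium signal m0,
## quiescent background, with fixed anatomical texture (papillary muscles,
## septal brightening, epicardial fat, lung/liver interface) as deterministic
## Gaussian structures.  The texture breaks rotational symmetry, so a rigid
## in-plane displacement perturbs the ring-mean signal linearly — the
## control/tag inconsistency mechanism behind physiological noise.  Region
## edges are smoothed over ~2 mm (edge width of a b-SSFP short-axis image).
.asl_texture <- cbind(angle = c(20, 130, 75, 250, 310, 180) * pi / 180,
                      radius = c(24, 26, 34, 42, 30, 44),
                      amp = c(-0.5, -0.45, 0.35, 0.6, -0.3, 0.5),
                      sigma = c(5, 4, 5, 6, 4, 7))
.asl_scene <- function(geo, delta = c(0, 0), m0 = 1000,
                       cavity = 2.5 * m0, background = 0.25 * m0,
                       edge_mm = 2) {
  n <- geo$n
  px <- geo$pixel_mm
  coords <- (seq_len(n) - (n + 1) / 2) * px
  X <- matrix(coords, n, n) - geo$center[1] - delta[1]
  Y <- matrix(coords, n, n, byrow = TRUE) - geo$center[2] - delta[2]
  r <- sqrt(X^2 + Y^2)
  ramp <- function(u) pmin(pmax(u, 0), 1)         # linear edge ramp
  w <- edge_mm
  img <- cavity +
    (m0 - cavity) * ramp((r - (geo$r_endo - w / 2)) / w) +
    (background - m0) * ramp((r - (geo$r_epi - w / 2)) / w)
  for (b in seq_len(nrow(.asl_texture))) {
    bx <- .asl_texture[b, "radius"] * cos(.asl_texture[b, "angle"])
    by <- .asl_texture[b, "radius"] * sin(.asl_texture[b, "angle"])
    img <- img + .asl_texture[b, "amp"] * m0 *
      exp(-((X - bx)^2 + (Y - by)^2) / (2 * .asl_texture[b, "sigma"]^2))
  }
  img
}

.asl_ring_at <- function(geo, delta = c(0, 0)) {
  n <- geo$n
  px <- geo$pixel_mm
  coords <- (seq_len(n) - (n + 1) / 2) * px
  X <- matrix(coords, n, n)
  Y <- matrix(coords, n, n, byrow = TRUE)
  r2 <- (X - geo$center[1] - delta[1])^2 + (Y - geo$center[2] - delta[2])^2
  r2 >= geo$r_endo^2 & r2 <= geo$r_epi^2
}

#' Simulate a FAIR-ASL image series
#'
#' Forward model of the single-TI FAIR experiment over an annular myocardium:
#' the control image carries the equilibrium scene; the tagged image differs
#' by the perfusion signal `2 * M0 * TI * exp(-TI / T1) * MBF / 60000` on the
#' myocardial ring (TI = R-R interval, T1 of blood). Motion enters as a rigid
#' in-plane displacement drawn independently per acquired image with standard
#' deviation `motion_amplitude * acquisition_window / reference_window`
#' (motion during a longer readout leaves larger control/tag inconsistencies
#' — the physiological-noise mechanism); thermal noise is additive Gaussian
#' with `thermal_sd * sqrt(sense_factor)`. The first breath-hold contributes
#' a noise-free baseline (M0 surrogate) and pure thermal-noise images.
#'
#' With zero motion and zero thermal noise, quantification inverts this model
#' exactly.
#'
#' @param protocol An [asl_protocol()].
#' @param truth An [asl_truth()].
#' @param geometry An [asl_ring_geometry()].
#' @param n_noise Number of noise images.
#' @param m0 Myocardial equilibrium signal (scene units).
#' @param constants [blood_constants()] (supplies T1 of blood).
#' @return Object of class `asl_series`: `baseline`, `noise_images`
#'   (n x n x n_noise), `controls` and `tagged` (n x n x n_pairs), plus the
#'   protocol, geometry and truth.
#' @export
simulate_asl_series <- function(protocol, truth = asl_truth(),
                                geometry = asl_ring_geometry(),
                                n_noise = 6L, m0 = 1000,
                                constants = blood_constants()) {
  if (!any(geometry$mask)) stop("myocardial mask is empty")
  ti <- protocol$rr_interval
  baseline0 <- .asl_scene(geometry, m0 = m0)
  # the perfusion signal scales with the same M0 surrogate the quantifier
  # reads off the baseline: the mean myocardial baseline signal
  m0_eff <- mean(baseline0[geometry$mask])
  dm <- 2 * m0_eff * ti * exp(-ti / constants$t1_blood) *
    truth$mbf_true / 60000 / constants$partition_coefficient
  # motion scale is anchored to the reference readout (96 lines at TR 3.2 ms)
  ref_window <- 307
  motion_sd <- truth$motion_amplitude * acquisition_window(protocol) / ref_window
  noise_sd <- truth$thermal_sd * sqrt(protocol$sense_factor)
  n <- geometry$n
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(truth$seed)
  baseline <- baseline0
  noise_images <- array(stats::rnorm(n * n * n_noise, 0, noise_sd),
                        dim = c(n, n, n_noise))
  controls <- array(0, dim = c(n, n, protocol$n_pairs))
  tagged <- array(0, dim = c(n, n, protocol$n_pairs))
  for (k in seq_len(protocol$n_pairs)) {
    d_c <- stats::rnorm(2, 0, motion_sd)
    d_t <- stats::rnorm(2, 0, motion_sd)
    controls[, , k] <- .asl_scene(geometry, d_c, m0 = m0) +
      stats::rnorm(n * n, 0, noise_sd)
    tagged[, , k] <- .asl_scene(geometry, d_t, m0 = m0) -
      dm * .asl_ring_at(geometry, d_t) + stats::rnorm(n * n, 0, noise_sd)
  }
  structure(list(baseline = baseline, noise_images = noise_images,
                 controls = controls, tagged = tagged,
                 protocol = protocol, geometry = geometry, truth = truth,
                 m0_scene = m0, constants = constants),
            class = "asl_series")
}

#' @export
print.asl_series <- function(x, ...) {
  cat("asl_series: ", x$geometry$n, "x", x$geometry$n, " px, ",
      x$protocol$n_pairs, " control/tag pairs, ",
      dim(x$noise_images)[3], " noise images\n", sep = "")
  cat(sprintf("  acquisition window %d ms (R=%d), TI = R-R = %.0f ms\n",
              acquisition_window(x$protocol), x$protocol$sense_factor,
              x$protocol$rr_interval))
  cat(sprintf("  truth: MBF %.2f ml/g/min, motion %.3f mm, thermal sd %.1f\n",
              x$truth$mbf_true, x$truth$motion_amplitude, x$truth$thermal_sd))
  invisible(x)
}

#' Write / read an ASL series as NIfTI stacks + JSON sidecar
#'
#' Images go into one 3-D stack per role (`baseline`, `noise`, `controls`,
#' `tagged`); protocol and geometry go into `series.json`. The ground truth
#' is withheld in a separate `truth.json` for blinded testing.
#'
#' @param series An `asl_series`.
#' @param dir Output directory.
#' @return `dir` / the series.
#' @export
write_asl_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(a, f) RNifti::writeNifti(RNifti::asNifti(a),
                                          file.path(dir, f), datatype = "double")
  wr(series$baseline, "baseline.nii.gz")
  wr(series$noise_images, "noise.nii.gz")
  wr(series$controls, "controls.nii.gz")
  wr(series$tagged, "tagged.nii.gz")
  g <- series$geometry
  jsonlite::write_json(list(protocol = unclass(series$protocol),
                            geometry = list(n = g$n, fov = g$n * g$pixel_mm,
                                            r_endo = g$r_endo, r_epi = g$r_epi,
                                            center = g$center),
                            m0_scene = series$m0_scene),
                       file.path(dir, "series.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(unclass(series$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_asl_series
#' @export
read_asl_series <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "series.json"),
                              simplifyVector = TRUE)
  pr <- do.call(asl_protocol, meta$protocol)
  g <- meta$geometry
  geometry <- asl_ring_geometry(n = g$n, fov = g$fov, r_endo = g$r_endo,
                                r_epi = g$r_epi, center = g$center)
  rd <- function(f) {
    img <- RNifti::readNifti(file.path(dir, f))
    array(as.numeric(img), dim = dim(img))
  }
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    tl <- jsonlite::read_json(tf, simplifyVector = TRUE)
    truth <- do.call(asl_truth, tl)
  }
  structure(list(baseline = rd("baseline.nii.gz"),
                 noise_images = rd("noise.nii.gz"),
                 controls = rd("controls.nii.gz"), tagged = rd("tagged.nii.gz"),
                 protocol = pr, geometry = geometry, truth = truth,
                 m0_scene = meta$m0_scene, constants = blood_constants()),
            class = "asl_series")
}
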