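# Shared phantom fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, .fixture_cache)) assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

lv_phantom_default <- function() {
  cached("lv_default", function()
    make_lv_phantom(phantom_params(), ground_truth = FALSE))
}

# default-phantom pathlines, traced + QC + classified (no E/A split)
lv_pathlines_default <- function() {
  cached("lv_ps", function() {
    ph <- lv_phantom_default()
    ps <- trace_cycle(ph$field, ph$geometry)
    classify_pathlines(qc_pathlines(ps, ph$geometry)$pathlines, ph$geometry)
  })
}

duct_default <- function() {
  cached("duct", function() make_duct_phantom(v = 0.1))
}

rotation_default <- function() {
  cached("rotation", function() make_rotation_phantom(omega = 8))
}

# noise-free ASL series at the reference protocol
asl_clean <- function() {
  cached("asl_clean", function()
    simulate_asl_series(asl_protocol(),
                        asl_truth(mbf_true = 1.20, motion_amplitude = 0,
                                  thermal_sd = 0)))
}
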