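#' Cine phase-contrast sequence parameters
#'
#' @param tr Repetition time, ms.
#' @param k_seg k-space segmentation factor (lines per cardiac phase per
#'   heartbeat).
#' @param n_encodes Velocity-encoding acquisitions per k-space line; 4 for
#'   three-directional encoding (one reference plus three encoded).
#' @return Object of class `flow_seq_params`.
#' @export
flow_seq_params <- function(tr = 6.3, k_seg = 2L, n_encodes = 4L) {
  stopifnot(tr > 0, k_seg >= 1, n_encodes >= 1)
  structure(list(tr = tr, k_seg = as.integer(k_seg),
                 n_encodes = as.integer(n_encodes)),
            class = "flow_seq_params")
}

#' Temporal resolution of a segmented cine phase-contrast acquisition
#'
#' One reconstructed cardiac phase takes `n_encodes * k_seg * tr`
#' milliseconds: every k-space segment is acquired once per velocity
#' encoding.
#'
#' @param params [flow_seq_params()].
#' @return Temporal resolution, ms.
#' @examples
#' temporal_resolution(flow_seq_params(tr = 6.3, k_seg = 2, n_encodes = 4))  # 50.4
#' @export
temporal_resolution <- function(params = flow_seq_params()) {
  params$n_encodes * params$k_seg * params$tr
}

#' k-space coverage arithmetic for a segmented acquisition
#'
#' How many cardiac cycles a full k-space pass needs when `lines_per_cycle`
#' lines are acquired per heartbeat (ceiling on indivisible counts), and the
#' implied duration if the R-R interval is given. Navigator efficiency and
#' arrhythmia rejection are patient-dependent and deliberately excluded.
#'
#' @param n_lines Total k-space lines (> 0).
#' @param lines_per_cycle Lines acquired per cardiac cycle (> 0).
#' @param rr_interval Optional R-R interval, ms.
#' @return List with `lines_per_cycle`, `cycles_needed` and (if `rr_interval`
#'   is given) `duration_s`.
#' @export
kspace_acq_time <- function(n_lines, lines_per_cycle, rr_interval = NULL) {
  if (n_lines <= 0) stop("n_lines must be positive")
  if (lines_per_cycle <= 0) stop("lines_per_cycle must be positive")
  cycles <- as.integer(ceiling(n_lines / lines_per_cycle))
  out <- list(lines_per_cycle = lines_per_cycle, cycles_needed = cycles)
  if (!is.null(rr_interval)) out$duration_s <- cycles * rr_interval / 1000
  out
}
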