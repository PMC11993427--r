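#' Cohort-level summary of analysis results
#'
#' Mean and standard deviation per metric over a list of results
#' (`component_result` / `lv_flow` or `mbf_fit`), and — when a paired second
#' list is given (e.g. reference-method vs accelerated-method MBF fits from
#' the same subjects) — a paired two-sided t-test per metric. By convention a
#' zero-variance set of differences reports p = 1 when the mean difference is
#' zero (identical methods) and p = 0 otherwise.
#'
#' @param results List of `component_result`, `lv_flow` or `mbf_fit` objects
#'   (at least 2 for dispersion).
#' @param paired Optional list of the same length and type for a paired
#'   comparison.
#' @return data.frame with `metric`, `n`, `mean`, `sd` (and `mean_paired`,
#'   `mean_diff`, `p_value` if `paired` is given).
#' @export
summarize_cohort <- function(results, paired = NULL) {
  if (length(results) < 2) stop("need at least 2 results for dispersion")
  met <- lapply(results, .result_metrics)
  nm <- names(met[[1]])
  if (!all(vapply(met, function(m) identical(names(m), nm), logical(1))))
    stop("results are not of one type")
  M <- do.call(rbind, met)
  out <- data.frame(metric = nm, n = nrow(M),
                    mean = colMeans(M), sd = apply(M, 2, stats::sd),
                    row.names = NULL)
  if (!is.null(paired)) {
    if (length(paired) != length(results))
      stop("paired results must match the reference results one-to-one")
    met2 <- lapply(paired, .result_metrics)
    if (!all(vapply(met2, function(m) identical(names(m), nm), logical(1))))
      stop("paired results are not of the same type as the reference results")
    M2 <- do.call(rbind, met2)
    d <- M - M2
    out$mean_paired <- colMeans(M2)
    out$mean_diff <- colMeans(d)
    out$p_value <- vapply(seq_along(nm), function(j) {
      dj <- d[, j]
      if (stats::sd(dj) == 0) return(if (mean(dj) == 0) 1 else 0)
      stats::t.test(dj)$p.value
    }, numeric(1))
  }
  out
}

.result_metrics <- function(x) {
  if (inherits(x, "lv_flow")) x <- component_result(x)
  if (inherits(x, "component_result")) {
    v <- x$volumes_ml
    out <- c(v, edv_ml = x$edv_ml, inflow_ml = x$inflow_ml,
             ejected_ml = x$ejected_ml,
             direct_to_inflow = unname(v["direct"]) /
               (unname(v["direct"]) + unname(v["retained_inflow"])))
    names(out)[seq_along(v)] <- paste0(names(v), "_ml")
    return(out)
  }
  if (inherits(x, "mbf_fit"))
    return(c(global_mbf = x$global_mbf, pn = x$pn, tn = x$tn))
  stop("unsupported result type: ", paste(class(x), collapse = "/"))
}
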