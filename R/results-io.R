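#' Write an analysis result to disk
#'
#' `component_result` objects go to CSV (deterministic column order, units in
#' the headers: `component`, `volume_ml`, `ke_ed_uJ_per_ml`, followed by
#' `#`-prefixed summary lines are avoided — summary quantities are written as
#' extra rows with component names `edv`, `inflow`, `ejected`,
#' `direct_early`, `direct_late`). `mbf_fit` objects go to JSON with keys
#' `global_mbf`, `regional_mbf` (6), `septal_mbf` (3), `per_pair_mbf`, `pn`,
#' `tn` (all ml/g/min).
#'
#' @param result A `component_result` or `mbf_fit`.
#' @param path Output path (`.csv` / `.json`).
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  UseMethod("write_results")
}

#' @export
write_results.component_result <- function(result, path) {
  ke <- result$ke_per_ml_at_ed_uJ[names(result$volumes_ml)]
  df <- data.frame(component = names(result$volumes_ml),
                   volume_ml = unname(result$volumes_ml),
                   ke_ed_uJ_per_ml = unname(ke))
  extra <- data.frame(
    component = c("edv", "inflow", "ejected"),
    volume_ml = c(result$edv_ml, result$inflow_ml, result$ejected_ml),
    ke_ed_uJ_per_ml = NA_real_)
  if (!is.null(result$direct_flow_split))
    extra <- rbind(extra, data.frame(
      component = c("direct_early", "direct_late"),
      volume_ml = unname(result$direct_flow_split$split$direct),
      ke_ed_uJ_per_ml = NA_real_))
  utils::write.csv(rbind(df, extra), path, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.mbf_fit <- function(result, path) {
  jsonlite::write_json(list(global_mbf = result$global_mbf,
                            regional_mbf = result$regional_mbf,
                            septal_mbf = result$septal_mbf,
                            per_pair_mbf = result$per_pair_mbf,
                            pn = result$pn, tn = result$tn,
                            units = "ml/g/min"),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_results
#' @param type `"component"` or `"mbf"`; inferred from the file extension by
#'   default (`.csv` = component, `.json` = mbf).
#' @export
read_results <- function(path, type = NULL) {
  if (is.null(type))
    type <- if (grepl("\\.json$", path)) "mbf" else "component"
  if (type == "component") {
    df <- utils::read.csv(path)
    comp <- df[df$component %in% COMPONENTS, ]
    getrow <- function(k) df$volume_ml[df$component == k]
    split <- NULL
    if ("direct_early" %in% df$component)
      split <- list(split = list(direct = c(early = getrow("direct_early"),
                                            late = getrow("direct_late"))))
    structure(list(volumes_ml = stats::setNames(comp$volume_ml, comp$component),
                   ke_per_ml_at_ed_uJ = stats::setNames(comp$ke_ed_uJ_per_ml,
                                                        comp$component),
                   edv_ml = getrow("edv"), inflow_ml = getrow("inflow"),
                   ejected_ml = getrow("ejected"), direct_flow_split = split),
              class = "component_result")
  } else {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    structure(list(global_mbf = x$global_mbf,
                   regional_mbf = as.numeric(x$regional_mbf),
                   septal_mbf = as.numeric(x$septal_mbf),
                   per_pair_mbf = as.numeric(x$per_pair_mbf),
                   pn = x$pn, tn = x$tn), class = "mbf_fit")
  }
}
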