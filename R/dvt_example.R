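#' Published per-cluster estimates for the DVT worked example
#'
#' Per-cluster regression coefficients (with SEs) of a three-predictor
#' diagnostic model for deep vein thrombosis — history of malignancy, calf
#' circumference difference >= 3 cm, recent surgery — estimated with
#' Firth's correction in each of 11 diagnostic studies, and the matching
#' internal-external cross-validation performance estimates (calibration
#' slope, calibration-in-the-large and c-statistic per hold-out cluster).
#' These are the published per-cluster values, shipped so the worked
#' example (pooling them by random-effects meta-analysis) runs without
#' access to the restricted participant-level data.
#'
#' @return data.frame with one row per cluster; estimate and `_se` column
#'   pairs per quantity.
#' @examples
#' tab <- dvt_cluster_coefficients()
#' pool(tab$malignancy, tab$malignancy_se, method = "DL")
#' @export
dvt_cluster_coefficients <- function() {
  utils::read.csv(system.file("extdata", "dvt_cluster_coefficients.csv",
                              package = "siecv"),
                  check.names = FALSE)
}

#' @rdname dvt_cluster_coefficients
#' @export
dvt_iecv_performance <- function() {
  utils::read.csv(system.file("extdata", "dvt_iecv_performance.csv",
                              package = "siecv"),
                  check.names = FALSE)
}
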