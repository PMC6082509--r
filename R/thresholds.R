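#' KDIGO creatinine thresholds used for AKI ascertainment
#'
#' Bundles the creatinine-based detection constants: a community-acquired (CA)
#' AKI flag at admission when admission creatinine is at least
#' `ratio_threshold` times the pre-admission baseline (or exceeds
#' `absolute_level` when no baseline exists), and a hospital-acquired (HA) AKI
#' flag when, within the first `horizon` hours of admission, a measurement
#' rises to at least `ratio_threshold` times the admission value or by at
#' least `absolute_rise` above the minimum observed in the trailing `window`
#' hours. Severity staging uses `stage2_ratio` and `stage3_ratio` bands.
#'
#' @param ratio_threshold Ratio of creatinine to reference defining AKI
#'   (dimensionless, default 1.5).
#' @param absolute_rise Rise within the rolling window defining AKI
#'   (micromol/l, default 26.5).
#' @param absolute_level Absolute creatinine defining CA-AKI when no baseline
#'   is available (micromol/l, default 354).
#' @param window Rolling window for the absolute-rise rule (hours, default 48).
#' @param horizon Detection horizon after admission for HA-AKI (hours,
#'   default 168, i.e. seven days).
#' @param stage2_ratio,stage3_ratio Ratio-to-reference bounds for KDIGO
#'   stages 2 and 3 (defaults 2 and 3).
#'
#' @return An object of class `aki_thresholds` (a named list).
#' @examples
#' aki_thresholds()
#' @export
aki_thresholds <- function(ratio_threshold = 1.5, absolute_rise = 26.5,
                           absolute_level = 354, window = 48, horizon = 168,
                           stage2_ratio = 2, stage3_ratio = 3) {
  th <- list(
    ratio_threshold = ratio_threshold, absolute_rise = absolute_rise,
    absolute_level = absolute_level, window = window, horizon = horizon,
    stage2_ratio = stage2_ratio, stage3_ratio = stage3_ratio
  )
  if (any(vapply(th, function(x) !is.numeric(x) || length(x) != 1 || x <= 0,
                 logical(1)))) {
    stop("all thresholds must be single positive numbers", call. = FALSE)
  }
  if (th$window > th$horizon) stop("window must not exceed horizon", call. = FALSE)
  structure(th, class = "aki_thresholds")
}
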