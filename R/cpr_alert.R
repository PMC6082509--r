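#' Load a clinical-prediction-rule weight table
#'
#' The score is a sum of integer points over satisfied conditions, each
#' condition comparing one admission-record field against a threshold. The
#' table is declarative: columns `predictor` (an admission field), `op`
#' (one of `ge`, `gt`, `le`, `lt`, `eq`, `true`), `threshold` (numeric;
#' ignored for `true`) and `points` (non-negative integer).
#'
#' The packaged default (`aps_weights_synthetic.csv`) is a synthetic stand-in
#' for the published risk-score weightings, which are not reproduced here; it
#' uses the score's documented predictor families (age, chronic kidney
#' disease and other comorbidity, tachypnoea, reduced consciousness, early
#' warning score) with points calibrated once so that roughly a quarter of
#' simulated admissions reach the default cut-off of 5. Replace it with a
#' validated table for real use.
#'
#' @param path CSV path; defaults to the packaged synthetic table.
#' @return Data frame of class `aps_weights` with attribute `cutoff` (5).
#' @export
aps_weights <- function(path = system.file("extdata",
                                           "aps_weights_synthetic.csv",
                                           package = "akiimpact")) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("predictor", "op", "threshold", "points")
  if (!all(required %in% names(w))) {
    stop("weight table needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (any(w$points < 0) || any(w$points != round(w$points))) {
    stop("points must be non-negative integers", call. = FALSE)
  }
  bad <- setdiff(w$op, c("ge", "gt", "le", "lt", "eq", "true"))
  if (length(bad)) stop("unknown comparator(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(w, class = c("aps_weights", "data.frame"), cutoff = 5L)
}

#' Compute the AKI prediction score for each admission
#'
#' Deterministic additive score: for every weight-table row whose condition
#' holds on an admission, its points are added. Order of the weight rows is
#' immaterial. Missing values in a referenced predictor are an error — the
#' score is defined at admission, when all fields are observed.
#'
#' @param admissions Data frame of admissions (one row each).
#' @param weights An [aps_weights()] table (or any data frame with the same
#'   columns).
#' @return Integer score vector, one per admission.
#' @examples
#' w <- data.frame(predictor = c("age", "ckd"), op = c("ge", "true"),
#'                 threshold = c(65, NA), points = c(3L, 2L))
#' compute_aps(data.frame(age = 70, ckd = TRUE), w)
#' @export
compute_aps <- function(admissions, weights) {
  score <- rep(0L, nrow(admissions))
  for (i in seq_len(nrow(weights))) {
    f <- weights$predictor[i]
    if (!f %in% names(admissions)) {
      stop("weight table references unknown field: ", f, call. = FALSE)
    }
    x <- admissions[[f]]
    if (anyNA(x)) stop("missing values in predictor: ", f, call. = FALSE)
    hit <- switch(weights$op[i],
                  ge = x >= weights$threshold[i],
                  gt = x > weights$threshold[i],
                  le = x <= weights$threshold[i],
                  lt = x < weights$threshold[i],
                  eq = x == weights$threshold[i],
                  true = as.logical(x),
                  stop("unknown comparator: ", weights$op[i], call. = FALSE))
    score <- score + as.integer(hit) * as.integer(weights$points[i])
  }
  as.integer(score)
}

#' Assign RED/AMBER/GREEN alert states
#'
#' RED flags AKI (community-acquired at admission, or hospital-acquired at
#' onset); AMBER flags an at-risk score at or above the cut-off; GREEN is
#' everything else. With `at = "admission"` only CA-AKI can be RED (the state
#' as first shown); with `at = "final"` (default) admissions that later
#' develop HA-AKI are RED too — states only ever escalate, never de-escalate.
#'
#' @param aps Integer score vector (>= 0).
#' @param category AKI category per admission: "none", "CA" or "HA".
#' @param cutoff At-risk cut-off on the score (default 5).
#' @param at "final" or "admission".
#' @return Data frame with columns `state` (factor GREEN < AMBER < RED) and
#'   `reason` ("none", "aps_at_risk", "ca_aki", "ha_aki").
#' @examples
#' assign_state(c(5L, 4L, 2L), c("none", "none", "CA"))
#' @export
assign_state <- function(aps, category, cutoff = 5L,
                         at = c("final", "admission")) {
  at <- match.arg(at)
  if (any(aps < 0)) stop("scores must be non-negative", call. = FALSE)
  stopifnot(length(aps) == length(category))
  red <- if (at == "admission") !is.na(category) & category == "CA"
         else !is.na(category) & category != "none"
  reason <- ifelse(red, ifelse(category == "CA", "ca_aki", "ha_aki"),
                   ifelse(aps >= cutoff, "aps_at_risk", "none"))
  state <- factor(ifelse(red, "RED",
                         ifelse(aps >= cutoff, "AMBER", "GREEN")),
                  levels = c("GREEN", "AMBER", "RED"), ordered = TRUE)
  data.frame(state = state, reason = reason)
}

#' Care-bundle compliance proportions by alert class
#'
#' Completion of the suggested care bundle is tracked per alerted admission;
#' compliance is reported as the percentage of RED (AKI) admissions with a
#' submitted complete bundle, and of all flagged admissions (AMBER or RED).
#'
#' @param alerted Data frame with columns `admission_id` and `state`.
#' @param submitted Character vector of admission ids with a complete bundle
#'   submission; must be a subset of the AMBER/RED admissions.
#' @return List with `red_pct` and `flagged_pct` (percentages; `NA` when the
#'   denominator is empty) plus the underlying counts.
#' @export
bundle_compliance <- function(alerted, submitted) {
  stopifnot(all(c("admission_id", "state") %in% names(alerted)))
  red_ids <- alerted$admission_id[alerted$state == "RED"]
  amb_ids <- alerted$admission_id[alerted$state == "AMBER"]
  flagged <- c(red_ids, amb_ids)
  bad <- setdiff(submitted, flagged)
  if (length(bad)) {
    stop("bundle submitted for non-alerted admission(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(
    red_pct = pct(sum(submitted %in% red_ids), length(red_ids)),
    flagged_pct = pct(length(submitted), length(flagged)),
    n_red = length(red_ids), n_flagged = length(flagged),
    n_submitted = length(submitted)
  )
}
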