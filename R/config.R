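#' DEA solver configuration
#'
#' @param returns_to_scale `"constant"` (the CCR model; the default and the
#'   model used throughout the bundled analyses) or `"variable"` (BCC; adds
#'   the convexity constraint `sum(lambda) = 1`).
#' @param orientation only `"input"` is implemented: efficiency is the
#'   maximal equiproportional contraction of inputs at fixed outputs.
#' @param solver_tolerance numerical tolerance used by the LP solver and when
#'   snapping near-1 scores to the frontier.
#' @param lambda_peer_cutoff intensity weights above this value mark a unit as
#'   a peer.
#' @param score_decimals decimals used when reporting scores (internal
#'   arithmetic is always full precision).
#' @return a list of class `dea_config`.
#' @export
dea_config <- function(returns_to_scale = c("constant", "variable"),
                       orientation = "input",
                       solver_tolerance = 1e-9,
                       lambda_peer_cutoff = 1e-6,
                       score_decimals = 3L) {
  returns_to_scale <- match.arg(returns_to_scale)
  orientation <- match.arg(orientation, "input")
  stopifnot(solver_tolerance > 0, lambda_peer_cutoff > 0,
            score_decimals >= 0)
  structure(
    list(returns_to_scale = returns_to_scale,
         orientation = orientation,
         solver_tolerance = solver_tolerance,
         lambda_peer_cutoff = lambda_peer_cutoff,
         score_decimals = as.integer(score_decimals)),
    class = "dea_config"
  )
}

#' Saturation / untapped-capacity thresholds
#'
#' The benchmarking thresholds used to classify DMU scores: units above
#' `saturation` are considered saturated (operating at or over capacity),
#' units at or below `untapped` have untapped operational capacity. The
#' defaults are the highest (0.82) and lowest (0.22) institutional average
#' efficiencies observed in the bundled 2012-2018 Mexican obstetric-care
#' panel.
#'
#' @param saturation upper threshold (strict: classified saturated only when
#'   the score exceeds it).
#' @param untapped lower threshold (inclusive: a score equal to it is
#'   classified untapped).
#' @return a list of class `dea_thresholds`.
#' @export
dea_thresholds <- function(saturation = 0.82, untapped = 0.22) {
  if (!(untapped > 0 && untapped < saturation && saturation < 1)) {
    stop("need 0 < untapped < saturation < 1", call. = FALSE)
  }
  structure(list(saturation = saturation, untapped = untapped),
            class = "dea_thresholds")
}
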