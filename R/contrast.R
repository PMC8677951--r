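#' ON/OFF state pair of a molecular NLO switch
#'
#' Bundles the \eqn{\beta_{HRS}} responses of the two states of a switch.
#' The OFF state is assigned by chemical role (for hexaphyrin switches the
#' antiaromatic `28R` conformer, whose centrosymmetry typically forces
#' \eqn{\beta_{HRS} \approx 0}), never by magnitude: when the nominal OFF
#' state outshines the ON state the contrast functions report a reversal
#' instead of silently relabelling.
#'
#' @param beta_on,beta_off \eqn{\beta_{HRS}} of the ON / OFF state (a.u., >= 0)
#' @param on_label,off_label state identifiers (e.g. `"26R"`, `"28M"`; OFF is
#'   `"28R"` by convention)
#' @param frequency photon energy tag in eV
#' @return an object of class `switch_pair`.
#' @export
switch_pair <- function(beta_on, beta_off, on_label = "26R",
                        off_label = "28R", frequency = 0) {
  for (v in list(beta_on, beta_off)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("beta values must be single finite numbers", call. = FALSE)
    }
    if (v < 0) stop("beta_HRS values must be non-negative", call. = FALSE)
  }
  structure(list(beta_on = as.double(beta_on), beta_off = as.double(beta_off),
                 on_label = on_label, off_label = off_label,
                 frequency = frequency),
            class = "switch_pair")
}

#' Ratio-based NLO switch contrast
#'
#' \eqn{\mathrm{contrast} = \beta_{HRS}(\mathrm{ON}) /
#' \beta_{HRS}(\mathrm{OFF})}. A (near-)centrosymmetric OFF state drives the
#' denominator to zero, so the ratio is regularized: when
#' \eqn{\beta_{HRS}(\mathrm{OFF})} falls below `clamp_threshold` the
#' denominator is replaced by `clamp_value` (defaults 10 a.u. and 0.001 a.u.).
#'
#' @param pair a [switch_pair()]
#' @param clamp_threshold OFF-state beta below which the clamp fires (a.u.)
#' @param clamp_value replacement denominator when clamped (a.u.)
#' @return list with `ratio` and logical `clamped`.
#' @examples
#' ratio_contrast(switch_pair(2347, 0))$ratio # 2.347e6
#' @export
ratio_contrast <- function(pair, clamp_threshold = 10, clamp_value = 0.001) {
  stopifnot(inherits(pair, "switch_pair"))
  clamped <- pair$beta_off < clamp_threshold
  denom <- if (clamped) clamp_value else pair$beta_off
  list(ratio = pair$beta_on / denom, clamped = clamped)
}

#' Difference-based NLO switch contrast
#'
#' \eqn{\mathrm{contrast} = \beta_{HRS}(\mathrm{ON}) -
#' \beta_{HRS}(\mathrm{OFF})}; needs no regularization and may be negative
#' when the ON/OFF roles have effectively reversed.
#'
#' @param pair a [switch_pair()]
#' @return the difference in a.u.
#' @export
difference_contrast <- function(pair) {
  stopifnot(inherits(pair, "switch_pair"))
  pair$beta_on - pair$beta_off
}

#' Evaluate both switch-contrast figures of merit
#'
#' Computes the ratio and difference contrasts for a state pair and marks one
#' of them (the `objective`) as the value an optimizer should maximize.
#'
#' @param pair a [switch_pair()]
#' @param objective `"ratio"` or `"difference"`
#' @param clamp_threshold,clamp_value see [ratio_contrast()]
#' @return an object of class `contrast_result`: list with `ratio`,
#'   `difference`, `clamped`, `reversed`, `objective`, `objective_value`.
#' @export
evaluate_switch <- function(pair, objective = c("ratio", "difference"),
                            clamp_threshold = 10, clamp_value = 0.001) {
  objective <- match.arg(objective)
  rc <- ratio_contrast(pair, clamp_threshold, clamp_value)
  dc <- difference_contrast(pair)
  structure(list(ratio = rc$ratio,
                 difference = dc,
                 clamped = rc$clamped,
                 reversed = dc < 0,
                 objective = objective,
                 objective_value = if (objective == "ratio") rc$ratio else dc,
                 pair = pair),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("switch %s (ON, beta = %g a.u.) / %s (OFF, beta = %g a.u.)\n",
              x$pair$on_label, x$pair$beta_on,
              x$pair$off_label, x$pair$beta_off))
  cat(sprintf("  ratio = %.4g%s   difference = %.4g a.u.%s\n",
              x$ratio, if (x$clamped) " [clamped]" else "",
              x$difference, if (x$reversed) " [ON/OFF reversed]" else ""))
  invisible(x)
}

#' Correlation between the two contrast definitions
#'
#' Ordinary-least-squares \eqn{R^2} of the difference contrast regressed on
#' the ratio contrast (with intercept), as in a standard correlation plot of
#' the two figures of merit. For switches whose OFF state is centrosymmetric
#' (stored \eqn{\beta_{HRS}=0}), the clamp makes ratio = difference /
#' `clamp_value` exactly, so the fit is exactly linear with \eqn{R^2 = 1}.
#'
#' @param ratio,difference numeric vectors of equal length (>= 2 points)
#' @return the \eqn{R^2} of the fit.
#' @export
contrast_correlation <- function(ratio, difference) {
  if (length(ratio) != length(difference)) {
    stop("`ratio` and `difference` must have equal length", call. = FALSE)
  }
  if (length(ratio) < 2L) {
    stop("at least 2 points are required", call. = FALSE)
  }
  if (stats::var(ratio) == 0 || stats::var(difference) == 0) {
    stop("zero variance: R^2 undefined", call. = FALSE)
  }
  fit <- stats::lm(difference ~ ratio)
  # R^2 from the sums of squares directly (summary.lm warns on perfect fits)
  1 - sum(stats::resid(fit)^2) / sum((difference - mean(difference))^2)
}
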