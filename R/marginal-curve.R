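#' Construct a mono-therapy (marginal) concentration-response curve
#'
#' A four-parameter log-logistic (4PLL) curve describing the readout of a
#' single compound as a function of its concentration,
#' \deqn{R(c) = b + (m - b) \, o(c), \qquad
#'       o(c) = \frac{1}{1 + (i/c)^{h}},}
#' where `o(c)` is the occupancy — the fraction of (virtual) enzyme bound by
#' the compound. The baseline `b` is the readout of the untreated system and
#' is shared by all compounds measured in the same assay; `m` is the maximal
#' effect, `ec50` the half-maximally effective concentration and `hill` the
#' cooperativity coefficient.
#'
#' `m` may exceed `b` (full or partial agonist), fall below it (inverse
#' agonist) or equal it (neutral antagonist: the compound occupies the
#' binding site without changing the readout).
#'
#' @param b Baseline readout at zero concentration (readout units).
#' @param m Maximal effect of the compound (readout units).
#' @param ec50 Half-maximally effective concentration; must be positive.
#' @param hill Hill (cooperativity) coefficient; must be positive.
#' @return An object of class `marginal_curve`.
#' @examples
#' crv <- marginal_curve(b = 0.1, m = 1, ec50 = 5, hill = 1.5)
#' readout(crv, 5)    # midpoint: b + (m - b)/2
#' @export
marginal_curve <- function(b, m, ec50, hill) {
  check_number(b, "b")
  check_number(m, "m")
  check_number(ec50, "ec50", min = 0, strict = TRUE)
  check_number(hill, "hill", min = 0, strict = TRUE)
  structure(list(b = b, m = m, ec50 = ec50, hill = hill),
            class = "marginal_curve")
}

#' @export
print.marginal_curve <- function(x, ...) {
  cat(sprintf(
    "4PLL marginal curve: b = %g, m = %g, ec50 = %g, hill = %g\n",
    x$b, x$m, x$ec50, x$hill))
  invisible(x)
}

#' Occupancy of a marginal curve at given concentrations
#'
#' Fraction of (virtual) enzyme bound by the compound:
#' `1 / (1 + (ec50/conc)^hill)`. Zero at `conc = 0`, strictly increasing,
#' always in `[0, 1)` for finite concentrations.
#'
#' @param curve A [marginal_curve()].
#' @param conc Vector of non-negative concentrations.
#' @return Occupancy values in `[0, 1)`.
#' @export
occupancy <- function(curve, conc) {
  stopifnot(inherits(curve, "marginal_curve"))
  if (!is.numeric(conc) || anyNA(conc) || any(conc < 0))
    stop_invalid("concentrations must be non-negative numbers")
  # plogis form of the Hill equation; log(0) = -Inf gives occupancy 0 exactly
  stats::plogis(curve$hill * (log(conc) - log(curve$ec50)))
}

#' Predicted readout of a marginal curve at given concentrations
#'
#' Evaluates the 4PLL readout `b + (m - b) * occupancy(curve, conc)`.
#' Equals `b` at zero concentration and tends to `m` at saturating
#' concentrations.
#'
#' @inheritParams occupancy
#' @return Readout values.
#' @export
readout <- function(curve, conc) {
  curve$b + (curve$m - curve$b) * occupancy(curve, conc)
}

#' Invert a marginal curve: concentration producing a given occupancy
#'
#' The inverse Hill relation `C(o) = ec50 * (1/o - 1)^(-1/hill)`. Only
#' occupancies strictly inside `(0, 1)` are invertible (the extremes are
#' reached only at zero or infinite concentration).
#'
#' @param curve A [marginal_curve()].
#' @param o Occupancy values strictly in `(0, 1)`.
#' @return Concentrations.
#' @export
conc_from_occupancy <- function(curve, o) {
  stopifnot(inherits(curve, "marginal_curve"))
  if (!is.numeric(o) || anyNA(o) || any(o <= 0 | o >= 1))
    stop_invalid("occupancy must lie strictly in (0, 1)")
  curve$ec50 * ((1 - o) / o)^(-1 / curve$hill)
}

#' Invert a marginal curve: concentration producing a given readout
#'
#' `C(r) = ec50 * ((m - b)/(r - b) - 1)^(-1/hill)`. The readout must lie
#' strictly between the baseline `b` and the maximal effect `m`; a flat
#' curve (`m == b`, a neutral antagonist) is not invertible.
#'
#' @param curve A [marginal_curve()].
#' @param r Readout values strictly between `b` and `m`.
#' @return Concentrations.
#' @export
conc_from_readout <- function(curve, r) {
  stopifnot(inherits(curve, "marginal_curve"))
  if (curve$m == curve$b)
    stop_invalid("curve is flat (m equals b): readout is not invertible")
  lo <- min(curve$b, curve$m); hi <- max(curve$b, curve$m)
  if (!is.numeric(r) || anyNA(r) || any(r <= lo | r >= hi))
    stop_invalid("readout must lie strictly between the baseline (",
                 curve$b, ") and the maximal effect (", curve$m, ")")
  # (m-b)/(r-b) - 1 rewritten as (m-r)/(r-b): exact near the asymptote
  curve$ec50 * ((curve$m - r) / (r - curve$b))^(-1 / curve$hill)
}

#' Variance-stabilizing transform for growth-type readouts
#'
#' Optional natural-log pre-processing applied to raw readouts before
#' marginal fitting, intended for growth or viability measurements whose
#' noise scales with the signal. Disabled it is the identity.
#'
#' @param effects Numeric vector of readouts.
#' @param enabled Apply the transform? When `TRUE` all readouts must be
#'   strictly positive.
#' @return Transformed (or unchanged) readouts.
#' @export
growth_transform <- function(effects, enabled = TRUE) {
  if (!is.numeric(effects) || anyNA(effects))
    stop_invalid("effects must be numeric and non-missing")
  if (!enabled) return(effects)
  if (any(effects <= 0))
    stop_invalid("growth transform requires strictly positive readouts")
  log(effects)
}
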