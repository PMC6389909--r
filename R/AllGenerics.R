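#' Fraction of unfolded protein implied by a curve fit
#'
#' Evaluates the fitted unfolding model at arbitrary temperatures. For a
#' [BoltzmannFit-class] this is \eqn{1/(1+\exp((T_m - T)/a))}; for a
#' [ThermoFit-class] it is \eqn{K_U(T)/(1+K_U(T))} with \eqn{K_U} from the
#' Gibbs-Helmholtz expression. Model output is clamped to [0, 1]. Either
#' way \code{fractionUnfolded(fit, Tm)} is exactly 0.5 at the fitted
#' midpoint.
#'
#' @param fit a [BoltzmannFit-class] or [ThermoFit-class].
#' @param temperature temperatures (deg C) at which to evaluate.
#' @param extrapolationMargin how far (deg C) beyond the fitted range the
#'   model may be evaluated before a warning is raised. Default 5.
#' @return numeric vector of fractions unfolded in [0, 1].
#' @examples
#' fit <- new("BoltzmannFit", Tm = 52.5, a = 1.5, mF = 0, bF = 0, mU = 0,
#'            bU = 1, residNorm = 0, converged = TRUE, tempRange = c(35, 65))
#' fractionUnfolded(fit, 52.5)  # 0.5
#' @export
setGeneric("fractionUnfolded",
    function(fit, temperature, extrapolationMargin = 5)
        standardGeneric("fractionUnfolded"))

#' Predicted raw signal of a curve fit
#'
#' Folded/unfolded dye baselines mixed by the model's fraction unfolded:
#' \eqn{Y(T) = (1-f_u)(m_F T + b_F) + f_u (m_U T + b_U)}.
#'
#' @inheritParams fractionUnfolded
#' @return numeric vector of predicted signal.
#' @export
setGeneric("predictSignal",
    function(fit, temperature) standardGeneric("predictSignal"))

#' Fitted melting midpoint on the Celsius scale
#'
#' @param fit a curve fit object.
#' @return midpoint temperature (deg C).
#' @export
setGeneric("meltingTemperature",
    function(fit) standardGeneric("meltingTemperature"))

#' @rdname MeltCurve-accessors
#' @export
setGeneric("temperatures", function(x) standardGeneric("temperatures"))

#' @rdname MeltCurve-accessors
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' @rdname MeltCurve-accessors
#' @export
setGeneric("ligandConc", function(x) standardGeneric("ligandConc"))

#' @rdname MeltCurve-accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
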