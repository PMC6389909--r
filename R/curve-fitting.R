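## Melt-curve models and their least-squares fitting.
##
## Two models for one well's fluorescence-vs-temperature trace:
##  * Boltzmann: empirical sigmoid f_u(T) = 1/(1+exp((Tm-T)/a)); midpoint
##    and normalization only.
##  * thermodynamic: two-state Gibbs-Helmholtz unfolding with fixed dCp;
##    dG_U(T) = dH_U (1 - T/Tm) - dCp (Tm - T + T ln(T/Tm)), K_U = e^{-dG/RT}.
## Raw signal mixes linear dye baselines by the fraction unfolded:
##    Y(T) = (1-f_u)(mF T + bF) + f_u (mU T + bU), T on the Celsius scale.

.boltzmannFu <- function(tempC, Tm, a) 1 / (1 + exp((Tm - tempC) / a))

.thermoKU <- function(tempK, TmK, dHU, dCpU) {
    dG <- dHU * (1 - tempK / TmK) -
        dCpU * (TmK - tempK + tempK * log(tempK / TmK))
    exp(-dG / (.RGAS * tempK))
}

.thermoFu <- function(tempC, TmK, dHU, dCpU) {
    ku <- .thermoKU(tempC + .C2K, TmK, dHU, dCpU)
    ku / (1 + ku)
}

.mixBaselines <- function(fu, tempC, mF, bF, mU, bU)
    (1 - fu) * (mF * tempC + bF) + fu * (mU * tempC + bU)

## Robust noise scale from lag-1 differences (transition contributes little
## because most points sit on the baselines).
.noiseScale <- function(signal)
    stats::median(abs(diff(signal))) / (0.6745 * sqrt(2))

.checkTransition <- function(curve, noiseFloor) {
    rng <- diff(range(curve@signal))
    floor <- max(noiseFloor, 5 * .noiseScale(curve@signal))
    if (rng <= floor || rng == 0)
        stop(structure(class = c("isoDSF_no_transition", "error",
                                 "condition"),
            list(message = sprintf(
                "no unfolding transition detected in '%s' (signal range %.3g <= noise floor %.3g)",
                curve@replicateId, rng, floor), call = NULL)))
    invisible(TRUE)
}

## Midpoint start from the steepest point of the trace (centred first
## derivative of a lightly smoothed signal, so point noise does not drown
## the transition), steepness start 1 degC, dH_U start 100 kcal/mol,
## baselines from straight lines through the first/last 15% of points.
.initCurve <- function(curve) {
    tp <- curve@temperature; y <- curve@signal; n <- length(tp)
    ## moving average over ~1.5 degC
    dT <- stats::median(diff(tp))
    k <- min(2L * as.integer(0.75 / dT) + 1L, 2L * (n %/% 10L) + 1L)
    ys <- if (k >= 3L) {
        sm <- stats::filter(y, rep(1 / k, k), sides = 2)
        ifelse(is.na(sm), y, as.numeric(sm))
    } else y
    slope <- (ys[-(1:2)] - ys[seq_len(n - 2)]) /
        (tp[-(1:2)] - tp[seq_len(n - 2)])
    Tm0 <- tp[which.max(slope) + 1L]
    k <- max(3L, round(0.15 * n))
    lo <- stats::lm.fit(cbind(1, tp[seq_len(k)]), y[seq_len(k)])$coefficients
    hi <- stats::lm.fit(cbind(1, tp[seq(n - k + 1L, n)]),
                        y[seq(n - k + 1L, n)])$coefficients
    list(Tm = Tm0, a = 1, dHU = 100,
         bF = unname(lo[1]), mF = unname(lo[2]),
         bU = unname(hi[1]), mU = unname(hi[2]))
}

.lmControl <- function()
    minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, maxfev = 5000)

.fitError <- function(curve, what) {
    stop(structure(class = c("isoDSF_fit_error", "error", "condition"),
        list(message = sprintf("fit of '%s' failed: %s",
                               curve@replicateId, what), call = NULL)))
}

#' Fit the Boltzmann sigmoid to one melt curve
#'
#' Least-squares fit of the empirical sigmoid (with linear dye baselines
#' when the curve is raw). The fitted \code{Tm} is the temperature at which
#' the normalized signal crosses 0.5.
#'
#' @param curve a [MeltCurve-class].
#' @param noiseFloor minimum signal range (absolute units) required to call
#'   a transition; in addition the range must exceed five times a robust
#'   noise estimate from lag-1 differences.
#' @param fitBaselines fit the four baseline parameters; defaults to
#'   \code{TRUE} for raw curves and \code{FALSE} for normalized ones (where
#'   the baselines are fixed at 0 and 1).
#' @return a [BoltzmannFit-class]. Non-convergence or a midpoint outside
#'   the observed range raises a classed error
#'   (\code{isoDSF_fit_error} / \code{isoDSF_no_transition}).
#' @examples
#' tp <- seq(40, 65, by = 0.25)
#' mc <- meltCurve(tp, 1 / (1 + exp((52.5 - tp) / 1.5)), normalized = TRUE)
#' fitBoltzmann(mc)
#' @export
fitBoltzmann <- function(curve, noiseFloor = 0,
                         fitBaselines = !isNormalized(curve)) {
    stopifnot(methods::is(curve, "MeltCurve"))
    .checkTransition(curve, noiseFloor)
    ini <- .initCurve(curve)
    tp <- curve@temperature; y <- curve@signal
    if (fitBaselines) {
        par0 <- c(Tm = ini$Tm, a = ini$a, mF = ini$mF, bF = ini$bF,
                  mU = ini$mU, bU = ini$bU)
        resid <- function(p) {
            fu <- .boltzmannFu(tp, p[1], p[2])
            y - .mixBaselines(fu, tp, p[3], p[4], p[5], p[6])
        }
        lower <- c(min(tp), 1e-6, rep(-Inf, 4))
        upper <- c(max(tp), Inf, rep(Inf, 4))
    } else {
        par0 <- c(Tm = ini$Tm, a = ini$a)
        resid <- function(p) y - .boltzmannFu(tp, p[1], p[2])
        lower <- c(min(tp), 1e-6)
        upper <- c(max(tp), Inf)
    }
    fit <- minpack.lm::nls.lm(par0, lower, upper, resid,
                              control = .lmControl())
    conv <- fit$info %in% 1:4
    if (!conv) .fitError(curve, fit$message)
    p <- fit$par
    bl <- if (fitBaselines) c(p[3], p[4], p[5], p[6]) else c(0, 0, 0, 1)
    methods::new("BoltzmannFit", Tm = unname(p[1]), a = unname(p[2]),
        mF = unname(bl[1]), bF = unname(bl[2]), mU = unname(bl[3]),
        bU = unname(bl[4]), residNorm = sqrt(fit$deviance),
        converged = conv, tempRange = range(tp))
}

#' Fit the two-state thermodynamic model to one melt curve
#'
#' Least-squares fit of the Gibbs-Helmholtz unfolding model with a fixed
#' heat-capacity change. Free parameters: \code{Tm}, \code{dHU} and (for
#' raw curves) the four baseline parameters. At the fitted \code{Tm} the
#' unfolding free energy is zero, so \eqn{K_U(T_m) = 1} and the fraction
#' unfolded is exactly 0.5.
#'
#' @inheritParams fitBoltzmann
#' @param dCpU fixed unfolding heat-capacity change (kcal/mol/K); supply a
#'   value from complementary experiments or buried-surface-area estimates
#'   (4 is the documented example value for an MBP-sized protein).
#' @return a [ThermoFit-class].
#' @examples
#' tp <- seq(35, 65, by = 0.25)
#' fu <- sapply(tp, function(tc) {
#'   ku <- exp(-(120 * (1 - (tc + 273.15) / 323.15) -
#'     4 * (323.15 - (tc + 273.15) + (tc + 273.15) *
#'     log((tc + 273.15) / 323.15))) / (1.987204e-3 * (tc + 273.15)))
#'   ku / (1 + ku)
#' })
#' fitThermodynamic(meltCurve(tp, fu, normalized = TRUE), dCpU = 4)
#' @export
fitThermodynamic <- function(curve, dCpU, noiseFloor = 0,
                             fitBaselines = !isNormalized(curve)) {
    stopifnot(methods::is(curve, "MeltCurve"), is.numeric(dCpU))
    .checkTransition(curve, noiseFloor)
    ini <- .initCurve(curve)
    tp <- curve@temperature; y <- curve@signal
    if (fitBaselines) {
        par0 <- c(Tm = ini$Tm + .C2K, dHU = ini$dHU, mF = ini$mF,
                  bF = ini$bF, mU = ini$mU, bU = ini$bU)
        resid <- function(p) {
            fu <- .thermoFu(tp, p[1], p[2], dCpU)
            y - .mixBaselines(fu, tp, p[3], p[4], p[5], p[6])
        }
        lower <- c(200, 1e-3, rep(-Inf, 4))
    } else {
        par0 <- c(Tm = ini$Tm + .C2K, dHU = ini$dHU)
        resid <- function(p) y - .thermoFu(tp, p[1], p[2], dCpU)
        lower <- c(200, 1e-3)
    }
    fit <- minpack.lm::nls.lm(par0, lower, rep(Inf, length(par0)), resid,
                              control = .lmControl())
    if (!fit$info %in% 1:4) .fitError(curve, fit$message)
    p <- fit$par
    if (p[2] <= 1e-3) .fitError(curve, "unfolding enthalpy collapsed to zero")
    bl <- if (fitBaselines) c(p[3], p[4], p[5], p[6]) else c(0, 0, 0, 1)
    methods::new("ThermoFit", Tm = unname(p[1]), dHU = unname(p[2]),
        dCpU = dCpU, mF = unname(bl[1]), bF = unname(bl[2]),
        mU = unname(bl[3]), bU = unname(bl[4]),
        residNorm = sqrt(fit$deviance), converged = TRUE,
        tempRange = range(tp))
}

#' Jointly fit several melt curves with shared baseline slopes
#'
#' Because the dye's temperature dependence does not change with ligand
#' concentration, the folded/unfolded baseline slopes (\code{mF},
#' \code{mU}) are shared across all wells of a plate while the midpoint,
#' enthalpy (or steepness) and baseline intercepts remain per-curve. A
#' curve that fails its transition check is returned as a
#' [CurveFitFailure-class] and the joint fit proceeds without it.
#'
#' @param curves list of [MeltCurve-class] objects (>= 1).
#' @param model "thermodynamic" or "boltzmann".
#' @param dCpU fixed heat-capacity change, required for the thermodynamic
#'   model.
#' @param noiseFloor see [fitBoltzmann()].
#' @return named list, one [ThermoFit-class]/[BoltzmannFit-class] (or
#'   [CurveFitFailure-class]) per input curve, all successful fits sharing
#'   \code{mF} and \code{mU}.
#' @export
fitGlobal <- function(curves, model = c("thermodynamic", "boltzmann"),
                      dCpU = NULL, noiseFloor = 0) {
    model <- match.arg(model)
    stopifnot(is.list(curves), length(curves) >= 1L)
    if (model == "thermodynamic" && is.null(dCpU))
        stop("dCpU must be supplied for the thermodynamic model")
    nm <- vapply(curves, function(cc) cc@replicateId, character(1))
    out <- stats::setNames(vector("list", length(curves)), nm)

    ok <- logical(length(curves))
    for (i in seq_along(curves)) {
        res <- tryCatch({ .checkTransition(curves[[i]], noiseFloor); TRUE },
            isoDSF_no_transition = function(e)
                methods::new("CurveFitFailure", replicateId = nm[i],
                             message = conditionMessage(e)))
        if (isTRUE(res)) ok[i] <- TRUE else out[[i]] <- res
    }
    idx <- which(ok)
    if (!length(idx)) return(out)
    if (length(idx) == 1L) {
        i <- idx
        out[[i]] <- if (model == "thermodynamic")
            fitThermodynamic(curves[[i]], dCpU, noiseFloor)
        else fitBoltzmann(curves[[i]], noiseFloor)
        return(out)
    }

    thermo <- model == "thermodynamic"
    ## seed the joint problem from independent per-curve fits: the shared
    ## 50-odd-parameter optimisation is much less forgiving of the crude
    ## derivative-based starts than a 2- or 6-parameter fit is
    inis <- lapply(curves[idx], function(cc) {
        seed <- tryCatch(
            if (thermo) fitThermodynamic(cc, dCpU, noiseFloor,
                                         fitBaselines = TRUE)
            else fitBoltzmann(cc, noiseFloor, fitBaselines = TRUE),
            error = function(e) NULL)
        if (is.null(seed)) {
            ini <- .initCurve(cc)
            list(mid = if (thermo) ini$Tm + .C2K else ini$Tm,
                 steep = if (thermo) ini$dHU else ini$a,
                 mF = ini$mF, bF = ini$bF, mU = ini$mU, bU = ini$bU)
        } else list(mid = seed@Tm,
                    steep = if (thermo) seed@dHU else seed@a,
                    mF = seed@mF, bF = seed@bF, mU = seed@mU, bU = seed@bU)
    })
    par0 <- c(mF = mean(vapply(inis, `[[`, 0, "mF")),
              mU = mean(vapply(inis, `[[`, 0, "mU")))
    for (ini in inis)
        par0 <- c(par0, ini$mid, ini$steep, ini$bF, ini$bU)
    tps <- lapply(curves[idx], slot, "temperature")
    ys  <- lapply(curves[idx], slot, "signal")
    resid <- function(p) {
        mF <- p[1]; mU <- p[2]
        unlist(lapply(seq_along(idx), function(j) {
            q <- p[3 + 4 * (j - 1) + 0:3]
            fu <- if (thermo) .thermoFu(tps[[j]], q[1], q[2], dCpU)
                  else .boltzmannFu(tps[[j]], q[1], q[2])
            ys[[j]] - .mixBaselines(fu, tps[[j]], mF, q[3], mU, q[4])
        }), use.names = FALSE)
    }
    lower <- c(-Inf, -Inf, rep(c(if (thermo) 200 else -Inf,
                                 1e-3, -Inf, -Inf), length(idx)))
    fit <- minpack.lm::nls.lm(par0, lower, rep(Inf, length(par0)), resid,
                              control = .lmControl())
    conv <- fit$info %in% 1:4
    p <- fit$par
    for (j in seq_along(idx)) {
        i <- idx[j]
        q <- p[3 + 4 * (j - 1) + 0:3]
        fu <- if (thermo) .thermoFu(tps[[j]], q[1], q[2], dCpU)
              else .boltzmannFu(tps[[j]], q[1], q[2])
        rn <- sqrt(sum((ys[[j]] -
            .mixBaselines(fu, tps[[j]], p[1], q[3], p[2], q[4]))^2))
        out[[i]] <- if (thermo)
            methods::new("ThermoFit", Tm = unname(q[1]), dHU = unname(q[2]),
                dCpU = dCpU, mF = unname(p[1]), bF = unname(q[3]),
                mU = unname(p[2]), bU = unname(q[4]), residNorm = rn,
                converged = conv, tempRange = range(tps[[j]]))
        else
            methods::new("BoltzmannFit", Tm = unname(q[1]), a = unname(q[2]),
                mF = unname(p[1]), bF = unname(q[3]), mU = unname(p[2]),
                bU = unname(q[4]), residNorm = rn, converged = conv,
                tempRange = range(tps[[j]]))
    }
    out
}

#' Fit every well of a MeltExperiment
#'
#' Convenience wrapper: splits the plate into per-well curves and fits them
#' either jointly (shared baseline slopes, the default) or independently.
#'
#' @param x a [MeltExperiment-class].
#' @inheritParams fitGlobal
#' @param globalSlopes share the baseline slopes across wells?
#' @return named list of fits (see [fitGlobal()]).
#' @export
fitCurves <- function(x, model = c("thermodynamic", "boltzmann"),
                      dCpU = NULL, globalSlopes = TRUE, noiseFloor = 0) {
    model <- match.arg(model)
    curves <- meltCurves(x)
    if (globalSlopes && length(curves) >= 2L)
        return(fitGlobal(curves, model, dCpU, noiseFloor))
    lapply(curves, function(cc) {
        tryCatch(
            if (model == "thermodynamic")
                fitThermodynamic(cc, dCpU, noiseFloor)
            else fitBoltzmann(cc, noiseFloor),
            error = function(e) methods::new("CurveFitFailure",
                replicateId = cc@replicateId,
                message = conditionMessage(e)))
    })
}

#' Has a per-curve fit failed?
#'
#' @param fit an element of the list returned by [fitGlobal()] or
#'   [fitCurves()].
#' @return logical.
#' @export
isFailedFit <- function(fit) methods::is(fit, "CurveFitFailure")

#' Normalize a raw melt curve using its fitted baselines
#'
#' Rescales the signal to \eqn{(Y - B_F(T)) / (B_U(T) - B_F(T))}, the
#' fraction-unfolded scale, where \eqn{B_F} and \eqn{B_U} are the fitted
#' folded/unfolded baselines. Values are deliberately not clipped to
#' [0, 1] so residual structure survives normalization.
#'
#' @param curve the raw [MeltCurve-class] the fit came from.
#' @param fit a [BoltzmannFit-class] or [ThermoFit-class] with baselines,
#'   obtained from this curve.
#' @return a normalized [MeltCurve-class].
#' @section Errors: if the unfolded baseline does not exceed the folded
#'   baseline anywhere over the central half of the transition (fraction
#'   unfolded between 0.25 and 0.75) the curve is reported as inverted /
#'   unfittable via a classed error (\code{isoDSF_degenerate_baselines}).
#' @export
normalizeCurve <- function(curve, fit) {
    stopifnot(methods::is(curve, "MeltCurve"), methods::is(fit, "CurveFit"))
    tp <- curve@temperature
    ## central 50% of the transition: f_u in [0.25, 0.75], i.e. Tm +/-
    ## a*ln(3) with the effective Boltzmann steepness a = R Tm^2 / dH_U for
    ## the thermodynamic model.
    if (methods::is(fit, "BoltzmannFit")) {
        TmC <- fit@Tm; aEff <- fit@a
    } else {
        TmC <- fit@Tm - .C2K; aEff <- .RGAS * fit@Tm^2 / fit@dHU
    }
    win <- tp >= TmC - aEff * log(3) & tp <= TmC + aEff * log(3)
    if (!any(win)) win <- rep(TRUE, length(tp))
    fb <- fit@mF * tp + fit@bF
    ub <- fit@mU * tp + fit@bU
    if (any((ub - fb)[win] <= 0))
        stop(structure(class = c("isoDSF_degenerate_baselines", "error",
                                 "condition"),
            list(message = sprintf(
                "'%s': unfolded baseline does not exceed folded baseline over the transition; inverted or unfittable curve",
                curve@replicateId), call = NULL)))
    meltCurve(tp, (curve@signal - fb) / (ub - fb),
              ligandConc = curve@ligandConc,
              replicateId = curve@replicateId, normalized = TRUE)
}

.warnExtrapolation <- function(fit, temperature, margin) {
    lo <- fit@tempRange[1] - margin; hi <- fit@tempRange[2] + margin
    if (any(temperature < lo | temperature > hi))
        warning(sprintf(
            "evaluating fit %.1f degC beyond the fitted range [%.1f, %.1f]",
            max(abs(pmax(temperature - fit@tempRange[2], 0)),
                abs(pmin(temperature - fit@tempRange[1], 0))),
            fit@tempRange[1], fit@tempRange[2]), call. = FALSE)
}

#' @rdname fractionUnfolded
#' @export
setMethod("fractionUnfolded", "BoltzmannFit",
    function(fit, temperature, extrapolationMargin = 5) {
        .warnExtrapolation(fit, temperature, extrapolationMargin)
        pmin(pmax(.boltzmannFu(temperature, fit@Tm, fit@a), 0), 1)
    })

#' @rdname fractionUnfolded
#' @export
setMethod("fractionUnfolded", "ThermoFit",
    function(fit, temperature, extrapolationMargin = 5) {
        .warnExtrapolation(fit, temperature, extrapolationMargin)
        pmin(pmax(.thermoFu(temperature, fit@Tm, fit@dHU, fit@dCpU), 0), 1)
    })

#' @rdname predictSignal
#' @export
setMethod("predictSignal", "BoltzmannFit", function(fit, temperature) {
    fu <- .boltzmannFu(temperature, fit@Tm, fit@a)
    .mixBaselines(fu, temperature, fit@mF, fit@bF, fit@mU, fit@bU)
})

#' @rdname predictSignal
#' @export
setMethod("predictSignal", "ThermoFit", function(fit, temperature) {
    fu <- .thermoFu(temperature, fit@Tm, fit@dHU, fit@dCpU)
    .mixBaselines(fu, temperature, fit@mF, fit@bF, fit@mU, fit@bU)
})

#' @rdname meltingTemperature
#' @export
setMethod("meltingTemperature", "BoltzmannFit", function(fit) fit@Tm)

#' @rdname meltingTemperature
#' @export
setMethod("meltingTemperature", "ThermoFit", function(fit) fit@Tm - .C2K)
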