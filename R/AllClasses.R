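#' MeltCurve: one well's fluorescence-versus-temperature trace
#'
#' A single thermal unfolding trace together with the total ligand
#' concentration present in that well. Temperatures are in degrees Celsius
#' (instrument scale); the signal is fluorescence in arbitrary units, or the
#' fraction unfolded if the curve has been normalized.
#'
#' @slot temperature numeric, strictly increasing, length >= 10 (deg C).
#' @slot signal numeric fluorescence, same length as \code{temperature}.
#' @slot ligandConc total ligand concentration in the well (molar).
#' @slot replicateId character label identifying the well / replicate.
#' @slot normalized logical; \code{TRUE} once baselines have been divided
#'   out so the signal approximates the fraction unfolded. Normalized
#'   signals may slightly over/undershoot [0, 1]; they are deliberately not
#'   clipped so residual structure is preserved.
#'
#' @seealso [meltCurve()], [fitBoltzmann()], [fitThermodynamic()]
#' @export
setClass("MeltCurve",
    representation(
        temperature = "numeric",
        signal      = "numeric",
        ligandConc  = "numeric",
        replicateId = "character",
        normalized  = "logical"),
    prototype(ligandConc = 0, replicateId = "well", normalized = FALSE))

setValidity("MeltCurve", function(object) {
    msg <- character()
    tp <- object@temperature
    if (length(tp) < 10L)
        msg <- c(msg, "need at least 10 temperature points")
    if (length(tp) != length(object@signal))
        msg <- c(msg, "temperature and signal lengths differ")
    if (anyNA(tp) || anyNA(object@signal))
        msg <- c(msg, "temperature/signal must not contain NA")
    if (length(tp) > 1L && any(diff(tp) <= 0))
        msg <- c(msg, "temperature must be strictly increasing")
    if (length(object@ligandConc) != 1L || is.na(object@ligandConc) ||
        object@ligandConc < 0)
        msg <- c(msg, "ligandConc must be a single nonnegative number")
    if (isTRUE(object@normalized)) {
        ## allow noise-driven over/undershoot before complaining
        if (any(object@signal < -1) || any(object@signal > 2))
            msg <- c(msg, "normalized signal far outside [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a MeltCurve
#'
#' @param temperature strictly increasing temperatures (deg C).
#' @param signal fluorescence values, same length.
#' @param ligandConc total ligand concentration (molar). Default 0.
#' @param replicateId well / replicate label.
#' @param normalized logical; is the signal already on the 0-1
#'   fraction-unfolded scale?
#' @return a [MeltCurve-class] object.
#' @examples
#' tp <- seq(35, 65, by = 0.25)
#' fu <- 1 / (1 + exp((52.5 - tp) / 1.5))
#' mc <- meltCurve(tp, fu, normalized = TRUE)
#' @export
meltCurve <- function(temperature, signal, ligandConc = 0,
                      replicateId = "well", normalized = FALSE) {
    new("MeltCurve", temperature = as.numeric(temperature),
        signal = as.numeric(signal), ligandConc = as.numeric(ligandConc),
        replicateId = as.character(replicateId),
        normalized = isTRUE(normalized))
}

#' Virtual parent of single-curve fit results
#'
#' Both melt-curve models share the dye baselines (folded/unfolded slope and
#' intercept, on the Celsius scale), a residual norm, a convergence flag and
#' the fitted temperature range; [fractionUnfolded()] dispatches on the
#' concrete class.
#'
#' @slot mF,bF folded-baseline slope (signal per deg C) and intercept.
#' @slot mU,bU unfolded-baseline slope and intercept.
#' @slot residNorm sqrt of the residual sum of squares at the optimum.
#' @slot converged logical optimizer convergence flag.
#' @slot tempRange range of temperatures (deg C) the fit was trained on.
#' @export
setClass("CurveFit",
    representation("VIRTUAL",
        mF = "numeric", bF = "numeric", mU = "numeric", bU = "numeric",
        residNorm = "numeric", converged = "logical",
        tempRange = "numeric"))

#' Boltzmann sigmoid fit of a melt curve
#'
#' Empirical model: the fraction unfolded is
#' \eqn{f_u(T) = 1 / (1 + \exp((T_m - T)/a))}. Used for midpoint
#' determination and normalization only; \code{a} carries no thermodynamic
#' meaning.
#'
#' @slot Tm melting temperature (deg C).
#' @slot a transition steepness (deg C), > 0.
#' @export
setClass("BoltzmannFit", contains = "CurveFit",
    representation(Tm = "numeric", a = "numeric"))

setValidity("BoltzmannFit", function(object) {
    msg <- character()
    if (length(object@a) != 1L || is.na(object@a) || object@a <= 0)
        msg <- c(msg, "steepness a must be positive")
    if (length(object@tempRange) == 2L && !anyNA(object@tempRange) &&
        length(object@Tm) == 1L && !is.na(object@Tm) &&
        (object@Tm < object@tempRange[1] || object@Tm > object@tempRange[2]))
        msg <- c(msg, "Tm outside the observed temperature range")
    if (length(msg)) msg else TRUE
})

#' Two-state thermodynamic fit of a melt curve
#'
#' Gibbs-Helmholtz model with a fixed heat-capacity change:
#' \deqn{\Delta G_U(T) = \Delta H_U (1 - T/T_m)
#'       - \Delta C_p (T_m - T + T \ln(T/T_m))}
#' \eqn{K_U(T) = e^{-\Delta G_U / RT}}, fraction unfolded
#' \eqn{K_U/(1+K_U)}. By construction \eqn{\Delta G_U(T_m) = 0}, so
#' \eqn{K_U(T_m) = 1} and the fraction unfolded at \eqn{T_m} is exactly 0.5.
#'
#' @slot Tm melting temperature (kelvin).
#' @slot dHU unfolding enthalpy at Tm (kcal/mol), > 0.
#' @slot dCpU unfolding heat-capacity change (kcal/mol/K); held fixed
#'   during fitting, recorded here for reproducibility.
#' @export
setClass("ThermoFit", contains = "CurveFit",
    representation(Tm = "numeric", dHU = "numeric", dCpU = "numeric"))

setValidity("ThermoFit", function(object) {
    msg <- character()
    if (length(object@Tm) != 1L || is.na(object@Tm) || object@Tm <= 0)
        msg <- c(msg, "Tm (kelvin) must be positive")
    if (length(object@dHU) != 1L || is.na(object@dHU) || object@dHU <= 0)
        msg <- c(msg, "unfolding enthalpy dHU must be positive")
    if (length(msg)) msg else TRUE
})

#' Failed per-curve fit marker
#'
#' Returned by [fitGlobal()] (and the pipeline) in place of a fit when one
#' member curve is unfittable, so the remaining curves still succeed.
#'
#' @slot replicateId the offending well label.
#' @slot message diagnostic message.
#' @export
setClass("CurveFitFailure",
    representation(replicateId = "character", message = "character"))

#' Isothermal slice of a melt-curve family
#'
#' Fraction-unfolded observations at one fixed temperature across a ligand
#' dilution series, the input to [fitIsothermal()].
#'
#' @slot temperature the slice temperature (deg C).
#' @slot ligandConc total ligand concentrations (molar).
#' @slot fu fraction unfolded at each concentration, in [0, 1].
#' @slot sem standard error of the mean of each \code{fu} (NA when only a
#'   single replicate is available).
#' @slot nReps number of replicates behind each point.
#' @slot proteinConc total protein concentration (molar), > 0.
#' @export
setClass("IsothermalDataset",
    representation(
        temperature = "numeric",
        ligandConc  = "numeric",
        fu          = "numeric",
        sem         = "numeric",
        nReps       = "integer",
        proteinConc = "numeric"))

setValidity("IsothermalDataset", function(object) {
    msg <- character()
    n <- length(object@ligandConc)
    if (length(object@fu) != n || length(object@sem) != n ||
        length(object@nReps) != n)
        msg <- c(msg, "ligandConc, fu, sem, nReps must have equal length")
    if (any(object@ligandConc < 0, na.rm = TRUE))
        msg <- c(msg, "ligand concentrations must be nonnegative")
    if (any(object@fu < 0 | object@fu > 1, na.rm = TRUE))
        msg <- c(msg, "fraction unfolded must lie in [0, 1]")
    if (length(object@proteinConc) != 1L || is.na(object@proteinConc) ||
        object@proteinConc <= 0)
        msg <- c(msg, "proteinConc must be a single positive number")
    if (length(object@temperature) != 1L || is.na(object@temperature))
        msg <- c(msg, "temperature must be a single number")
    if (length(msg)) msg else TRUE
})

#' Construct an IsothermalDataset
#'
#' @param temperature slice temperature (deg C).
#' @param ligandConc total ligand concentrations (molar).
#' @param fu fraction unfolded at each concentration.
#' @param sem optional standard errors of the mean (default NA).
#' @param nReps optional replicate counts (default 1).
#' @param proteinConc total protein concentration (molar).
#' @return an [IsothermalDataset-class].
#' @examples
#' iso <- isothermalDataset(53, c(0, 1e-6, 1e-5, 1e-4),
#'                          c(0.56, 0.45, 0.2, 0.05), proteinConc = 2e-6)
#' @export
isothermalDataset <- function(temperature, ligandConc, fu,
                              sem = rep(NA_real_, length(fu)),
                              nReps = rep(1L, length(fu)),
                              proteinConc) {
    new("IsothermalDataset", temperature = as.numeric(temperature),
        ligandConc = as.numeric(ligandConc), fu = as.numeric(fu),
        sem = as.numeric(sem), nReps = as.integer(nReps),
        proteinConc = as.numeric(proteinConc))
}

#' Coupled folding/binding fit result
#'
#' The outcome of fitting \eqn{f_u([L]_T)} at one temperature with the
#' coupled-equilibrium model. When the fitted EC50 does not exceed the
#' total protein concentration the experiment is in the stoichiometric
#' regime: the dissociation constant is not identifiable and only the upper
#' bound \eqn{K_d < (1-f_{u0})\,[P]_T/2} is reported
#' (\code{stoichiometricRegime = TRUE}, \code{kdUpperBound} set).
#'
#' @slot Kd dissociation constant (molar).
#' @slot KU ligand-free unfolding constant at the slice temperature.
#' @slot fu0 fraction unfolded at zero ligand, \eqn{K_U/(1+K_U)}.
#' @slot EC50 total ligand concentration halving \eqn{f_u} relative to its
#'   zero-ligand plateau (molar).
#' @slot KdSE,KUSE,EC50SE standard errors (linear scale, delta method).
#' @slot stoichiometricRegime logical; see description.
#' @slot kdUpperBound molar upper bound on Kd in the stoichiometric regime
#'   (NA otherwise).
#' @slot KUFixed logical; was KU held fixed during the fit?
#' @slot converged logical; residNorm, nPoints: fit diagnostics.
#' @slot temperature slice temperature (deg C); proteinConc: molar.
#' @export
setClass("BindingFit",
    representation(
        Kd = "numeric", KU = "numeric", fu0 = "numeric", EC50 = "numeric",
        KdSE = "numeric", KUSE = "numeric", EC50SE = "numeric",
        stoichiometricRegime = "logical", kdUpperBound = "numeric",
        KUFixed = "logical", converged = "logical",
        residNorm = "numeric", nPoints = "integer",
        temperature = "numeric", proteinConc = "numeric"))

setValidity("BindingFit", function(object) {
    msg <- character()
    if (object@Kd <= 0) msg <- c(msg, "Kd must be positive")
    if (object@KU <= 0) msg <- c(msg, "KU must be positive")
    if (abs(object@fu0 - object@KU / (1 + object@KU)) > 1e-12)
        msg <- c(msg, "fu0 must equal KU/(1+KU)")
    ec50 <- object@Kd / (1 - object@fu0) + object@proteinConc / 2
    if (is.finite(object@EC50) &&
        abs(object@EC50 - ec50) > 1e-8 * max(ec50, .Machine$double.eps))
        msg <- c(msg, "EC50 inconsistent with Kd, fu0 and proteinConc")
    if (length(msg)) msg else TRUE
})

#' Thermodynamic simulation specification
#'
#' Parameter set for the melt-curve simulator: two-state unfolding
#' (Gibbs-Helmholtz, constant heat-capacity change) coupled to 1:1 binding
#' to the folded state (integrated van't Hoff with constant binding
#' heat-capacity change, anchored at the ligand-free midpoint). The
#' defaults in [simSpec()] reproduce a maltose-binding-protein-like system:
#' Tm = 50 deg C, dHU = 120 kcal/mol, dCpU = 4 kcal/mol/K,
#' dHb = -10 kcal/mol, dCpb = -0.5 kcal/mol/K, Kd(Tm) = 1 uM, 2 uM protein.
#'
#' @slot Tm ligand-free midpoint (kelvin).
#' @slot dHU unfolding enthalpy at Tm (kcal/mol).
#' @slot dCpU unfolding heat-capacity change (kcal/mol/K).
#' @slot dHb binding (association) enthalpy at Tm (kcal/mol).
#' @slot dCpb binding heat-capacity change (kcal/mol/K).
#' @slot KdTm dissociation constant at Tm (molar).
#' @slot Ptotal total protein concentration (molar).
#' @slot ligandLadder total ligand concentrations to simulate (molar).
#' @slot tempGrid temperatures (deg C) at which to evaluate curves.
#' @slot noiseSigma standard deviation of Gaussian noise added to the
#'   normalized signal (0 = noiseless).
#' @slot seed integer RNG seed controlling all noise.
#' @slot baselines numeric(4) (mF, bF, mU, bU) to emit raw-style signal,
#'   or numeric(0) to emit normalized fraction-unfolded curves.
#' @export
setClass("SimSpec",
    representation(
        Tm = "numeric", dHU = "numeric", dCpU = "numeric",
        dHb = "numeric", dCpb = "numeric", KdTm = "numeric",
        Ptotal = "numeric", ligandLadder = "numeric", tempGrid = "numeric",
        noiseSigma = "numeric", seed = "integer", baselines = "numeric"))

setValidity("SimSpec", function(object) {
    msg <- character()
    if (object@dHU <= 0) msg <- c(msg, "dHU must be positive")
    if (object@KdTm <= 0) msg <- c(msg, "KdTm must be positive")
    if (object@Tm <= 0) msg <- c(msg, "Tm (kelvin) must be positive")
    if (object@Ptotal <= 0) msg <- c(msg, "Ptotal must be positive")
    if (any(diff(object@tempGrid) <= 0))
        msg <- c(msg, "tempGrid must be strictly increasing")
    if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
    if (any(object@ligandLadder < 0))
        msg <- c(msg, "ligand ladder entries must be nonnegative")
    if (!length(object@baselines) %in% c(0L, 4L))
        msg <- c(msg, "baselines must be numeric(0) or (mF, bF, mU, bU)")
    if (length(msg)) msg else TRUE
})

#' Assay configuration for the end-to-end pipeline
#'
#' Carries the experimental constants ([P]_T, fixed dCp) and analysis
#' choices (model, slice temperatures, baseline sharing) into
#' [runPipeline()].
#'
#' @slot proteinConc total protein concentration (molar).
#' @slot dCpU fixed unfolding heat-capacity change (kcal/mol/K), used by
#'   the thermodynamic curve model.
#' @slot sliceTemperatures temperatures (deg C) at which isothermal fits
#'   are performed.
#' @slot model "thermodynamic" or "boltzmann".
#' @slot globalSlopes logical; share baseline slopes across wells?
#' @slot fixKU optional fixed unfolding constant for the isothermal fit
#'   (NA = fit it).
#' @slot outputDir optional directory for CSV/JSON reports ("" = none).
#' @export
setClass("AssayConfig",
    representation(
        proteinConc = "numeric", dCpU = "numeric",
        sliceTemperatures = "numeric", model = "character",
        globalSlopes = "logical", fixKU = "numeric",
        outputDir = "character"))

setValidity("AssayConfig", function(object) {
    msg <- character()
    if (object@proteinConc <= 0)
        msg <- c(msg, "proteinConc must be positive")
    if (!length(object@sliceTemperatures))
        msg <- c(msg, "need at least one slice temperature")
    if (!object@model %in% c("thermodynamic", "boltzmann"))
        msg <- c(msg, "model must be 'thermodynamic' or 'boltzmann'")
    if (length(msg)) msg else TRUE
})

#' Construct an AssayConfig
#'
#' @param proteinConc total protein concentration (molar).
#' @param sliceTemperatures slice temperatures (deg C).
#' @param dCpU fixed unfolding heat-capacity change (kcal/mol/K). The
#'   documented example value for an MBP-sized protein is 4.
#' @param model curve model, "thermodynamic" (default) or "boltzmann".
#' @param globalSlopes share baseline slopes across wells (default TRUE).
#' @param fixKU optional fixed KU for the isothermal fit.
#' @param outputDir optional report directory.
#' @return an [AssayConfig-class].
#' @export
assayConfig <- function(proteinConc, sliceTemperatures, dCpU = 4,
                        model = c("thermodynamic", "boltzmann"),
                        globalSlopes = TRUE, fixKU = NA_real_,
                        outputDir = "") {
    model <- match.arg(model)
    new("AssayConfig", proteinConc = as.numeric(proteinConc),
        dCpU = as.numeric(dCpU),
        sliceTemperatures = as.numeric(sliceTemperatures),
        model = model, globalSlopes = isTRUE(globalSlopes),
        fixKU = as.numeric(fixKU), outputDir = as.character(outputDir))
}
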