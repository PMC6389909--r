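#' MeltExperiment: a plate of melt curves
#'
#' A \linkS4class{SummarizedExperiment} holding one fluorescence assay
#' matrix (temperature points x wells). \code{rowData(x)$temperature}
#' carries the shared temperature grid (deg C); \code{colData(x)} carries
#' the per-well ligand map (\code{ligand_conc_molar},
#' \code{replicate_group}). \code{metadata(x)$normalized} records whether
#' the signal is on the fraction-unfolded scale.
#'
#' @seealso [MeltExperiment()], [readMeltTable()], [simulateDSF()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("MeltExperiment", contains = "SummarizedExperiment")

setValidity("MeltExperiment", function(object) {
    msg <- character()
    rd <- SummarizedExperiment::rowData(object)
    if (!"temperature" %in% colnames(rd))
        return("rowData must contain a 'temperature' column")
    tp <- rd$temperature
    if (anyNA(tp) || (length(tp) > 1L && any(diff(tp) <= 0)))
        msg <- c(msg, "temperatures must be strictly increasing")
    if (nrow(object) < 10L)
        msg <- c(msg, "need at least 10 temperature points")
    cd <- SummarizedExperiment::colData(object)
    need <- c("ligand_conc_molar", "replicate_group")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste("colData missing column(s):",
                            paste(miss, collapse = ", ")))
    else if (any(cd$ligand_conc_molar < 0, na.rm = TRUE))
        msg <- c(msg, "ligand concentrations must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' Construct a MeltExperiment
#'
#' @param signal numeric matrix, temperature points in rows, wells in
#'   columns; column names are well labels.
#' @param temperature strictly increasing temperatures (deg C), one per row.
#' @param ligandConc total ligand concentration per well (molar).
#' @param replicateGroup grouping label per well; wells sharing a label are
#'   treated as replicates of the same condition. Defaults to one group per
#'   distinct ligand concentration.
#' @param normalized logical; is the signal already on the
#'   fraction-unfolded scale?
#' @return a [MeltExperiment-class].
#' @examples
#' sp <- simSpec(noiseSigma = 0)
#' me <- simulateDSF(sp)
#' me
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
#' @export
MeltExperiment <- function(signal, temperature, ligandConc,
                           replicateGroup = NULL, normalized = FALSE) {
    signal <- as.matrix(signal)
    if (is.null(colnames(signal)))
        colnames(signal) <- sprintf("W%02d", seq_len(ncol(signal)))
    if (is.null(replicateGroup))
        replicateGroup <- match(ligandConc, sort(unique(ligandConc)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(fluorescence = signal),
        rowData = S4Vectors::DataFrame(temperature = as.numeric(temperature)),
        colData = S4Vectors::DataFrame(
            ligand_conc_molar = as.numeric(ligandConc),
            replicate_group = replicateGroup,
            row.names = colnames(signal)))
    me <- methods::new("MeltExperiment", se)
    S4Vectors::metadata(me)$normalized <- isTRUE(normalized)
    methods::validObject(me)
    me
}

#' Accessors for melt-curve containers
#'
#' \code{temperatures()} returns the temperature grid (deg C);
#' \code{signalValues()} the signal; \code{ligandConc()} the total ligand
#' concentration(s); \code{isNormalized()} whether the signal is on the
#' fraction-unfolded scale.
#'
#' @param x a [MeltCurve-class] or [MeltExperiment-class].
#' @name MeltCurve-accessors
NULL

#' @rdname MeltCurve-accessors
#' @export
setMethod("temperatures", "MeltCurve", function(x) x@temperature)

#' @rdname MeltCurve-accessors
#' @export
setMethod("temperatures", "MeltExperiment",
    function(x) SummarizedExperiment::rowData(x)$temperature)

#' @rdname MeltCurve-accessors
#' @export
setMethod("signalValues", "MeltCurve", function(x) x@signal)

#' @rdname MeltCurve-accessors
#' @importFrom SummarizedExperiment assay
#' @export
setMethod("signalValues", "MeltExperiment",
    function(x) SummarizedExperiment::assay(x, "fluorescence"))

#' @rdname MeltCurve-accessors
#' @export
setMethod("ligandConc", "MeltCurve", function(x) x@ligandConc)

#' @rdname MeltCurve-accessors
#' @export
setMethod("ligandConc", "MeltExperiment",
    function(x) {
        lc <- SummarizedExperiment::colData(x)$ligand_conc_molar
        names(lc) <- colnames(x)
        lc
    })

#' @rdname MeltCurve-accessors
#' @export
setMethod("isNormalized", "MeltCurve", function(x) x@normalized)

#' @rdname MeltCurve-accessors
#' @export
setMethod("isNormalized", "MeltExperiment",
    function(x) isTRUE(S4Vectors::metadata(x)$normalized))

#' Split a MeltExperiment into per-well MeltCurve objects
#'
#' @param x a [MeltExperiment-class].
#' @return named list of [MeltCurve-class], one per well.
#' @export
meltCurves <- function(x) {
    stopifnot(methods::is(x, "MeltExperiment"))
    tp <- temperatures(x)
    sig <- signalValues(x)
    lc <- ligandConc(x)
    norm <- isNormalized(x)
    out <- lapply(colnames(x), function(w)
        meltCurve(tp, sig[, w], ligandConc = lc[[w]], replicateId = w,
                  normalized = norm))
    names(out) <- colnames(x)
    out
}

setMethod("show", "MeltCurve", function(object) {
    cat("MeltCurve '", object@replicateId, "': ",
        length(object@temperature), " points, ",
        sprintf("%.2f-%.2f", min(object@temperature),
                max(object@temperature)), " degC, [L]_T = ",
        format(object@ligandConc, digits = 4), " M",
        if (object@normalized) " (normalized)" else "", "\n", sep = "")
})

setMethod("show", "BoltzmannFit", function(object) {
    cat("BoltzmannFit: Tm =", sprintf("%.3f degC,", object@Tm),
        "a =", sprintf("%.3f degC;", object@a),
        if (object@converged) "converged" else "NOT converged",
        sprintf("(resid norm %.3g)\n", object@residNorm))
})

setMethod("show", "ThermoFit", function(object) {
    cat("ThermoFit: Tm =", sprintf("%.3f degC,", object@Tm - 273.15),
        "dH_U =", sprintf("%.2f kcal/mol,", object@dHU),
        "dCp_U =", sprintf("%.2f kcal/mol/K (fixed);", object@dCpU),
        if (object@converged) "converged" else "NOT converged",
        sprintf("(resid norm %.3g)\n", object@residNorm))
})

setMethod("show", "CurveFitFailure", function(object) {
    cat("CurveFitFailure [", object@replicateId, "]: ", object@message,
        "\n", sep = "")
})

setMethod("show", "IsothermalDataset", function(object) {
    cat("IsothermalDataset at", sprintf("%.2f degC:", object@temperature),
        length(object@ligandConc), "ligand concentrations,",
        "[P]_T =", format(object@proteinConc, digits = 4), "M\n")
})

setMethod("show", "BindingFit", function(object) {
    cat("BindingFit at", sprintf("%.2f degC", object@temperature),
        sprintf("(n = %d):\n", object@nPoints))
    if (object@stoichiometricRegime) {
        cat("  stoichiometric regime: EC50 <= [P]_T; K_d <",
            format(object@kdUpperBound, digits = 3), "M (upper bound)\n")
    } else {
        cat("  K_d  =", format(object@Kd, digits = 4), "M",
            if (is.finite(object@KdSE))
                sprintf("(SE %.3g)", object@KdSE) else "", "\n")
    }
    cat("  K_U  =", sprintf("%.4g", object@KU),
        if (object@KUFixed) "(fixed)" else
            if (is.finite(object@KUSE))
                sprintf("(SE %.3g)", object@KUSE) else "", "\n")
    cat("  f_u0 =", sprintf("%.4g", object@fu0),
        "  EC50 =", format(object@EC50, digits = 4), "M\n")
})

setMethod("show", "SimSpec", function(object) {
    cat("SimSpec: Tm =", sprintf("%.2f degC,", object@Tm - 273.15),
        "dH_U =", object@dHU, "kcal/mol, dCp_U =", object@dCpU,
        "kcal/mol/K\n  dH_b =", object@dHb, "kcal/mol, dCp_b =",
        object@dCpb, "kcal/mol/K, Kd(Tm) =",
        format(object@KdTm, digits = 4), "M\n ",
        length(object@ligandLadder), "ligand concentrations,",
        length(object@tempGrid), "temperatures, sigma =",
        object@noiseSigma, "\n")
})
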