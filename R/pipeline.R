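## End-to-end analysis: fit every well's melt curve, slice the fitted
## family at each requested temperature, aggregate replicates, and fit the
## coupled folding/binding model per slice.

.curveFitTable <- function(fits, model) {
    rows <- lapply(names(fits), function(w) {
        f <- fits[[w]]
        if (isFailedFit(f))
            return(data.frame(well = w, model = model, Tm_C = NA_real_,
                dHU_kcal_mol = NA_real_, a_C = NA_real_, mF = NA_real_,
                bF = NA_real_, mU = NA_real_, bU = NA_real_,
                residNorm = NA_real_, converged = FALSE,
                note = f@message))
        data.frame(well = w, model = model,
            Tm_C = meltingTemperature(f),
            dHU_kcal_mol = if (methods::is(f, "ThermoFit")) f@dHU
                           else NA_real_,
            a_C = if (methods::is(f, "BoltzmannFit")) f@a else NA_real_,
            mF = f@mF, bF = f@bF, mU = f@mU, bU = f@bU,
            residNorm = f@residNorm, converged = f@converged, note = "")
    })
    do.call(rbind, rows)
}

#' Build an isothermal slice from per-well curve fits
#'
#' Evaluates each successful fit at the slice temperature, aggregates
#' replicate wells (same \code{replicate_group}) to mean fraction
#' unfolded with the standard error of the mean, and assembles an
#' [IsothermalDataset-class].
#'
#' @param x the [MeltExperiment-class] the fits came from.
#' @param fits list of per-well fits ([fitCurves()] output).
#' @param temperature slice temperature (deg C).
#' @param proteinConc total protein concentration (molar).
#' @return an [IsothermalDataset-class].
#' @export
sliceIsothermal <- function(x, fits, temperature, proteinConc) {
    cd <- SummarizedExperiment::colData(x)
    okWells <- names(fits)[!vapply(fits, isFailedFit, logical(1))]
    if (!length(okWells)) stop("no successfully fitted curves to slice")
    fu <- vapply(okWells, function(w)
        fractionUnfolded(fits[[w]], temperature), numeric(1))
    grp <- cd[okWells, "replicate_group"]
    lig <- cd[okWells, "ligand_conc_molar"]
    groups <- unique(grp)
    agg <- lapply(groups, function(g) {
        v <- fu[grp == g]
        data.frame(ligand = lig[grp == g][1], fu = mean(v),
            sem = if (length(v) > 1L)
                stats::sd(v) / sqrt(length(v)) else NA_real_,
            n = length(v))
    })
    agg <- do.call(rbind, agg)
    agg <- agg[order(agg$ligand), ]
    isothermalDataset(temperature, agg$ligand,
                      pmin(pmax(agg$fu, 0), 1), agg$sem,
                      as.integer(agg$n), proteinConc)
}

.bindingFitRow <- function(bf) {
    data.frame(temperature_C = bf@temperature,
        Kd_molar = bf@Kd, Kd_SE = bf@KdSE,
        KU = bf@KU, KU_SE = bf@KUSE, fu0 = bf@fu0,
        EC50_molar = bf@EC50, EC50_SE = bf@EC50SE,
        stoichiometric_regime = bf@stoichiometricRegime,
        Kd_upper_bound_molar = bf@kdUpperBound,
        KU_fixed = bf@KUFixed, n_points = bf@nPoints,
        resid_norm = bf@residNorm)
}

#' Run the full isothermal DSF analysis pipeline
#'
#' Fits every well (optionally with globally shared baseline slopes),
#' slices the fitted curves at each configured temperature, aggregates
#' replicates and fits the coupled folding/binding model, and summarizes
#' the conventional midpoint shift (delta-Tm) per ligand concentration for
#' reference. Per-curve failures and flat slices are isolated: the rest of
#' the analysis still completes, with the failures recorded in the log.
#'
#' @param x a [MeltExperiment-class].
#' @param config an [AssayConfig-class].
#' @return a list of class \code{"isoDSFReport"}:
#' \describe{
#'   \item{version}{report schema version string.}
#'   \item{curveFits}{per-well fit table (data.frame) and \code{fits}, the
#'     underlying fit objects.}
#'   \item{isothermal}{per slice temperature: the
#'     [IsothermalDataset-class], the [BindingFit-class] (or NULL on
#'     failure) and a one-row summary data.frame.}
#'   \item{bindingTable}{all slice summaries combined.}
#'   \item{deltaTm}{midpoint shift versus ligand concentration; reported
#'     for continuity with conventional analysis, never used for Kd.}
#'   \item{log}{character vector of decisions and per-item failures.}
#' }
#' If \code{config@outputDir} is set, writes \code{curve_fits.csv},
#' \code{binding_fits.csv}, \code{delta_tm.csv} and \code{report.json}
#' there.
#' @examples
#' me <- simulateDSF(simSpec())
#' rep <- runPipeline(me, assayConfig(2e-6, 50))
#' rep$bindingTable
#' @export
runPipeline <- function(x, config) {
    stopifnot(methods::is(x, "MeltExperiment"),
              methods::is(config, "AssayConfig"))
    methods::validObject(config)
    log <- character()
    note <- function(...) {
        msg <- sprintf(...)
        message("[isoDSF] ", msg)
        log <<- c(log, msg)
    }
    note("curve model: %s; dCp_U fixed at %g kcal/mol/K; global slopes: %s",
         config@model, config@dCpU, config@globalSlopes)
    fits <- fitCurves(x, model = config@model, dCpU = config@dCpU,
                      globalSlopes = config@globalSlopes)
    failed <- names(fits)[vapply(fits, isFailedFit, logical(1))]
    for (w in failed) note("curve '%s' flagged: %s", w, fits[[w]]@message)
    fitTab <- .curveFitTable(fits, config@model)

    ## conventional delta-Tm summary (reference only)
    cd <- SummarizedExperiment::colData(x)
    okW <- setdiff(names(fits), failed)
    tmByConc <- tapply(
        vapply(okW, function(w) meltingTemperature(fits[[w]]), numeric(1)),
        cd[okW, "ligand_conc_molar"], mean)
    conc <- as.numeric(names(tmByConc))
    tm0 <- if (any(conc == 0)) tmByConc[conc == 0][1] else NA_real_
    deltaTm <- data.frame(ligand_conc_molar = conc,
        Tm_C = as.numeric(tmByConc),
        delta_Tm_C = as.numeric(tmByConc) - tm0)

    iso <- list()
    for (tt in config@sliceTemperatures) {
        key <- sprintf("%.4g", tt)
        entry <- list(temperature = tt, dataset = NULL, fit = NULL,
                      summary = NULL)
        entry <- tryCatch({
            ds <- sliceIsothermal(x, fits, tt, config@proteinConc)
            fixKU <- config@fixKU
            if (is.finite(fixKU))
                note("slice %s degC: KU fixed at %g", key, fixKU)
            bf <- fitIsothermal(ds,
                fixKU = if (is.finite(fixKU)) fixKU else NULL)
            if (bf@stoichiometricRegime)
                note("slice %s degC: EC50 <= [P]_T, stoichiometric regime; reporting Kd < %.3g M (upper bound)",
                     key, bf@kdUpperBound)
            list(temperature = tt, dataset = ds, fit = bf,
                 summary = .bindingFitRow(bf))
        }, error = function(e) {
            note("slice %s degC failed: %s", key, conditionMessage(e))
            entry
        })
        iso[[key]] <- entry
    }
    bindingTable <- do.call(rbind,
        Filter(Negate(is.null), lapply(iso, `[[`, "summary")))

    report <- structure(list(version = "1.0",
        curveFits = list(table = fitTab, fits = fits),
        isothermal = iso, bindingTable = bindingTable,
        deltaTm = deltaTm, log = log), class = "isoDSFReport")
    if (nzchar(config@outputDir)) writeReport(report, config@outputDir)
    report
}

#' Write an isoDSF pipeline report to disk
#'
#' Emits human-readable CSVs (curve fits, binding fits, delta-Tm) and one
#' machine-readable, schema-versioned JSON.
#'
#' @param report list returned by [runPipeline()].
#' @param dir output directory (created if missing).
#' @return invisibly, the JSON path.
#' @export
writeReport <- function(report, dir) {
    stopifnot(inherits(report, "isoDSFReport"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report$curveFits$table,
                     file.path(dir, "curve_fits.csv"), row.names = FALSE)
    if (!is.null(report$bindingTable))
        utils::write.csv(report$bindingTable,
                         file.path(dir, "binding_fits.csv"),
                         row.names = FALSE)
    utils::write.csv(report$deltaTm, file.path(dir, "delta_tm.csv"),
                     row.names = FALSE)
    json <- list(version = report$version,
        curve_fits = report$curveFits$table,
        binding_fits = report$bindingTable,
        delta_tm = report$deltaTm, log = report$log)
    path <- file.path(dir, "report.json")
    jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    invisible(path)
}

#' @export
print.isoDSFReport <- function(x, ...) {
    cat("isoDSF pipeline report (schema", x$version, ")\n")
    nf <- sum(!x$curveFits$table$converged)
    cat(" ", nrow(x$curveFits$table), "curve fits (",
        nf, "flagged )\n")
    if (!is.null(x$bindingTable)) {
        cat("  binding fits:\n")
        print(x$bindingTable[, c("temperature_C", "Kd_molar", "KU",
                                 "EC50_molar", "stoichiometric_regime")],
              row.names = FALSE)
    }
    invisible(x)
}
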