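## Single melt-curve models: Boltzmann sigmoid and two-state
## thermodynamic fits, normalization, fraction-unfolded extraction.

tpGrid <- seq(35, 65, by = 0.25)

test_that("Boltzmann fit recovers known parameters from clean data", {
    cases <- list(c(Tm = 52.5, a = 1.5), c(Tm = 45, a = 0.8),
                  c(Tm = 58, a = 2.5))
    for (cs in cases) {
        fu <- 1 / (1 + exp((cs["Tm"] - tpGrid) / cs["a"]))
        fit <- fitBoltzmann(meltCurve(tpGrid, fu, normalized = TRUE))
        expect_equal(fit@Tm, unname(cs["Tm"]), tolerance = 1e-6)
        expect_equal(fit@a, unname(cs["a"]), tolerance = 1e-6)
        expect_true(fit@converged)
        ## midpoint property: normalized model crosses 0.5 at Tm
        expect_equal(fractionUnfolded(fit, fit@Tm), 0.5)
    }
})

test_that("Boltzmann fit with baselines inverts a raw synthetic curve", {
    fu <- 1 / (1 + exp((52.5 - tpGrid) / 1.5))
    raw <- oracleRawSignal(tpGrid, fu, mF = 0.02, bF = 1, mU = -0.05,
                           bU = 9)
    fit <- fitBoltzmann(meltCurve(tpGrid, raw))
    expect_equal(fit@Tm, 52.5, tolerance = 1e-5)
    expect_equal(fit@a, 1.5, tolerance = 1e-4)
    expect_equal(fit@mF, 0.02, tolerance = 1e-3)
    expect_equal(fit@mU, -0.05, tolerance = 1e-3)
})

test_that("a flat trace is rejected as having no transition", {
    flat <- meltCurve(tpGrid, rep(3.2, length(tpGrid)))
    expect_error(fitBoltzmann(flat), class = "isoDSF_no_transition")
    expect_error(fitThermodynamic(flat, dCpU = 4),
                 class = "isoDSF_no_transition")
})

test_that("thermodynamic fit round-trips generator parameters", {
    ## generator written first (helper oracle); fit must invert it
    truth <- list(TmK = 323.15, dHU = 120, dCpU = 4,
                  mF = 0.01, bF = 0.5, mU = -0.03, bU = 7)
    fu <- oracleThermoFu(tpGrid, truth$TmK, truth$dHU, truth$dCpU)
    raw <- oracleRawSignal(tpGrid, fu, truth$mF, truth$bF, truth$mU,
                           truth$bU)
    fit <- fitThermodynamic(meltCurve(tpGrid, raw), dCpU = truth$dCpU)
    expect_equal(fit@Tm, truth$TmK, tolerance = 1e-4)
    expect_equal(fit@dHU, truth$dHU, tolerance = 1e-4)
    expect_equal(fit@mF, truth$mF, tolerance = 1e-3)
    expect_equal(fit@bU, truth$bU, tolerance = 1e-3)
})

test_that("K_U = 1 and f_u = 0.5 hold exactly at the fitted Tm", {
    fu <- oracleThermoFu(tpGrid, 325, 110, 4)
    fit <- fitThermodynamic(meltCurve(tpGrid, fu, normalized = TRUE),
                            dCpU = 4)
    expect_equal(fractionUnfolded(fit, fit@Tm - 273.15), 0.5,
                 tolerance = 1e-12)
})

test_that("fraction unfolded matches the closed form and is monotone", {
    bfit <- new("BoltzmannFit", Tm = 52.5, a = 1.5, mF = 0, bF = 0,
                mU = 0, bU = 1, residNorm = 0, converged = TRUE,
                tempRange = c(35, 65))
    expect_equal(fractionUnfolded(bfit, 53), 1 / (1 + exp(-0.5 / 1.5)),
                 tolerance = 1e-12)
    tfit <- fitThermodynamic(
        meltCurve(tpGrid, oracleThermoFu(tpGrid, 323.15, 120, 4),
                  normalized = TRUE), dCpU = 4)
    for (fit in list(bfit, tfit)) {
        fuSeq <- fractionUnfolded(fit, seq(36, 64, by = 0.5))
        expect_true(all(diff(fuSeq) >= 0))
        expect_true(all(fuSeq >= 0 & fuSeq <= 1))
    }
    expect_warning(fractionUnfolded(bfit, 90), "beyond the fitted range")
})

test_that("normalization inverts the baseline mixing", {
    fuTrue <- oracleThermoFu(tpGrid, 323.15, 120, 4)
    raw <- oracleRawSignal(tpGrid, fuTrue, 0.02, 1, -0.05, 9)
    curve <- meltCurve(tpGrid, raw)
    fit <- fitThermodynamic(curve, dCpU = 4)
    norm <- normalizeCurve(curve, fit)
    expect_true(isNormalized(norm))
    expect_equal(signalValues(norm), fuTrue, tolerance = 1e-6)
    ## points sitting exactly on a baseline map to exactly 0 / 1
    onFolded <- meltCurve(tpGrid, 0.02 * tpGrid + 1)
    expect_equal(signalValues(normalizeCurve(onFolded, fit)),
                 rep(0, length(tpGrid)))
    onUnfolded <- meltCurve(tpGrid, -0.05 * tpGrid + 9)
    expect_equal(signalValues(normalizeCurve(onUnfolded, fit)),
                 rep(1, length(tpGrid)))
})

test_that("inverted baselines are reported as degenerate", {
    fuTrue <- oracleThermoFu(tpGrid, 323.15, 120, 4)
    raw <- oracleRawSignal(tpGrid, fuTrue, 0.02, 1, -0.05, 9)
    curve <- meltCurve(tpGrid, raw)
    bad <- new("ThermoFit", Tm = 323.15, dHU = 120, dCpU = 4,
               mF = -0.05, bF = 9, mU = 0.02, bU = 1,
               residNorm = 0, converged = TRUE, tempRange = range(tpGrid))
    expect_error(normalizeCurve(curve, bad),
                 class = "isoDSF_degenerate_baselines")
})

test_that("global fit shares slopes and matches independent fits", {
    set.seed(42)
    tms <- c(321, 323.15, 326)
    curves <- lapply(seq_along(tms), function(i) {
        fu <- oracleThermoFu(tpGrid, tms[i], 120, 4)
        meltCurve(tpGrid,
                  oracleRawSignal(tpGrid, fu, 0.02, 1 + 0.2 * i, -0.05,
                                  9 - 0.3 * i),
                  replicateId = paste0("W", i))
    })
    gl <- fitGlobal(curves, model = "thermodynamic", dCpU = 4)
    ind <- lapply(curves, fitThermodynamic, dCpU = 4)
    ## one shared slope pair across all member fits
    expect_equal(gl[[1]]@mF, gl[[2]]@mF)
    expect_equal(gl[[2]]@mU, gl[[3]]@mU)
    for (i in seq_along(tms)) {
        expect_equal(gl[[i]]@Tm, tms[i], tolerance = 1e-5)
        expect_equal(gl[[i]]@Tm, ind[[i]]@Tm, tolerance = 1e-5)
        expect_equal(gl[[i]]@dHU, ind[[i]]@dHU, tolerance = 1e-4)
    }
})

test_that("global fit degenerates to the single-curve fit", {
    fu <- oracleThermoFu(tpGrid, 323.15, 120, 4)
    curve <- meltCurve(tpGrid, oracleRawSignal(tpGrid, fu, 0.02, 1,
                                               -0.05, 9))
    gl <- fitGlobal(list(curve), model = "thermodynamic", dCpU = 4)
    single <- fitThermodynamic(curve, dCpU = 4)
    expect_equal(gl[[1]]@Tm, single@Tm, tolerance = 1e-10)
    expect_equal(gl[[1]]@dHU, single@dHU, tolerance = 1e-10)
})

test_that("global fit pays a residual price when true slopes differ", {
    curves <- lapply(1:2, function(i) {
        fu <- oracleThermoFu(tpGrid, 321 + 2 * i, 120, 4)
        mFi <- c(0.02, 0.08)[i]   # deliberately different folded slopes
        meltCurve(tpGrid, oracleRawSignal(tpGrid, fu, mFi, 1, -0.05, 9),
                  replicateId = paste0("W", i))
    })
    gl <- fitGlobal(curves, model = "thermodynamic", dCpU = 4)
    ind <- lapply(curves, fitThermodynamic, dCpU = 4)
    rGlobal <- sum(vapply(gl, slot, 0, "residNorm")^2)
    rInd <- sum(vapply(ind, slot, 0, "residNorm")^2)
    expect_gt(rGlobal, rInd)
})

test_that("global fit isolates an unfittable member curve", {
    fu <- oracleThermoFu(tpGrid, 323.15, 120, 4)
    good <- meltCurve(tpGrid, fu, replicateId = "good", normalized = TRUE)
    flat <- meltCurve(tpGrid, rep(0.5, length(tpGrid)),
                      replicateId = "flat", normalized = TRUE)
    out <- fitGlobal(list(good, flat), model = "thermodynamic", dCpU = 4)
    expect_true(isFailedFit(out$flat))
    expect_false(isFailedFit(out$good))
    expect_equal(out$good@Tm, 323.15, tolerance = 1e-4)
})

test_that("normalized-curve interpolation agrees with model extraction", {
    fuTrue <- oracleThermoFu(tpGrid, 323.15, 120, 4)
    curve <- meltCurve(tpGrid, oracleRawSignal(tpGrid, fuTrue, 0.02, 1,
                                               -0.05, 9))
    fit <- fitThermodynamic(curve, dCpU = 4)
    norm <- normalizeCurve(curve, fit)
    at <- c(48, 50, 52)
    direct <- stats::approx(temperatures(norm), signalValues(norm),
                            xout = at)$y
    expect_equal(fractionUnfolded(fit, at), direct, tolerance = 1e-4)
})
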