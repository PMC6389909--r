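## Coupled folding/binding equilibrium at a fixed temperature: free-ligand
## root, fraction-unfolded model, EC50/Kd closed forms, and the isothermal
## least-squares fit.

test_that("free ligand solves the mass-balance quadratic", {
    expect_equal(freeLigand(0, 2e-6, 1e-6, 1), 0)
    expect_equal(freeLigand(1e-5, 0, 1e-6, 1), 1e-5)
    ## against a brute-force root finder plus species reconstruction
    set.seed(11)
    for (i in 1:25) {
        Kd <- 10^runif(1, -8, -3); KU <- 10^runif(1, -1.5, 1.5)
        PT <- 10^runif(1, -7, -5); LT <- 10^runif(1, -8, -3)
        L <- freeLigand(LT, PT, Kd, KU)
        expect_equal(L, oracleFreeLigand(LT, PT, Kd, KU),
                     tolerance = 1e-9)
        expect_true(L >= 0 && L <= LT)
        expect_lt(massBalanceResidual(L, LT, PT, Kd, KU), 1e-10)
    }
    ## the worked spot check
    L <- freeLigand(10e-6, 2e-6, 1e-6, 1)
    expect_equal(L, oracleFreeLigand(10e-6, 2e-6, 1e-6, 1),
                 tolerance = 1e-12)
    expect_lt(massBalanceResidual(L, 10e-6, 2e-6, 1e-6, 1), 1e-12)
    expect_error(freeLigand(-1e-6, 2e-6, 1e-6, 1), "nonnegative")
})

test_that("fraction-unfolded model has the right limits and monotonicity", {
    expect_equal(fractionUnfoldedModel(0, 2e-6, 1e-6, 1), 0.5)
    expect_equal(fractionUnfoldedModel(0, 2e-6, 1e-6, 3), 0.75)
    expect_lt(fractionUnfoldedModel(1, 2e-6, 1e-6, 1), 1e-5)
    L <- c(0, 10^seq(-8, -2, by = 0.25))
    fu <- fractionUnfoldedModel(L, 2e-6, 1e-6, 1)
    expect_true(all(diff(fu) < 0))   # strictly decreasing in ligand
})

test_that("EC50 closed form is exact against the full model", {
    set.seed(23)
    for (i in 1:50) {
        Kd <- 10^runif(1, -8, -3); KU <- 10^runif(1, -1.5, 1.5)
        PT <- 10^runif(1, -7, -5)
        fu0 <- KU / (1 + KU)
        ec50 <- ec50FromKd(Kd, PT, fu0)
        expect_equal(fractionUnfoldedModel(ec50, PT, Kd, KU), fu0 / 2,
                     tolerance = 1e-10)
    }
})

test_that("EC50 <-> Kd conversions reproduce the worked numbers", {
    ## MBP/maltose at 53 degC: EC50 6.8 uM, 2 uM protein, K_U = 1.3
    expect_equal(signif(kdFromEC50(6.8e-6, 2e-6, 1.3 / 2.3) * 1e6, 2),
                 2.5)
    ## boundary of the interpretable regime
    expect_equal(ec50FromKd(0.5e-6, 2e-6, 0.5), 2e-6)
    ## fully folded limit: EC50 = Kd + P/2 inverts to Kd
    expect_equal(kdFromEC50(1e-6 + 1e-6, 2e-6, 0), 1e-6)
    ## algebraic inverse round trip
    set.seed(5)
    for (i in 1:20) {
        Kd <- 10^runif(1, -8, -3); fu0 <- runif(1, 0, 0.95)
        PT <- 2e-6
        expect_equal(kdFromEC50(ec50FromKd(Kd, PT, fu0), PT, fu0), Kd,
                     tolerance = 1e-12)
    }
    expect_error(kdFromEC50(0.9e-6, 2e-6, 0.5),
                 class = "isoDSF_stoichiometric")
    expect_error(ec50FromKd(1e-6, 2e-6, 1), "fully unfolded")
})

test_that("isothermal fit recovers parameters from its own model", {
    L <- c(0, 500e-6 / 2^(10:0))
    fu <- fractionUnfoldedModel(L, 2e-6, 1e-6, 1)
    bf <- fitIsothermal(isothermalDataset(50, L, fu, proteinConc = 2e-6))
    expect_equal(bf@Kd, 1e-6, tolerance = 1e-6)
    expect_equal(bf@KU, 1, tolerance = 1e-6)
    expect_equal(bf@fu0, bf@KU / (1 + bf@KU))
    ## Kd, fu0, P and EC50 jointly satisfy the closed form
    expect_equal(bf@EC50, ec50FromKd(bf@Kd, 2e-6, bf@fu0))
    expect_false(bf@stoichiometricRegime)
})

test_that("fixed-KU and free-KU fits agree when KU is the true value", {
    L <- c(0, 500e-6 / 2^(10:0))
    set.seed(99)
    fu <- pmin(pmax(
        fractionUnfoldedModel(L, 2e-6, 2e-6, 1.4) + rnorm(12, 0, 0.01),
        0), 1)
    ds <- isothermalDataset(50, L, fu, proteinConc = 2e-6)
    free <- fitIsothermal(ds)
    fixed <- fitIsothermal(ds, fixKU = free@KU)
    expect_true(fixed@KUFixed)
    tol <- sqrt(free@KdSE^2 + fixed@KdSE^2) + 1e-12
    expect_lt(abs(free@Kd - fixed@Kd), 3 * tol + 0.05 * free@Kd)
})

test_that("noisy recovery stays within 20% for sigma = 0.05 on the curves", {
    ## noise enters the normalized unfolding curves; slicing the fitted
    ## curves pools the whole trace, so the per-point noise on f_u is much
    ## smaller than the raw sigma
    errs <- vapply(1:100, function(seed) {
        sp <- simSpec(noiseSigma = 0.05, seed = seed)
        me <- simulateDSF(sp)
        fits <- fitCurves(me, model = "thermodynamic", dCpU = 4,
                          globalSlopes = FALSE)
        ds <- sliceIsothermal(me, fits, 50, 2e-6)
        bf <- try(fitIsothermal(ds), silent = TRUE)
        if (inherits(bf, "try-error")) NA_real_
        else abs(bf@Kd - 1e-6) / 1e-6
    }, numeric(1))
    expect_lt(median(errs, na.rm = TRUE), 0.20)
})

test_that("degenerate isothermal inputs fail informatively", {
    L <- c(0, 500e-6 / 2^(10:0))
    flat <- isothermalDataset(40, L, rep(0.02, 12), proteinConc = 2e-6)
    expect_error(fitIsothermal(flat), class = "isoDSF_flat_data")
    few <- isothermalDataset(50, c(0, 1e-6, 1e-5),
                             c(0.5, 0.4, 0.2), proteinConc = 2e-6)
    expect_error(fitIsothermal(few), ">= 4 distinct")
    noZero <- isothermalDataset(50, c(1e-7, 1e-6, 1e-5, 1e-4),
                                c(0.49, 0.4, 0.2, 0.05),
                                proteinConc = 2e-6)
    expect_error(fitIsothermal(noZero), "zero-ligand")
    ## but works when KU is supplied externally
    bf <- fitIsothermal(noZero, fixKU = 1)
    expect_true(bf@KUFixed)
})

test_that("tight binders are flagged as stoichiometric with an upper bound", {
    L <- c(0, 500e-6 / 2^(10:0))
    fu <- fractionUnfoldedModel(L, 2e-6, 1e-8, 1)   # Kd << [P]_T
    bf <- fitIsothermal(isothermalDataset(50, L, fu, proteinConc = 2e-6))
    expect_true(bf@stoichiometricRegime)
    expect_equal(bf@kdUpperBound, (1 - bf@fu0) * 1e-6)
})

test_that("logistic midpoint estimate matches the rigorous fit closely", {
    L <- c(0, 500e-6 / 2^(10:0))
    fu <- fractionUnfoldedModel(L, 2e-6, 2.5e-6, 1)
    ds <- isothermalDataset(53, L, fu, proteinConc = 2e-6)
    h <- ec50Hill(ds)
    rig <- fitIsothermal(ds)
    expect_lt(abs(h$EC50 - rig@EC50) / rig@EC50, 0.05)
    ## symmetric logistic toy: midpoint at the ladder's geometric centre
    x <- 10^seq(-8, -4, by = 0.5)
    toy <- isothermalDataset(50, c(0, x),
        c(0.5, 0.5 / (1 + (x / 1e-6))), proteinConc = 2e-6)
    expect_equal(ec50Hill(toy)$EC50, 1e-6, tolerance = 0.02)
})
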