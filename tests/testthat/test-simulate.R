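## Thermodynamic melt-curve simulator: anchoring identities, van't Hoff
## limits, noise model, determinism.

test_that("unfolding constant is anchored and monotone in temperature", {
    sp <- mbpLikeSpec()
    expect_equal(kuAtTemperature(sp, sp@Tm), 1)
    tk <- seq(sp@Tm - 15, sp@Tm + 15, by = 0.25)
    expect_true(all(diff(kuAtTemperature(sp, tk)) > 0))
})

test_that("dissociation constant anchors at Kd(Tm) with van't Hoff limits", {
    sp <- mbpLikeSpec()
    expect_equal(kdAtTemperature(sp, sp@Tm), sp@KdTm)
    ## athermal binding: Kd constant in T
    flat <- simSpec(dHb = 0, dCpb = 0)
    tk <- c(310, 320, 323.15, 330)
    expect_equal(kdAtTemperature(flat, tk), rep(flat@KdTm, 4),
                 tolerance = 1e-12)
    ## dCp_b = 0: two-point van't Hoff slope of the association free
    ## energy, ln(Kd(T1)/Kd(T2)) = (dH_b/R)(1/T1 - 1/T2)
    vh <- simSpec(dCpb = 0)
    t1 <- 318; t2 <- 330
    expect_equal(log(kdAtTemperature(vh, t1) / kdAtTemperature(vh, t2)),
                 (vh@dHb / 1.987204e-3) * (1 / t1 - 1 / t2),
                 tolerance = 1e-10)
})

test_that("simulated fraction unfolded behaves like a stabilizing ligand", {
    sp <- mbpLikeSpec()
    expect_equal(simulateFractionUnfolded(sp, sp@Tm, 0), 0.5)
    ## strictly decreasing in ligand at fixed T
    L <- c(0, 10^seq(-7, -3, by = 0.5))
    fu <- simulateFractionUnfolded(sp, sp@Tm, L)
    expect_true(all(diff(fu) < 0))
    ## strictly increasing in T at zero ligand
    tk <- seq(sp@Tm - 10, sp@Tm + 10, by = 0.5)
    fu0 <- simulateFractionUnfolded(sp, tk, 0)
    expect_true(all(diff(fu0) > 0))
})

test_that("apparent midpoints shift right as the ladder increases", {
    me <- simulateDSF(mbpLikeSpec())
    tp <- temperatures(me)
    mids <- apply(signalValues(me), 2, function(y)
        tp[which.min(abs(y - 0.5))])
    lc <- ligandConc(me)
    o <- order(lc)
    expect_true(all(diff(mids[o]) >= 0))
    expect_gt(mids[o][length(mids)] - mids[o][1], 4)  # several degC span
    ## plateaus run 0 -> 1
    expect_lt(max(signalValues(me)[1, ]), 0.05)
    expect_gt(min(signalValues(me)[nrow(me), ]), 0.9)
})

test_that("noiseless simulation is deterministic regardless of seed", {
    a <- simulateDSF(simSpec(noiseSigma = 0, seed = 1L))
    b <- simulateDSF(simSpec(noiseSigma = 0, seed = 999L))
    expect_identical(signalValues(a), signalValues(b))
})

test_that("noise has the requested standard deviation and is seeded", {
    spN <- simSpec(noiseSigma = 0.05, seed = 7L)
    clean <- signalValues(simulateDSF(simSpec(noiseSigma = 0)))
    noisy <- signalValues(simulateDSF(spN, replicates = 8L))
    resid <- noisy - clean[, rep(seq_len(ncol(clean)), each = 8L)]
    expect_gt(length(resid), 1e4)
    expect_equal(sd(resid), 0.05, tolerance = 0.05)
    ## same seed reproduces; different seed does not
    expect_identical(noisy,
        signalValues(simulateDSF(spN, replicates = 8L)))
    expect_false(identical(noisy,
        signalValues(simulateDSF(simSpec(noiseSigma = 0.05, seed = 8L),
                                 replicates = 8L))))
})

test_that("raw-style emission passes through the dye baselines", {
    bl <- c(0.02, 1, -0.05, 9)
    spRaw <- simSpec(baselines = bl)
    me <- simulateDSF(spRaw)
    expect_false(isNormalized(me))
    tp <- temperatures(me)
    fu <- signalValues(simulateDSF(simSpec()))
    expect_equal(signalValues(me)[, 1],
                 oracleRawSignal(tp, fu[, 1], bl[1], bl[2], bl[3], bl[4]),
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("simulator slice fed to the isothermal fit recovers the truth", {
    sp <- mbpLikeSpec()
    L <- sp@ligandLadder
    fu <- simulateFractionUnfolded(sp, sp@Tm, L)
    bf <- fitIsothermal(isothermalDataset(50, L, fu,
                                          proteinConc = sp@Ptotal))
    expect_equal(bf@Kd * 1e6, 1, tolerance = 0.01)
    expect_equal(bf@KU, 1, tolerance = 0.01)
})
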