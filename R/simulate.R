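## Thermodynamic melt-curve simulator.
##
## Unfolding: Gibbs-Helmholtz with constant dCp_U, anchored so that
## dG_U(Tm) = 0 (K_U(Tm) = 1 by definition).
## Binding: integrated van't Hoff / Gibbs-Helmholtz with constant dCp_b,
## anchored at the ligand-free midpoint through the association free energy
## dG_b(Tm) = R Tm ln Kd(Tm):
##    dG_b(T) = dH_b + dCp_b (T - Tm)
##              - T [ (dH_b - dG_b(Tm))/Tm + dCp_b ln(T/Tm) ]
##    Kd(T)   = exp(dG_b(T) / RT)
## The fraction unfolded at (T, [L]_T) then comes from the same coupled
## equilibrium solver the fitter uses (fractionUnfoldedModel), so the
## simulator and the analysis share one oracle.

#' Construct a simulation specification
#'
#' Defaults describe an MBP-like system: ligand-free midpoint 50 deg C with
#' unfolding enthalpy 120 kcal/mol and heat-capacity change 4 kcal/mol/K;
#' exothermic binding (-10 kcal/mol, dCp_b = -0.5 kcal/mol/K) with
#' Kd = 1 uM at the midpoint; 2 uM total protein. The default ligand
#' ladder is zero plus an 11-point two-fold dilution from 500 uM down to
#' ~0.49 uM (12 concentrations); the default temperature grid spans the
#' midpoint +/- 15 deg C in 0.25 deg C increments.
#'
#' @param Tm ligand-free midpoint, deg C (converted to kelvin internally).
#' @param dHU unfolding enthalpy at Tm (kcal/mol).
#' @param dCpU unfolding heat-capacity change (kcal/mol/K).
#' @param dHb binding (association) enthalpy at Tm (kcal/mol).
#' @param dCpb binding heat-capacity change (kcal/mol/K).
#' @param KdTm dissociation constant at Tm (molar).
#' @param Ptotal total protein concentration (molar).
#' @param ligandLadder total ligand concentrations (molar).
#' @param tempGrid temperatures (deg C).
#' @param noiseSigma sd of Gaussian noise on the normalized signal.
#' @param seed integer seed controlling all noise.
#' @param baselines optional numeric(4) (mF, bF, mU, bU) to emit raw-style
#'   fluorescence instead of normalized fraction unfolded.
#' @return a [SimSpec-class].
#' @examples
#' simSpec()                       # the MBP-like reference parameter set
#' simSpec(noiseSigma = 0.05, seed = 7)
#' @export
simSpec <- function(Tm = 50, dHU = 120, dCpU = 4, dHb = -10, dCpb = -0.5,
                    KdTm = 1e-6, Ptotal = 2e-6,
                    ligandLadder = c(0, 500e-6 / 2^(10:0)),
                    tempGrid = seq(Tm - 15, Tm + 15, by = 0.25),
                    noiseSigma = 0, seed = 1L, baselines = numeric(0)) {
    methods::new("SimSpec", Tm = Tm + .C2K, dHU = dHU, dCpU = dCpU,
        dHb = dHb, dCpb = dCpb, KdTm = KdTm, Ptotal = Ptotal,
        ligandLadder = as.numeric(ligandLadder),
        tempGrid = as.numeric(tempGrid), noiseSigma = noiseSigma,
        seed = as.integer(seed), baselines = as.numeric(baselines))
}

#' Ligand-free unfolding constant at a temperature
#'
#' \eqn{K_U(T) = e^{-\Delta G_U(T)/RT}} with the Gibbs-Helmholtz
#' \eqn{\Delta G_U}. Equals 1 exactly at \code{spec@Tm}.
#'
#' @param spec a [SimSpec-class].
#' @param tempK absolute temperature(s), kelvin.
#' @return K_U(T), dimensionless.
#' @examples
#' kuAtTemperature(simSpec(), 323.15)  # 1
#' @export
kuAtTemperature <- function(spec, tempK) {
    stopifnot(methods::is(spec, "SimSpec"), all(tempK > 0))
    .thermoKU(tempK, spec@Tm, spec@dHU, spec@dCpU)
}

#' Dissociation constant at a temperature
#'
#' Integrated Gibbs-Helmholtz/van't Hoff temperature dependence of the
#' association free energy with constant \eqn{\Delta C_{p,b}}, anchored at
#' \eqn{\Delta G_b(T_m) = R T_m \ln K_d^{Tm}}; returns
#' \eqn{K_d(T) = e^{\Delta G_b(T)/RT}}. Equals \code{spec@KdTm} exactly at
#' \code{spec@Tm}; constant in temperature when both binding enthalpy and
#' heat-capacity change are zero.
#'
#' @inheritParams kuAtTemperature
#' @return K_d(T), molar.
#' @examples
#' kdAtTemperature(simSpec(), 323.15)  # 1e-6
#' @export
kdAtTemperature <- function(spec, tempK) {
    stopifnot(methods::is(spec, "SimSpec"), all(tempK > 0))
    Tm <- spec@Tm
    dGbTm <- .RGAS * Tm * log(spec@KdTm)
    dSb <- (spec@dHb - dGbTm) / Tm
    dGb <- spec@dHb + spec@dCpb * (tempK - Tm) -
        tempK * (dSb + spec@dCpb * log(tempK / Tm))
    exp(dGb / (.RGAS * tempK))
}

#' Noise-free fraction unfolded at one temperature and ligand concentration
#'
#' Couples [kuAtTemperature()] and [kdAtTemperature()] through the same
#' equilibrium solver the isothermal fitter uses
#' ([fractionUnfoldedModel()]).
#'
#' @inheritParams kuAtTemperature
#' @param Ltotal total ligand concentration(s), molar.
#' @return fraction(s) unfolded.
#' @examples
#' simulateFractionUnfolded(simSpec(), 323.15, 0)  # 0.5 at the midpoint
#' @export
simulateFractionUnfolded <- function(spec, tempK, Ltotal) {
    ku <- kuAtTemperature(spec, tempK)
    kd <- kdAtTemperature(spec, tempK)
    if (length(tempK) == 1L)
        return(fractionUnfoldedModel(Ltotal, spec@Ptotal, kd, ku))
    stopifnot(length(Ltotal) == 1L)
    vapply(seq_along(tempK), function(i)
        fractionUnfoldedModel(Ltotal, spec@Ptotal, kd[i], ku[i]),
        numeric(1))
}

#' Simulate a family of DSF melt curves
#'
#' One curve per ladder entry (times \code{replicates}) over the
#' specification's temperature grid. Noise, when requested, is i.i.d.
#' Gaussian added on the normalized (0-1) scale; when baseline parameters
#' are present the noisy normalized signal is then mapped through the dye
#' baselines so the emitted raw signal carries proportional noise. All
#' randomness is controlled by \code{spec@seed}; with \code{noiseSigma = 0}
#' the output is bit-identical across runs regardless of seed.
#'
#' @param spec a [SimSpec-class].
#' @param replicates wells per ladder entry (default 1).
#' @return a [MeltExperiment-class]; wells are named
#'   \code{L<ladder index><replicate letter>} and \code{replicate_group}
#'   groups replicates of the same concentration.
#' @examples
#' me <- simulateDSF(simSpec())
#' dim(me)
#' @export
simulateDSF <- function(spec, replicates = 1L) {
    stopifnot(methods::is(spec, "SimSpec"), replicates >= 1L)
    methods::validObject(spec)
    tC <- spec@tempGrid
    tK <- tC + .C2K
    ku <- kuAtTemperature(spec, tK)
    kd <- kdAtTemperature(spec, tK)
    ladder <- spec@ligandLadder
    nL <- length(ladder)
    clean <- vapply(seq_len(nL), function(j)
        vapply(seq_along(tK), function(i)
            fractionUnfoldedModel(ladder[j], spec@Ptotal, kd[i], ku[i]),
            numeric(1)),
        numeric(length(tK)))
    if (replicates > 1L)
        clean <- clean[, rep(seq_len(nL), each = replicates), drop = FALSE]
    wellLadder <- rep(ladder, each = replicates)
    repGroup <- rep(seq_len(nL), each = replicates)
    wells <- sprintf("L%02d%s", repGroup,
                     rep(letters[seq_len(replicates)], nL))
    colnames(clean) <- wells

    sig <- clean
    if (spec@noiseSigma > 0) {
        ## one seed drives everything; per-curve substreams are consecutive
        ## column-wise draws, hence deterministic in column order
        set.seed(spec@seed)
        sig <- sig + matrix(stats::rnorm(length(sig), 0, spec@noiseSigma),
                            nrow = nrow(sig))
        colnames(sig) <- wells
    }
    raw <- length(spec@baselines) == 4L
    if (raw) {
        bl <- spec@baselines
        sig <- apply(sig, 2, .mixBaselines, tempC = tC, mF = bl[1],
                     bF = bl[2], mU = bl[3], bU = bl[4])
        colnames(sig) <- wells
    }
    MeltExperiment(sig, tC, wellLadder, replicateGroup = repGroup,
                   normalized = !raw)
}
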