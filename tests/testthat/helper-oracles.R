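## Independent oracles used across the suite. These deliberately do not
## call package internals for the quantity they check.

RGAS <- 1.987204e-3

## Two-state Gibbs-Helmholtz fraction unfolded, written out directly from
## the model definition (generator-first oracle for the curve fitters).
oracleThermoFu <- function(tempC, TmK, dHU, dCpU) {
    tk <- tempC + 273.15
    dG <- dHU * (1 - tk / TmK) - dCpU * (TmK - tk + tk * log(tk / TmK))
    ku <- exp(-dG / (RGAS * tk))
    ku / (1 + ku)
}

## Raw-style signal: baselines mixed by the fraction unfolded.
oracleRawSignal <- function(tempC, fu, mF, bF, mU, bU)
    (1 - fu) * (mF * tempC + bF) + fu * (mU * tempC + bU)

## Free-ligand concentration by brute-force numeric root extraction from
## the mass-balance quadratic (independent of the package's closed form).
oracleFreeLigand <- function(Ltotal, Ptotal, Kd, KU) {
    if (Ltotal == 0) return(0)
    r <- polyroot(c(-Ltotal * Kd * (1 + KU),
                    Ptotal - Ltotal + Kd * (1 + KU), 1))
    r <- Re(r[abs(Im(r)) < 1e-8 * Mod(r)])
    r[r >= 0 & r <= Ltotal * (1 + 1e-12)][1]
}

## Reconstruct all species from a free-ligand value and check the two
## conservation laws; returns the worst relative residual.
massBalanceResidual <- function(L, Ltotal, Ptotal, Kd, KU) {
    FL <- Ltotal - L
    Fc <- Kd * FL / L          # from Kd = [F][L]/[FL]
    U  <- KU * Fc
    max(abs(Fc + U + FL - Ptotal) / Ptotal,
        abs(L + FL - Ltotal) / max(Ltotal, .Machine$double.eps))
}

## Reference (Fig-like) simulation conditions reused by several tests.
mbpLikeSpec <- function(...) simSpec(...)
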