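## Coupled folding/binding equilibria at a single temperature.
##
## Scheme: U + L <-> F + L <-> FL, with K_U = [U]/[F] (ligand-free
## unfolding) and K_d = [F][L]/[FL] (unbinding). With total protein [P]_T
## and total ligand [L]_T, the free ligand concentration is the positive
## root of
##    [L]^2 + ([P]_T - [L]_T + K_d(1+K_U))[L] - [L]_T K_d (1+K_U) = 0
## and the fraction unfolded is
##    f_u = 1 / (1 + (1/K_U)(1 + [L]/K_d)).

#' Free ligand concentration in the coupled equilibrium
#'
#' Unique nonnegative root of the ligand mass-balance quadratic, evaluated
#' in a cancellation-safe form. Vectorized over \code{Ltotal}.
#'
#' @param Ltotal total ligand concentration(s), molar.
#' @param Ptotal total protein concentration, molar.
#' @param Kd dissociation constant (molar), > 0.
#' @param KU ligand-free unfolding constant at this temperature, >= 0.
#' @return free ligand concentration(s) in \code{[0, Ltotal]}, molar.
#' @examples
#' freeLigand(10e-6, 2e-6, 1e-6, 1)
#' freeLigand(0, 2e-6, 1e-6, 1)   # no ligand -> no free ligand
#' @export
freeLigand <- function(Ltotal, Ptotal, Kd, KU) {
    if (any(Ltotal < 0) || Ptotal < 0 || Kd <= 0 || KU < 0)
        stop("freeLigand: concentrations must be nonnegative and Kd > 0")
    keff <- Kd * (1 + KU)     # effective Kd: only folded protein binds
    b <- Ptotal - Ltotal + keff
    cc <- Ltotal * keff
    disc <- sqrt(b^2 + 4 * cc)
    ## root = (-b + disc)/2; rewrite via the conjugate when b > 0 to avoid
    ## catastrophic cancellation at Ltotal << Ptotal + keff
    ifelse(b > 0, 2 * cc / (b + disc), (disc - b) / 2)
}

#' Fraction unfolded under the coupled folding/binding model
#'
#' Evaluates the two-parameter isothermal model at total ligand
#' concentration(s): free ligand from [freeLigand()], then
#' \eqn{f_u = 1/(1 + (1/K_U)(1 + [L]/K_d))}. At zero ligand this reduces
#' to \eqn{f_{u0} = K_U/(1+K_U)}; as \eqn{[L]_T \to \infty} it tends to 0
#' (ligand pulls the equilibrium toward the folded, bound state).
#'
#' @inheritParams freeLigand
#' @return fraction(s) unfolded in (0, 1).
#' @examples
#' fractionUnfoldedModel(0, 2e-6, 1e-6, 1)       # 0.5
#' fractionUnfoldedModel(1e-3, 2e-6, 1e-6, 1)    # ~ 0
#' @export
fractionUnfoldedModel <- function(Ltotal, Ptotal, Kd, KU) {
    if (KU <= 0) stop("fractionUnfoldedModel: KU must be positive")
    L <- freeLigand(Ltotal, Ptotal, Kd, KU)
    1 / (1 + (1 / KU) * (1 + L / Kd))
}

#' EC50 implied by the coupled-equilibrium model
#'
#' Closed form: \eqn{EC_{50} = K_d/(1-f_{u0}) + [P]_T/2}. The EC50 is the
#' total ligand concentration at which the fraction unfolded is half its
#' zero-ligand value; the relation is exact under the model (no free-ligand
#' approximation involved). In the tight-binding limit \eqn{K_d \to 0} the
#' EC50 tends to \eqn{[P]_T/2}: stoichiometry, not affinity, sets the
#' midpoint.
#'
#' @param Kd dissociation constant (molar), > 0.
#' @param Ptotal total protein concentration (molar).
#' @param fu0 fraction unfolded at zero ligand, in [0, 1).
#' @return EC50 (molar).
#' @examples
#' ec50FromKd(0.5e-6, 2e-6, 0.5)   # 2e-6
#' @export
ec50FromKd <- function(Kd, Ptotal, fu0) {
    stopifnot(Kd > 0, Ptotal >= 0)
    if (any(fu0 < 0 | fu0 >= 1))
        stop("ec50FromKd: fu0 must lie in [0, 1); at fu0 = 1 the protein is fully unfolded and no binding signal exists")
    Kd / (1 - fu0) + Ptotal / 2
}

#' Dissociation constant from an observed EC50
#'
#' Inverse of [ec50FromKd()]: \eqn{K_d = (1-f_{u0})(EC_{50} - [P]_T/2)}.
#' Requires \eqn{EC_{50} > [P]_T/2}; below that bound the midpoint is set
#' by stoichiometry and the dissociation constant is not identifiable.
#'
#' @param EC50 observed EC50 (molar).
#' @inheritParams ec50FromKd
#' @return Kd (molar).
#' @examples
#' kdFromEC50(6.8e-6, 2e-6, 1.3 / 2.3) * 1e6   # 2.5 uM
#' @export
kdFromEC50 <- function(EC50, Ptotal, fu0) {
    if (any(fu0 < 0 | fu0 >= 1))
        stop("kdFromEC50: fu0 must lie in [0, 1)")
    if (any(EC50 <= Ptotal / 2))
        stop(structure(class = c("isoDSF_stoichiometric", "error",
                                 "condition"),
            list(message = "EC50 <= [P]_T/2: stoichiometric regime, Kd not identifiable", call = NULL)))
    (1 - fu0) * (EC50 - Ptotal / 2)
}

.flatError <- function() {
    stop(structure(class = c("isoDSF_flat_data", "error", "condition"),
        list(message = "fraction unfolded does not change with ligand concentration: the ligand does not stabilize the protein at this temperature",
             call = NULL)))
}

#' Quick EC50 estimate by four-parameter logistic fit
#'
#' Fits an arbitrary 4-parameter logistic in log10 total ligand
#' concentration (the zero-ligand point is placed two decades below the
#' smallest nonzero dose) and returns the concentration at which the fitted
#' curve crosses half its low-concentration plateau. This is a quick,
#' model-free midpoint estimate used to seed the rigorous fit; it is not a
#' substitute for [fitIsothermal()].
#'
#' @param data an [IsothermalDataset-class]; the fraction unfolded must
#'   decrease with ligand overall.
#' @return list with \code{EC50} (molar), \code{fu0} (the fitted
#'   low-concentration plateau) and \code{coefficients}. A midpoint outside
#'   the tested ladder triggers a warning.
#' @export
ec50Hill <- function(data) {
    stopifnot(methods::is(data, "IsothermalDataset"))
    L <- data@ligandConc; fu <- data@fu
    if (diff(range(fu)) < 1e-3) .flatError()
    nz <- L[L > 0]
    if (!length(nz)) stop("ec50Hill: need at least one nonzero dose")
    pseudo <- min(nz) / 100
    x <- log10(pmax(L, pseudo))
    o <- order(x)
    top0 <- max(fu); bot0 <- min(fu)
    mid0 <- x[o][which.min(abs(fu[o] - (top0 + bot0) / 2))]
    par0 <- c(top = top0, bottom = bot0, logMid = mid0, hill = 1)
    resid <- function(p)
        fu - (p[2] + (p[1] - p[2]) / (1 + 10^(p[4] * (x - p[3]))))
    fit <- minpack.lm::nls.lm(par0,
        lower = c(-Inf, -Inf, -Inf, 1e-3), upper = rep(Inf, 4),
        resid, control = .lmControl())
    if (!fit$info %in% 1:4)
        stop(structure(class = c("isoDSF_fit_error", "error", "condition"),
            list(message = paste("logistic fit failed:", fit$message),
                 call = NULL)))
    p <- fit$par
    ## concentration where the curve crosses top/2
    half <- p[1] / 2
    if (half <= p[2]) {
        warning("lower plateau above half the zero-ligand plateau; midpoint extrapolated", call. = FALSE)
        u <- 1e6
    } else u <- (p[1] - p[2]) / (half - p[2]) - 1
    xmid <- p[3] + log10(u) / p[4]
    ec50 <- 10^xmid
    if (ec50 < min(nz) || ec50 > max(L))
        warning("estimated EC50 lies outside the tested ligand ladder",
                call. = FALSE)
    list(EC50 = unname(ec50), fu0 = unname(p[1]),
         coefficients = stats::setNames(unname(p),
             c("top", "bottom", "logMid", "hill")))
}

#' Fit the coupled folding/binding model to an isothermal slice
#'
#' Weighted least squares of [fractionUnfoldedModel()] against fraction
#' unfolded versus total ligand concentration at one temperature. The two
#' free parameters (\eqn{K_d}, \eqn{K_U}) are fit on the log10 scale to
#' enforce positivity; weights are \eqn{1/\mathrm{sem}^2} when replicate
#' standard errors are available and positive, otherwise unweighted.
#' Starting values are data-driven: \eqn{K_U} from the zero-ligand point,
#' \eqn{K_d} from the logistic midpoint via the closed-form EC50 relation.
#'
#' When the fitted EC50 does not exceed the total protein concentration
#' the result is flagged as stoichiometric-regime and the upper bound
#' \eqn{K_d < (1-f_{u0})[P]_T/2} is reported alongside the point estimate.
#'
#' @param data an [IsothermalDataset-class] with >= 4 distinct ligand
#'   concentrations (>= 2 when \code{fixKU} is supplied), including a
#'   zero-ligand point unless \code{fixKU} is given.
#' @param fixKU optional externally determined unfolding constant (e.g.
#'   from the ligand-free melt curve); when supplied only \eqn{K_d} is fit.
#' @param flatTol minimum spread in fraction unfolded required to attempt
#'   a fit.
#' @return a [BindingFit-class].
#' @examples
#' L <- c(0, 2^(0:9) * 1e-6)
#' fu <- fractionUnfoldedModel(L, 2e-6, 1e-6, 1)
#' fitIsothermal(isothermalDataset(50, L, fu, proteinConc = 2e-6))
#' @export
fitIsothermal <- function(data, fixKU = NULL, flatTol = 0.02) {
    stopifnot(methods::is(data, "IsothermalDataset"))
    L <- data@ligandConc; fu <- data@fu; P <- data@proteinConc
    nDistinct <- length(unique(L))
    fitKU <- is.null(fixKU) || is.na(fixKU)
    if (fitKU && nDistinct < 4L)
        stop("need >= 4 distinct ligand concentrations for the 2-parameter fit")
    if (!fitKU && nDistinct < 2L)
        stop("need >= 2 distinct ligand concentrations")
    if (fitKU && !any(L == 0))
        stop("need a zero-ligand point, or supply fixKU from the ligand-free melt curve")
    if (diff(range(fu)) < flatTol) .flatError()

    w <- if (all(is.finite(data@sem)) && all(data@sem > 0))
        1 / data@sem^2 else rep(1, length(fu))
    sw <- sqrt(w)

    ## data-driven starts
    ku0 <- if (!fitKU) fixKU else {
        f0 <- mean(fu[L == 0])
        f0 <- min(max(f0, 0.02), 0.98)
        f0 / (1 - f0)
    }
    kd0 <- tryCatch({
        h <- suppressWarnings(ec50Hill(data))
        kdFromEC50(h$EC50, P, min(max(h$fu0, 0), 0.99))
    }, error = function(e) NA_real_)
    if (!is.finite(kd0) || kd0 <= 0)
        kd0 <- max(stats::median(L[L > 0]), P / 2)

    model <- function(lkd, lku)
        fractionUnfoldedModel(L, P, 10^lkd, 10^lku)
    if (fitKU) {
        par0 <- c(lkd = log10(kd0), lku = log10(ku0))
        resid <- function(p) sw * (fu - model(p[1], p[2]))
    } else {
        par0 <- c(lkd = log10(kd0))
        resid <- function(p) sw * (fu - model(p[1], log10(fixKU)))
    }
    fit <- minpack.lm::nls.lm(par0, fn = resid, control = .lmControl())
    if (!fit$info %in% 1:4)
        stop(structure(class = c("isoDSF_fit_error", "error", "condition"),
            list(message = paste("isothermal fit failed:", fit$message),
                 call = NULL)))
    p <- fit$par
    Kd <- 10^p[1]
    KU <- if (fitKU) 10^p[2] else fixKU
    fu0 <- KU / (1 + KU)

    ## standard errors on the log10 scale from the residual Jacobian,
    ## mapped to the linear scale by the delta method
    np <- length(p); n <- length(fu)
    se <- rep(NA_real_, np)
    if (n > np) {
        J <- .numJacobian(resid, p)
        s2 <- fit$deviance / (n - np)
        covm <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
        if (!is.null(covm)) se <- sqrt(pmax(diag(covm), 0))
    }
    KdSE <- log(10) * Kd * se[1]
    KUSE <- if (fitKU) log(10) * KU * se[2] else 0
    EC50 <- ec50FromKd(Kd, P, fu0)
    ## delta method for EC50 = Kd/(1-fu0) + P/2 = Kd(1+KU) + P/2 in
    ## (log10 Kd, log10 KU): gradient (ln10 Kd (1+KU), ln10 Kd KU)
    EC50SE <- if (fitKU && all(is.finite(se)) && exists("covm") &&
                  !is.null(covm)) {
        g <- c(log(10) * Kd * (1 + KU), log(10) * Kd * KU)
        sqrt(drop(t(g) %*% covm %*% g))
    } else if (!fitKU && is.finite(KdSE)) KdSE * (1 + fu0 / (1 - fu0))
    else NA_real_

    stoich <- EC50 <= P
    methods::new("BindingFit",
        Kd = unname(Kd), KU = unname(KU), fu0 = unname(fu0),
        EC50 = unname(EC50), KdSE = unname(KdSE), KUSE = unname(KUSE),
        EC50SE = unname(EC50SE), stoichiometricRegime = unname(stoich),
        kdUpperBound = if (stoich) unname((1 - fu0) * P / 2) else NA_real_,
        KUFixed = !fitKU, converged = TRUE,
        residNorm = sqrt(fit$deviance), nPoints = length(fu),
        temperature = data@temperature, proteinConc = P)
}

## forward-difference Jacobian of a residual function
.numJacobian <- function(f, p, eps = 1e-6) {
    f0 <- f(p)
    J <- matrix(0, length(f0), length(p))
    for (k in seq_along(p)) {
        h <- eps * max(abs(p[k]), 1)
        pk <- p; pk[k] <- pk[k] + h
        J[, k] <- (f(pk) - f0) / h
    }
    J
}
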