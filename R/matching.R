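#' Total cone excitation produced by a spectrum
#'
#' The inner product of an SPD with a cone sensitivity: the products are
#' summed over the grid and scaled by the sample spacing
#' (sum spd * cone * step), all in energy units.
#'
#' @param spd a [Spectrum-class]
#' @param cone a [ConeSensitivity-class] on the same grid
#' @return scalar excitation >= 0 (arbitrary energy units)
#' @export
coneExcitation <- function(spd, cone) {
    stopIfGridMismatch(spd, cone, "spd and cone")
    sum(spd@values * cone@values) * gridStep(spd)
}

# Per (instrument, observer) scalars: excitation of each cone by each
# channel's peak-normalized SPD. Everything downstream is linear in these,
# so match solving reduces to scalar arithmetic in the control setting.
channelExcitations <- function(instrument, observer) {
    list(
        aRed = coneExcitation(instrument@red@spd, observer@coneA),
        bRed = coneExcitation(instrument@red@spd, observer@coneB),
        aGreen = coneExcitation(instrument@green@spd, observer@coneA),
        bGreen = coneExcitation(instrument@green@spd, observer@coneB),
        aAmber = coneExcitation(instrument@amber@spd, observer@coneA),
        bAmber = coneExcitation(instrument@amber@spd, observer@coneB),
        rCurve = instrument@red@outputCurve,
        gCurve = instrument@green@outputCurve)
}

mixtureExcitations <- function(ce, lam) {
    r <- ce$rCurve(lam)
    g <- ce$gCurve(lam)
    list(a = r * ce$aRed + g * ce$aGreen, b = r * ce$bRed + g * ce$bGreen)
}

#' Cone-excitation ratio curve over the mixture range
#'
#' Evaluates both cones' total excitations and their ratio (numerator =
#' coneA: L/M for normals, M'/M for protans, L/L' for deutans) on a
#' uniform grid of mixture settings. Settings where the denominator
#' excitation vanishes are flagged in the `flagged` column, not dropped.
#'
#' @param instrument an [Instrument-class]
#' @param observer an [Observer-class]
#' @param nPoints number of settings (>= 2)
#' @return data.frame with columns `lambda`, `excitationA`, `excitationB`,
#'   `ratio`, `flagged`
#' @export
excitationRatioCurve <- function(instrument, observer, nPoints = 101) {
    if (nPoints < 2) rmStop("nPoints must be >= 2", "badArgument")
    cr <- instrument@controlRange
    lams <- seq(cr[1], cr[2], length.out = nPoints)
    ce <- channelExcitations(instrument, observer)
    r <- vapply(lams, ce$rCurve, numeric(1))
    g <- vapply(lams, ce$gCurve, numeric(1))
    excA <- r * ce$aRed + g * ce$aGreen
    excB <- r * ce$bRed + g * ce$bGreen
    flagged <- excB <= 0 | excA <= 0
    ratio <- ifelse(flagged, NA_real_, excA / excB)
    data.frame(lambda = lams, excitationA = excA, excitationB = excB,
               ratio = ratio, flagged = flagged)
}

#' Cone-excitation ratio of the amber reference field
#'
#' The amber field elicits a fixed coneA/coneB excitation ratio that is
#' independent of the amber intensity (intensity scales both excitations
#' equally, so it cancels).
#'
#' @param instrument an [Instrument-class]
#' @param observer an [Observer-class]
#' @param amberIntensity any positive intensity (the result does not
#'   depend on it)
#' @return dimensionless ratio > 0
#' @export
referenceRatio <- function(instrument, observer, amberIntensity = 1) {
    if (amberIntensity <= 0)
        rmStop("amberIntensity must be > 0", "badArgument")
    spd <- referenceSpd(instrument, amberIntensity)
    a <- coneExcitation(spd, observer@coneA)
    b <- coneExcitation(spd, observer@coneB)
    if (b <= 0) rmStop("amber field produces zero denominator excitation",
                       "degenerateField")
    a / b
}

#' Predict the Rayleigh match
#'
#' Finds the mixture setting at which the observer's cone-excitation
#' ratio for the mixture field equals the fixed ratio elicited by the
#' amber field — graphically, the intersection of the ratio curve with
#' the amber's horizontal line. Solved by a 64-point bracketing scan of
#' f(lambda) = log ratio_mix(lambda) - log ratio_amber followed by
#' bisection to |f| <= 1e-8. If several sign changes exist (possible with
#' exotic configurations) the one nearest the midpoint of the control
#' range is solved and a note is attached.
#'
#' @param instrument an [Instrument-class]
#' @param observer an [Observer-class]
#' @param amberIntensity positive amber intensity; the prediction is
#'   invariant to it
#' @return a [MatchPrediction-class]
#' @examples
#' penn <- makeInstrument("penn")
#' lambdaStar(predictMatch(penn, makeNormalObserver()))
#' @export
predictMatch <- function(instrument, observer, amberIntensity = 1) {
    ce <- channelExcitations(instrument, observer)
    if (ce$bAmber <= 0 || ce$aAmber <= 0)
        rmStop("amber field produces zero cone excitation", "degenerateField")
    amberRatio <- (amberIntensity * ce$aAmber) / (amberIntensity * ce$bAmber)
    f <- function(lam) {
        e <- mixtureExcitations(ce, lam)
        if (e$a <= 0 || e$b <= 0) return(NA_real_)
        log(e$a / e$b) - log(amberRatio)
    }
    cr <- instrument@controlRange
    scan <- seq(cr[1], cr[2], length.out = 64)
    fs <- vapply(scan, f, numeric(1))
    ok <- which(!is.na(fs))
    if (length(ok) < 2)
        rmStop("mixture field excitations vanish over the control range",
               "degenerateField")
    if (all(abs(fs[ok]) < 1e-12))
        rmStop("degenerate observer: the two cones are identical, every setting matches",
               "degenerateMatch")
    sgn <- sign(fs[ok])
    cross <- which(sgn[-length(sgn)] * sgn[-1] <= 0 & sgn[-length(sgn)] != 0)
    notes <- character(0)
    if (length(cross) == 0) {
        rmStop(sprintf(
            "no match in range: log-ratio difference has sign %+d at lambda=%g and %+d at lambda=%g",
            sign(fs[ok][1]), scan[ok[1]], sign(fs[ok][length(ok)]),
            scan[ok[length(ok)]]), "noMatchInRange",
            signLow = sign(fs[ok][1]), signHigh = sign(fs[ok][length(ok)]))
    }
    if (length(cross) > 1) {
        notes <- c(notes, sprintf("%d sign changes found; solving the one nearest the range midpoint",
                                  length(cross)))
        mid <- mean(cr)
        centers <- (scan[ok[cross]] + scan[ok[cross + 1]]) / 2
        cross <- cross[which.min(abs(centers - mid))]
    }
    lo <- scan[ok[cross]]; hi <- scan[ok[cross + 1]]
    flo <- fs[ok[cross]]; fhi <- fs[ok[cross + 1]]
    inBr <- scan >= lo & scan <= hi
    if (any(diff(fs[inBr]) > 0) && any(diff(fs[inBr]) < 0))
        notes <- c(notes, "log-ratio difference is not monotone over the bracket")
    bracket <- c(lo, hi)
    iter <- 0L
    fmid <- flo
    mid <- lo
    while (iter < 200L) {
        mid <- (lo + hi) / 2
        fmid <- f(mid)
        iter <- iter + 1L
        if (is.na(fmid)) rmStop("excitation vanished inside the bracket",
                                "degenerateField")
        if (abs(fmid) <= 1e-8 || (hi - lo) / 2 < 1e-13 * max(1, abs(hi)))
            break
        if (sign(fmid) == sign(flo)) { lo <- mid; flo <- fmid }
        else { hi <- mid; fhi <- fmid }
    }
    e <- mixtureExcitations(ce, mid)
    new("MatchPrediction", lambdaStar = mid, amberRatio = amberRatio,
        mixtureRatioAtMatch = e$a / e$b, bracket = bracket,
        solverIterations = iter, notes = notes)
}

#' Match-prediction accessors
#' @param x a [MatchPrediction-class] or [MatchingRange-class]
#' @return `lambdaStar`: the matched setting; `matchNotes`: solver notes.
#' @name match-accessors
NULL

#' @rdname match-accessors
#' @export
lambdaStar <- function(x) x@lambdaStar

#' @rdname match-accessors
#' @export
matchNotes <- function(x) x@notes

#' Brute-force grid-search match (oracle)
#'
#' Exhaustively evaluates the absolute log-ratio difference between the
#' mixture and amber fields on a uniform grid of settings and returns the
#' minimizing setting (ties: the smallest). Computes the mixture SPD
#' explicitly at every grid setting — an independent check on the
#' bracketing solver of [predictMatch()].
#'
#' @param instrument an [Instrument-class]
#' @param observer an [Observer-class]
#' @param resolution grid spacing on the control scale (default 1e-3)
#' @return the minimizing setting (scalar)
#' @export
bruteForceMatch <- function(instrument, observer, resolution = 1e-3) {
    if (resolution <= 0) rmStop("resolution must be > 0", "badArgument")
    cr <- instrument@controlRange
    lams <- seq(cr[1], cr[2], by = resolution)
    rOut <- vapply(lams, instrument@red@outputCurve, numeric(1))
    gOut <- vapply(lams, instrument@green@outputCurve, numeric(1))
    # explicit mixture SPDs, vectorized as a wavelength x setting matrix
    M <- outer(instrument@red@spd@values, rOut) +
        outer(instrument@green@spd@values, gOut)
    step <- gridStep(instrument@red@spd)
    excA <- as.vector(observer@coneA@values %*% M) * step
    excB <- as.vector(observer@coneB@values %*% M) * step
    amber <- referenceSpd(instrument, 1)
    target <- log(coneExcitation(amber, observer@coneA) /
                  coneExcitation(amber, observer@coneB))
    d <- abs(log(excA / excB) - target)
    d[!is.finite(d)] <- Inf
    lams[which.min(d)]  # which.min takes the first (smallest lambda) on ties
}

#' Accepted matching range around the predicted match
#'
#' The connected interval of settings around lambda* where the absolute
#' log-ratio difference from the amber field stays within `delta` (a
#' Weber-like tolerance standing for the observer's acceptance window).
#' `touchesEnd` reports whether the interval reaches an end of the control
#' range — the signature of the "extreme anomalous" observer.
#'
#' @param instrument an [Instrument-class]
#' @param observer an [Observer-class]
#' @param delta log-ratio tolerance >= 0 (default 0.01)
#' @param resolution scan resolution on the control scale, as a fraction
#'   of the range (default 1e-4)
#' @return a [MatchingRange-class]
#' @export
matchingRange <- function(instrument, observer, delta = 0.01,
                          resolution = 1e-4) {
    if (delta < 0) rmStop("delta must be >= 0", "badArgument")
    pred <- predictMatch(instrument, observer)
    lamStar <- pred@lambdaStar
    if (delta == 0)
        return(new("MatchingRange", lambdaLo = lamStar, lambdaHi = lamStar,
                   lambdaStar = lamStar, delta = 0, touchesEnd = FALSE))
    ce <- channelExcitations(instrument, observer)
    cr <- instrument@controlRange
    absf <- function(lam) {
        e <- mixtureExcitations(ce, lam)
        if (e$a <= 0 || e$b <= 0) return(Inf)
        abs(log(e$a / e$b) - log(pred@amberRatio))
    }
    step <- diff(cr) * resolution
    walk <- function(dir) {
        lam <- lamStar
        end <- if (dir > 0) cr[2] else cr[1]
        repeat {
            nxt <- lam + dir * step
            if ((dir > 0 && nxt >= end) || (dir < 0 && nxt <= end)) {
                if (absf(end) <= delta) return(c(end, TRUE))
                return(c(lam, FALSE))
            }
            if (absf(nxt) > delta) return(c(lam, FALSE))
            lam <- nxt
        }
    }
    up <- walk(1)
    dn <- walk(-1)
    new("MatchingRange", lambdaLo = dn[1], lambdaHi = up[1],
        lambdaStar = lamStar, delta = delta,
        touchesEnd = up[2] > 0 || dn[2] > 0)
}

#' @rdname match-accessors
#' @export
touchesEnd <- function(x) x@touchesEnd

#' @rdname match-accessors
#' @export
rangeWidth <- function(x) x@lambdaHi - x@lambdaLo

#' Amber intensity equating total excitation with the mixture field
#'
#' Solves for the amber control value at which the summed two-cone
#' excitation of the amber field equals that of the mixture field at the
#' given setting — the brightness dimension of the match. The amber
#' excitation is linear in intensity, so the solution is exact; values
#' outside the amber range are clamped and flagged via the `"clamped"`
#' attribute.
#'
#' @param instrument an [Instrument-class]
#' @param observer an [Observer-class]
#' @param lambdaSetting mixture setting, within the control range
#' @return amber intensity (scalar) with attribute `clamped` (logical)
#' @export
brightnessMatchIntensity <- function(instrument, observer, lambdaSetting) {
    ce <- channelExcitations(instrument, observer)
    e <- mixtureExcitations(ce, lambdaSetting)
    cr <- instrument@controlRange
    if (lambdaSetting < cr[1] - 1e-12 || lambdaSetting > cr[2] + 1e-12)
        rmStop("lambdaSetting outside the control range", "settingOutOfRange")
    perUnit <- ce$aAmber + ce$bAmber
    if (perUnit <= 0) rmStop("amber field excites neither cone", "degenerateField")
    intensity <- (e$a + e$b) / perUnit
    ar <- instrument@amberRange
    clamped <- intensity < ar[1] || intensity > ar[2]
    structure(min(max(intensity, ar[1]), ar[2]),
              clamped = clamped, rawIntensity = intensity)
}
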