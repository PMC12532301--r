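#' A1 visual-pigment absorbance template
#'
#' The standard rhodopsin (A1) absorbance nomogram of Govardovskii and
#' colleagues: an alpha band that is a fixed shape in the normalized
#' variable x = lambda_max / lambda, with an optional beta (cis) band.
#' Evaluating it at a choice of lambda_max yields a peak-normalized
#' pigment absorbance spectrum. The beta band is off by default: it lies
#' below 450 nm where lens screening suppresses it, it never reaches the
#' Rayleigh range, and omitting it keeps the template strictly unimodal
#' under frequency shifts.
#'
#' @param lambdaMaxNm peak wavelength of the alpha band (nm)
#' @param grid a [WavelengthGrid-class]
#' @param betaBand include the beta (cis) band (default FALSE)
#' @return numeric vector of normalized absorbance over the grid
#' @export
pigmentTemplate <- function(lambdaMaxNm, grid = defaultGrid(), betaBand = FALSE) {
    wl <- wavelengths(grid)
    x <- lambdaMaxNm / wl
    a <- 0.8795 + 0.0459 * exp(-(lambdaMaxNm - 300)^2 / 11940)
    alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
    v <- alpha
    if (betaBand) {
        lmb <- 189 + 0.315 * lambdaMaxNm
        b <- -40.5 + 0.195 * lambdaMaxNm
        v <- v + 0.26 * exp(-((wl - lmb) / b)^2)
    }
    v / max(v)
}

#' Smooth model of 2-degree pre-receptoral densities
#'
#' Lens and macular pigment optical densities for a standard 2-degree
#' observer, as smooth parametric shapes: an exponential decay for the
#' lens (about 1.8 log units at 400 nm falling to near zero beyond 600 nm)
#' and a Gaussian centered at 460 nm for the macular pigment (peak density
#' 0.35, negligible above 550 nm, hence negligible throughout the Rayleigh
#' range). [readPrereceptoralCsv()] loads tabulated templates instead when
#' available.
#'
#' @param grid a [WavelengthGrid-class]
#' @param lensScale lens density at 400 nm (default 1.765)
#' @param macularPeak macular density at 460 nm (default 0.35)
#' @return a [PrereceptoralFilter-class]
#' @export
prereceptoralTemplate <- function(grid = defaultGrid(), lensScale = 1.765,
                                  macularPeak = 0.35) {
    wl <- wavelengths(grid)
    lens <- lensScale * exp(-(wl - 400) / 45)
    lens[wl < 400] <- lensScale * exp((400 - wl[wl < 400]) / 60)
    mac <- macularPeak * exp(-((wl - 460) / 26)^2)
    mac[mac < 1e-12] <- 0
    new("PrereceptoralFilter", grid = grid, lensDensity = lens,
        macularDensity = mac)
}

#' Read pre-receptoral densities from CSV
#'
#' Expects columns `wavelength_nm,lens_density,macular_density`.
#'
#' @param path file path
#' @param grid target [WavelengthGrid-class] (file is interpolated onto it)
#' @return a [PrereceptoralFilter-class]
#' @export
readPrereceptoralCsv <- function(path, grid = defaultGrid()) {
    df <- utils::read.csv(path, check.names = FALSE)
    need <- c("wavelength_nm", "lens_density", "macular_density")
    if (!all(need %in% names(df)))
        rmStop(sprintf("%s: need columns %s", path, paste(need, collapse = ", ")),
               "malformedCsv")
    wl <- wavelengths(grid)
    interp <- function(col) {
        v <- stats::approx(df$wavelength_nm, df[[col]], xout = wl, rule = 2)$y
        pmax(v, 0)
    }
    mac <- interp("macular_density")
    mac[wl > 550 & mac < 0.01] <- pmin(mac[wl > 550 & mac < 0.01], 0.009999)
    new("PrereceptoralFilter", grid = grid, lensDensity = interp("lens_density"),
        macularDensity = mac)
}

#' Write pre-receptoral densities to CSV
#' @param pre a [PrereceptoralFilter-class]
#' @param path file path
#' @return `path`, invisibly
#' @export
writePrereceptoralCsv <- function(pre, path) {
    utils::write.csv(data.frame(wavelength_nm = wavelengths(pre@grid),
                                lens_density = pre@lensDensity,
                                macular_density = pre@macularDensity),
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

newConeSensitivity <- function(grid, values, label) {
    v <- as.numeric(values)
    v[v < 0] <- 0
    new("ConeSensitivity", grid = grid, values = v / max(v), label = label)
}

#' Build normal cone fundamentals
#'
#' Constructs the L, M, S corneal sensitivities of the normal observer.
#' In `"nomogram"` mode each fundamental is the A1 pigment template at its
#' lambda_max, screened by the pre-receptoral densities
#' (template x 10^-(lens + macular)) and renormalized to peak 1. A CSV
#' source (`"csv:<path>"`, columns `wavelength_nm,L,M,S`) loads tabulated
#' fundamentals instead.
#'
#' @param grid a [WavelengthGrid-class]
#' @param source `"nomogram"` or `"csv:<path>"`
#' @param lambdaMax named vector of pigment peaks (nm) for nomogram mode
#' @param pre a [PrereceptoralFilter-class] for nomogram mode
#' @return named list of [ConeSensitivity-class]: `L`, `M`, `S`
#' @examples
#' fund <- buildNormalFundamentals()
#' which.max(specValues(fund$L)) > which.max(specValues(fund$M))  # TRUE
#' @export
buildNormalFundamentals <- function(grid = defaultGrid(), source = "nomogram",
                                    lambdaMax = c(L = 559, M = 530, S = 421),
                                    pre = prereceptoralTemplate(grid)) {
    if (identical(source, "nomogram")) {
        stopIfGridMismatch(grid, pre@grid, "grid and pre-receptoral filter")
        screen <- 10^(-(pre@lensDensity + pre@macularDensity))
        build <- function(label) {
            t <- pigmentTemplate(lambdaMax[[label]], grid)
            lbl <- if (label == "S") "S" else label
            newConeSensitivity(grid, t * screen, lbl)
        }
        list(L = build("L"), M = build("M"), S = build("S"))
    } else if (startsWith(source, "csv:")) {
        path <- substring(source, 5)
        df <- utils::read.csv(path, check.names = FALSE)
        need <- c("wavelength_nm", "L", "M", "S")
        miss <- setdiff(need, names(df))
        if (length(miss))
            rmStop(sprintf("%s: missing cone column(s) %s", path,
                           paste(miss, collapse = ", ")), "malformedCsv")
        wl <- wavelengths(grid)
        load <- function(col) {
            v <- stats::approx(df$wavelength_nm, df[[col]], xout = wl, rule = 1)$y
            v[is.na(v)] <- 0
            newConeSensitivity(grid, v, col)
        }
        list(L = load("L"), M = load("M"), S = load("S"))
    } else {
        rmStop("source must be 'nomogram' or 'csv:<path>'", "badArgument")
    }
}

#' Write a fundamentals set to CSV
#'
#' Columns `wavelength_nm,L,M,S`; anomalous members, if supplied, are
#' written as `Lp` / `Mp` columns.
#'
#' @param fundamentals named list of [ConeSensitivity-class]
#' @param path file path
#' @return `path`, invisibly
#' @export
writeFundamentalsCsv <- function(fundamentals, path) {
    df <- data.frame(wavelength_nm = wavelengths(fundamentals[[1]]))
    for (nm in names(fundamentals)) df[[nm]] <- fundamentals[[nm]]@values
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Remove pre-receptoral screening from a cone sensitivity
#'
#' Divides out the lens and macular attenuation
#' (multiplies by 10^(+lens+macular)) and renormalizes to peak 1, leaving
#' the bare photopigment shape ready for template shifting.
#'
#' @param cone a [ConeSensitivity-class]
#' @param pre a [PrereceptoralFilter-class] on the same grid
#' @return the stripped, renormalized [ConeSensitivity-class]
#' @seealso [restorePrereceptoral()], the exact inverse to within
#'   renormalization
#' @export
stripPrereceptoral <- function(cone, pre) {
    stopIfGridMismatch(cone, pre, "cone and pre-receptoral filter")
    newConeSensitivity(cone@grid,
                       cone@values * 10^(pre@lensDensity + pre@macularDensity),
                       cone@label)
}

#' Reapply pre-receptoral screening to a pigment shape
#'
#' @param pigment a stripped [ConeSensitivity-class]
#' @param pre a [PrereceptoralFilter-class] on the same grid
#' @param label optional new cone label for the result
#' @return the screened, renormalized [ConeSensitivity-class]
#' @export
restorePrereceptoral <- function(pigment, pre, label = pigment@label) {
    stopIfGridMismatch(pigment, pre, "pigment and pre-receptoral filter")
    newConeSensitivity(pigment@grid,
                       pigment@values * 10^(-(pre@lensDensity + pre@macularDensity)),
                       label)
}

#' Shift a pigment template on the frequency abscissa
#'
#' Translates the pigment sensitivity rigidly in wavenumber: writing
#' q(nu) for the sensitivity as a function of frequency nu = 1e7/lambda
#' (cm^-1), the result is q(nu - shift). Positive shifts move the peak
#' toward shorter wavelengths (higher frequency); the shifted peak sits at
#' 1 / (1/lambda_peak + shift * 1e-7) nm. Implemented as the exact change
#' of variable: the output at grid wavelength lambda is the input
#' evaluated (by linear interpolation) at
#' lambda' = 1 / (1/lambda - shift * 1e-7).
#'
#' @param pigment a [ConeSensitivity-class] (normally a stripped pigment)
#' @param shiftCm1 wavenumber shift in cm^-1; |shift| <= `maxShift`
#' @param maxShift sanity bound on |shift| (default 3000 cm^-1)
#' @return the shifted [ConeSensitivity-class] (same label)
#' @export
shiftPigmentFrequency <- function(pigment, shiftCm1, maxShift = 3000) {
    if (abs(shiftCm1) > maxShift)
        rmStop(sprintf("|shift| = %.0f cm^-1 exceeds the %g cm^-1 bound",
                       abs(shiftCm1), maxShift), "badArgument")
    wl <- wavelengths(pigment)
    if (shiftCm1 == 0) return(pigment)
    # source wavelength for each output sample under the wavenumber translation
    nuSrc <- 1e7 / wl - shiftCm1
    if (any(nuSrc <= 0))
        rmStop("shift maps part of the grid to non-positive frequency",
               "shiftOutOfRange")
    wlSrc <- 1e7 / nuSrc
    peakOld <- wl[which.max(pigment@values)]
    peakNew <- 1 / (1 / peakOld + shiftCm1 * 1e-7)
    if (peakNew < wl[1] || peakNew > wl[length(wl)])
        rmStop(sprintf("shift %.0f cm^-1 moves the pigment peak (%.1f nm) outside the grid",
                       shiftCm1, peakNew), "shiftOutOfRange")
    v <- stats::approx(wl, pigment@values, xout = wlSrc, rule = 1)$y
    v[is.na(v)] <- 0
    newConeSensitivity(pigment@grid, v, pigment@label)
}

#' Construct the textbook normal observer
#'
#' @param fundamentals output of [buildNormalFundamentals()]
#' @return an [Observer-class] with cones (L, M) and shift 0
#' @export
makeNormalObserver <- function(fundamentals = buildNormalFundamentals()) {
    new("Observer", kind = "normal", coneA = fundamentals$L,
        coneB = fundamentals$M, shiftCm1 = 0)
}

#' Construct an anomalous observer by template shifting
#'
#' Builds a protanomalous or deuteranomalous observer the DeMarco way:
#' strip lens and macular screening from the normal parent pigment (M for
#' protan, L for deutan), translate the bare template on the wavenumber
#' abscissa by `shiftCm1`, then restore the pre-receptoral factors. The
#' unshifted partner cone is taken unmodified from the normal set. The
#' same construction with a small shift on the L branch models normal
#' individual differences.
#'
#' @param fundamentals output of [buildNormalFundamentals()]
#' @param kind `"protanomalous"` or `"deuteranomalous"` (or `"normal"`,
#'   giving a normal observer whose L pigment carries a small jitter shift)
#' @param shiftCm1 wavenumber shift (cm^-1); positive = toward shorter
#'   wavelengths
#' @param pre the [PrereceptoralFilter-class] used for strip/restore
#' @return an [Observer-class]: (M', M) for protan, (L, L') for deutan
#' @export
makeAnomalousObserver <- function(fundamentals, kind, shiftCm1,
                                  pre = prereceptoralTemplate(fundamentals$L@grid)) {
    if (!(kind %in% .observerKinds))
        rmStop(sprintf("kind must be one of %s",
                       paste(.observerKinds, collapse = ", ")), "badArgument")
    shiftCone <- function(cone, newLabel) {
        bare <- stripPrereceptoral(cone, pre)
        moved <- shiftPigmentFrequency(bare, shiftCm1)
        restorePrereceptoral(moved, pre, label = newLabel)
    }
    if (kind == "protanomalous") {
        new("Observer", kind = kind,
            coneA = shiftCone(fundamentals$M, "Mp"),
            coneB = fundamentals$M, shiftCm1 = shiftCm1)
    } else if (kind == "deuteranomalous") {
        new("Observer", kind = kind, coneA = fundamentals$L,
            coneB = shiftCone(fundamentals$L, "Lp"), shiftCm1 = shiftCm1)
    } else {
        new("Observer", kind = "normal",
            coneA = shiftCone(fundamentals$L, "L"),
            coneB = fundamentals$M, shiftCm1 = shiftCm1)
    }
}

#' Observer accessors
#'
#' @param observer an [Observer-class]
#' @return `observerKind`: the phenotype label; `observerShift`: the
#'   generating wavenumber shift (cm^-1); `coneA`/`coneB`: the numerator /
#'   denominator [ConeSensitivity-class].
#' @name observer-accessors
NULL

#' @rdname observer-accessors
#' @export
observerKind <- function(observer) observer@kind

#' @rdname observer-accessors
#' @export
observerShift <- function(observer) observer@shiftCm1

#' @rdname observer-accessors
#' @export
coneA <- function(observer) observer@coneA

#' @rdname observer-accessors
#' @export
coneB <- function(observer) observer@coneB

#' Fit the template shift that reproduces a target match
#'
#' Searches a uniform grid of wavenumber shifts for the one whose
#' predicted Rayleigh match on the given instrument is closest to
#' `targetLambda`, mirroring the original small-step adjustment that fit
#' anomalous pigments to average empirical matches. Ties break toward the
#' smaller |shift|.
#'
#' @param kind `"protanomalous"`, `"deuteranomalous"`, or `"normal"`
#'   (jitter branch)
#' @param targetLambda target mixture setting, inside the instrument's
#'   control range
#' @param instrument an [Instrument-class]
#' @param fundamentals output of [buildNormalFundamentals()]
#' @param pre a [PrereceptoralFilter-class]
#' @param stepCm1 search grid step (default 10 cm^-1)
#' @param bounds search interval (default c(-2000, 2000) cm^-1)
#' @return the best shift (cm^-1); attribute `"achievedLambda"` carries
#'   the predicted match at that shift
#' @export
fitShiftToMatch <- function(kind, targetLambda, instrument,
                            fundamentals = buildNormalFundamentals(),
                            pre = prereceptoralTemplate(fundamentals$L@grid),
                            stepCm1 = 10, bounds = c(-2000, 2000)) {
    if (stepCm1 <= 0) rmStop("stepCm1 must be > 0", "badArgument")
    cr <- controlRange(instrument)
    if (targetLambda < cr[1] || targetLambda > cr[2])
        rmStop("targetLambda lies outside the instrument's control range",
               "badArgument")
    shifts <- seq(bounds[1], bounds[2], by = stepCm1)
    shifts <- shifts[order(abs(shifts), shifts)]  # tie-break: smaller |shift| first
    best <- NULL
    bestDist <- Inf
    anyMatch <- FALSE
    for (s in shifts) {
        lam <- tryCatch({
            obs <- makeAnomalousObserver(fundamentals, kind, s, pre)
            lambdaStar(predictMatch(instrument, obs))
        }, rayleighMatchError = function(e) NA_real_)
        if (is.na(lam)) next
        anyMatch <- TRUE
        d <- abs(lam - targetLambda)
        if (d < bestDist - 1e-15) {
            bestDist <- d
            best <- c(shift = s, lambda = lam)
        }
    }
    if (!anyMatch || is.null(best))
        rmStop("unreachable target: no shift in bounds yields a match in the instrument range",
               "unreachableTarget")
    structure(unname(best["shift"]), achievedLambda = unname(best["lambda"]))
}
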