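#' @import methods
NULL

.tol <- 1e-9

#' Uniform wavelength grid
#'
#' A uniform sampling grid in wavelength, the shared abscissa of every
#' spectral object in the package. All spectral arithmetic requires its
#' operands to live on one grid; [resampleSpectrum()] moves between grids.
#'
#' @slot startNm first sample wavelength (nm)
#' @slot stopNm last sample wavelength (nm)
#' @slot stepNm sample spacing (nm); must divide `stopNm - startNm`
#'
#' @seealso [makeGrid()], [wavelengths()]
#' @exportClass WavelengthGrid
setClass("WavelengthGrid",
    representation(startNm = "numeric", stopNm = "numeric", stepNm = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(object@startNm) != 1L || length(object@stopNm) != 1L ||
            length(object@stepNm) != 1L)
            msg <- c(msg, "startNm, stopNm, stepNm must be scalars")
        else {
            if (!is.finite(object@startNm) || !is.finite(object@stopNm) ||
                !is.finite(object@stepNm))
                msg <- c(msg, "grid bounds must be finite")
            else {
                if (object@startNm >= object@stopNm)
                    msg <- c(msg, "startNm must be < stopNm")
                if (object@stepNm <= 0)
                    msg <- c(msg, "stepNm must be > 0")
                else {
                    n <- (object@stopNm - object@startNm) / object@stepNm
                    if (abs(n - round(n)) > 1e-8)
                        msg <- c(msg, "stepNm must divide (stopNm - startNm)")
                }
            }
        }
        if (is.null(msg)) TRUE else msg
    })

#' Sampled spectral power distribution
#'
#' A non-negative wavelength-sampled function in relative energy units
#' (energy per unit wavelength). Used for LED primary outputs, mixture
#' fields, and the amber reference field.
#'
#' @slot grid a [WavelengthGrid-class]
#' @slot values numeric vector, one non-negative finite value per grid sample
#'
#' @seealso [synthesizeLedSpd()], [applyFilter()], [specValues()]
#' @exportClass Spectrum
setClass("Spectrum",
    representation(grid = "WavelengthGrid", values = "numeric"),
    validity = function(object) {
        n <- gridLength(object@grid)
        if (length(object@values) != n)
            return(sprintf("values has length %d; grid has %d samples",
                           length(object@values), n))
        if (anyNA(object@values) || any(!is.finite(object@values)))
            return("values must be finite")
        if (any(object@values < -.tol))
            return("spectral values must be non-negative")
        TRUE
    })

#' Spectral transmittance
#'
#' A dimensionless transmittance fraction per wavelength sample, in [0, 1].
#' Extends [Spectrum-class] with the upper bound.
#'
#' @slot grid a [WavelengthGrid-class]
#' @slot values transmittance fractions in [0, 1]
#'
#' @seealso [synthesizeCutonFilter()], [applyFilter()]
#' @exportClass Transmittance
setClass("Transmittance", contains = "Spectrum",
    validity = function(object) {
        if (any(object@values > 1 + .tol))
            return("transmittance values must be <= 1")
        TRUE
    })

.coneLabels <- c("L", "M", "S", "Lp", "Mp")

#' Cone spectral sensitivity
#'
#' A relative corneal spectral sensitivity (energy units), peak-normalized
#' to 1. Labels follow the modern convention: `Lp` (L') is the variant
#' long-wave pigment of the deuteranomalous observer, `Mp` (M') the variant
#' middle-wave pigment of the protanomalous observer.
#'
#' @slot grid a [WavelengthGrid-class]
#' @slot values non-negative sensitivities, max exactly 1
#' @slot label one of `"L"`, `"M"`, `"S"`, `"Lp"`, `"Mp"`
#'
#' @seealso [buildNormalFundamentals()], [shiftPigmentFrequency()]
#' @exportClass ConeSensitivity
setClass("ConeSensitivity", contains = "Spectrum",
    representation(label = "character"),
    validity = function(object) {
        msg <- NULL
        if (length(object@label) != 1L || !(object@label %in% .coneLabels))
            msg <- c(msg, sprintf("label must be one of %s",
                                  paste(.coneLabels, collapse = ", ")))
        if (abs(max(object@values) - 1) > 1e-6)
            msg <- c(msg, "sensitivity must be peak-normalized (max == 1)")
        if (is.null(msg)) TRUE else msg
    })

#' Pre-receptoral filter densities
#'
#' Lens and macular pigment optical densities (log10 units) on a shared
#' grid. These screen light before it reaches the photopigment; removing
#' and restoring them brackets the frequency-abscissa template shift that
#' builds anomalous pigments.
#'
#' @slot grid a [WavelengthGrid-class]
#' @slot lensDensity lens optical density per sample (>= 0)
#' @slot macularDensity macular pigment optical density per sample (>= 0;
#'   negligible above 550 nm)
#'
#' @seealso [prereceptoralTemplate()], [stripPrereceptoral()]
#' @exportClass PrereceptoralFilter
setClass("PrereceptoralFilter",
    representation(grid = "WavelengthGrid", lensDensity = "numeric",
                   macularDensity = "numeric"),
    validity = function(object) {
        n <- gridLength(object@grid)
        msg <- NULL
        if (length(object@lensDensity) != n || length(object@macularDensity) != n)
            msg <- c(msg, "density vectors must match the grid length")
        else {
            if (any(object@lensDensity < -.tol) || any(object@macularDensity < -.tol))
                msg <- c(msg, "optical densities must be non-negative")
            wl <- wavelengths(object@grid)
            if (any(object@macularDensity[wl > 550] >= 0.01))
                msg <- c(msg, "macular density must be < 0.01 above 550 nm")
        }
        if (is.null(msg)) TRUE else msg
    })

.observerKinds <- c("normal", "protanomalous", "deuteranomalous")

#' Rayleigh-range observer
#'
#' A labeled pair of cone sensitivities active in the Rayleigh (red/green)
#' spectral range, plus the wavenumber shift that generated the anomalous
#' member. The first cone (`coneA`) is the ratio numerator by convention:
#' normal L/M, protanomalous M'/M, deuteranomalous L/L'. S cones are
#' excluded from all Rayleigh computations (they are minimally sensitive
#' in this range).
#'
#' @slot kind `"normal"`, `"protanomalous"`, or `"deuteranomalous"`
#' @slot coneA numerator [ConeSensitivity-class] (L, M', or L)
#' @slot coneB denominator [ConeSensitivity-class] (M, M, or L')
#' @slot shiftCm1 wavenumber shift (cm^-1) applied to the anomalous member;
#'   0 for a textbook normal. Positive shifts move the pigment peak toward
#'   shorter wavelengths.
#'
#' @seealso [makeNormalObserver()], [makeAnomalousObserver()]
#' @exportClass Observer
setClass("Observer",
    representation(kind = "character", coneA = "ConeSensitivity",
                   coneB = "ConeSensitivity", shiftCm1 = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(object@kind) != 1L || !(object@kind %in% .observerKinds))
            msg <- c(msg, sprintf("kind must be one of %s",
                                  paste(.observerKinds, collapse = ", ")))
        if (length(object@shiftCm1) != 1L || !is.finite(object@shiftCm1))
            msg <- c(msg, "shiftCm1 must be a finite scalar")
        if (!isTRUE(all.equal(gridDef(object@coneA@grid), gridDef(object@coneB@grid))))
            msg <- c(msg, "both cones must share one grid")
        if (identical(object@kind, "normal")) {
            ok <- identical(object@coneA@label, "L") &&
                identical(object@coneB@label, "M")
            if (!ok) msg <- c(msg, "normal observer must be (L, M)")
        } else if (identical(object@kind, "protanomalous")) {
            ok <- identical(object@coneA@label, "Mp") &&
                identical(object@coneB@label, "M")
            if (!ok) msg <- c(msg, "protanomalous observer must be (Mp, M)")
        } else if (identical(object@kind, "deuteranomalous")) {
            ok <- identical(object@coneA@label, "L") &&
                identical(object@coneB@label, "Lp")
            if (!ok) msg <- c(msg, "deuteranomalous observer must be (L, Lp)")
        }
        if (is.null(msg)) TRUE else msg
    })

#' Anomaloscope primary channel
#'
#' One primary light: a peak-normalized SPD together with the curve mapping
#' the instrument's control variable to an intensity multiplier.
#'
#' @slot spd peak-normalized [Spectrum-class]
#' @slot outputCurve function(control setting) -> intensity multiplier >= 0
#'
#' @exportClass PrimaryChannel
setClass("PrimaryChannel",
    representation(spd = "Spectrum", outputCurve = "function"))

#' Anomaloscope model
#'
#' A spectral model of an anomaloscope: red and green mixture primaries
#' whose outputs are driven by a single mixture control, and an amber
#' reference primary with its own intensity control.
#'
#' @slot name instrument name
#' @slot red,green,amber [PrimaryChannel-class] objects
#' @slot controlRange closed interval of the mixture setting
#' @slot amberRange closed interval of the amber intensity control
#'
#' @seealso [makeInstrument()], [mixtureSpd()], [referenceSpd()]
#' @exportClass Instrument
setClass("Instrument",
    representation(name = "character", red = "PrimaryChannel",
                   green = "PrimaryChannel", amber = "PrimaryChannel",
                   controlRange = "numeric", amberRange = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(object@controlRange) != 2L ||
            diff(object@controlRange) <= 0)
            msg <- c(msg, "controlRange must be a non-degenerate interval")
        if (length(object@amberRange) != 2L || diff(object@amberRange) < 0)
            msg <- c(msg, "amberRange must be an interval")
        g <- gridDef(object@red@spd@grid)
        if (!isTRUE(all.equal(g, gridDef(object@green@spd@grid))) ||
            !isTRUE(all.equal(g, gridDef(object@amber@spd@grid))))
            msg <- c(msg, "all three primaries must share one grid")
        if (is.null(msg)) TRUE else msg
    })

#' Predicted Rayleigh match
#'
#' The mixture setting at which the observer's cone-excitation ratio for
#' the mixture field equals the (intensity-invariant) ratio for the amber
#' field, with solver diagnostics.
#'
#' @slot lambdaStar matched mixture setting
#' @slot amberRatio cone-excitation ratio of the amber field
#' @slot mixtureRatioAtMatch mixture ratio at `lambdaStar`
#' @slot bracket solver bracket (lo, hi) on the control scale
#' @slot solverIterations bisection iterations used
#' @slot notes character vector of solver warnings (e.g. multiple crossings)
#'
#' @seealso [predictMatch()]
#' @exportClass MatchPrediction
setClass("MatchPrediction",
    representation(lambdaStar = "numeric", amberRatio = "numeric",
                   mixtureRatioAtMatch = "numeric", bracket = "numeric",
                   solverIterations = "integer", notes = "character"),
    validity = function(object) {
        rel <- abs(object@mixtureRatioAtMatch - object@amberRatio) /
            object@amberRatio
        if (rel > 1e-6)
            return("mixture ratio at match must equal the amber ratio to 1e-6")
        TRUE
    })

#' Accepted matching range
#'
#' The connected interval of mixture settings around the predicted match
#' where the log cone-excitation ratio stays within `delta` of the amber
#' ratio. An observer whose range reaches an end of the instrument scale
#' (`touchesEnd`) is the "extreme anomalous" case excluded from cohort
#' analyses.
#'
#' @slot lambdaLo,lambdaHi interval endpoints on the control scale
#' @slot lambdaStar the contained match point
#' @slot delta log-ratio tolerance (dimensionless)
#' @slot touchesEnd TRUE when an endpoint of the control range satisfies
#'   the tolerance
#'
#' @seealso [matchingRange()]
#' @exportClass MatchingRange
setClass("MatchingRange",
    representation(lambdaLo = "numeric", lambdaHi = "numeric",
                   lambdaStar = "numeric", delta = "numeric",
                   touchesEnd = "logical"),
    validity = function(object) {
        msg <- NULL
        if (object@delta < 0) msg <- c(msg, "delta must be >= 0")
        if (object@lambdaLo > object@lambdaStar + 1e-12 ||
            object@lambdaHi < object@lambdaStar - 1e-12)
            msg <- c(msg, "matching range must contain lambdaStar")
        if (is.null(msg)) TRUE else msg
    })
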