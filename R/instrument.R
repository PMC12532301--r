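#' Construct a primary channel
#'
#' @param spd the channel's [Spectrum-class]; peak-normalized internally
#' @param outputCurve function mapping the control setting to a
#'   non-negative intensity multiplier
#' @return a [PrimaryChannel-class]
#' @export
newPrimaryChannel <- function(spd, outputCurve) {
    peak <- max(spd@values)
    if (peak <= 0) rmStop("channel SPD must be non-zero", "badArgument")
    if (is(spd, "Transmittance")) spd <- newSpectrum(spd@grid, spd@values)
    new("PrimaryChannel", spd = scaleSpectrum(spd, 1 / peak),
        outputCurve = outputCurve)
}

pennGreenCurve <- function(knee = 0.3) {
    force(knee)
    function(lam) ifelse(lam <= knee, 1, pmax(0, (1 - lam) / (1 - knee)))
}

complementaryCurves <- function(scaleMax) {
    list(red = function(s) s / scaleMax,
         green = function(s) 1 - s / scaleMax)
}

#' Construct an anomaloscope model
#'
#' Presets:
#' \describe{
#'   \item{penn}{LED device: red 623 nm, green 523 nm, amber 592 nm
#'     screened by the deep-yellow (Wratten-15-like) filter. Mixture
#'     control lambda in [0, 1]; red output r(lambda) = lambda; green
#'     output constant at 1 up to the knee (lambda = 0.3), then linear to
#'     0 at lambda = 1 — so the total mixture output is not constant in
#'     lambda.}
#'   \item{oculus}{commercial instrument: green 545 nm, red 670 nm, amber
#'     589 nm; mixture scale 0-73 with complementary linear outputs
#'     (0 = pure green, 73 = pure red).}
#'   \item{nagel}{classical primaries 537 / 666 nm with amber 589 nm;
#'     scale 0-73, complementary linear outputs.}
#' }
#' A configuration list (or a path to a JSON file with the same structure)
#' overrides any preset field:
#' `list(name=, primaries=list(red=list(peak_nm=, fwhm_nm=), green=..., amber=...),`
#' `control_range=, knee=, amber_range=)`.
#'
#' @param preset `"penn"`, `"oculus"`, or `"nagel"`
#' @param config optional list or JSON file path overriding preset fields
#' @param grid shared [WavelengthGrid-class]
#' @return an [Instrument-class]
#' @examples
#' penn <- makeInstrument("penn")
#' controlRange(penn)  # 0 1
#' @export
makeInstrument <- function(preset = c("penn", "oculus", "nagel"),
                           config = NULL, grid = defaultGrid()) {
    defaults <- list(
        penn = list(name = "penn",
                    primaries = list(red = list(peak_nm = 623, fwhm_nm = 20),
                                     green = list(peak_nm = 523, fwhm_nm = 30),
                                     amber = list(peak_nm = 592, fwhm_nm = 16,
                                                  wratten15 = TRUE)),
                    control_range = c(0, 1), knee = 0.3, amber_range = c(0, 2)),
        oculus = list(name = "oculus",
                      primaries = list(red = list(peak_nm = 670, fwhm_nm = 20),
                                       green = list(peak_nm = 545, fwhm_nm = 30),
                                       amber = list(peak_nm = 589, fwhm_nm = 16)),
                      control_range = c(0, 73), amber_range = c(0, 2)),
        nagel = list(name = "nagel",
                     primaries = list(red = list(peak_nm = 666, fwhm_nm = 10),
                                      green = list(peak_nm = 537, fwhm_nm = 10),
                                      amber = list(peak_nm = 589, fwhm_nm = 10)),
                     control_range = c(0, 73), amber_range = c(0, 2)))
    if (is.character(config) && length(config) == 1L) {
        config <- tryCatch(jsonlite::fromJSON(config, simplifyVector = TRUE),
                           error = function(e)
                               rmStop(sprintf("malformed instrument config: %s",
                                              conditionMessage(e)), "malformedConfig"))
    }
    preset <- match.arg(preset)
    cfg <- defaults[[preset]]
    if (!is.null(config)) {
        if (!is.list(config))
            rmStop("config must be a list or a JSON file path", "malformedConfig")
        cfg <- utils::modifyList(cfg, config)
    }
    for (ch in c("red", "green", "amber")) {
        p <- cfg$primaries[[ch]]
        if (is.null(p$peak_nm) || is.null(p$fwhm_nm) ||
            !is.finite(p$peak_nm) || !is.finite(p$fwhm_nm) || p$fwhm_nm <= 0)
            rmStop(sprintf("malformed config at primaries$%s: need finite peak_nm and fwhm_nm > 0", ch),
                   "malformedConfig")
    }
    if (length(cfg$control_range) != 2L || diff(range(cfg$control_range)) <= 0)
        rmStop("malformed config at control_range", "malformedConfig")

    buildSpd <- function(p) {
        spd <- synthesizeLedSpd(p$peak_nm, p$fwhm_nm, grid,
                                shoulderAmplitude = p$shoulder_amplitude %||% 0)
        if (isTRUE(p$wratten15)) spd <- applyFilter(spd, wratten15Filter(grid))
        if (isTRUE(p$orange)) spd <- applyFilter(spd, orangeFilter(grid))
        spd
    }
    if (identical(cfg$name, "penn") || !is.null(cfg$knee)) {
        redCurve <- function(lam) lam
        greenCurve <- pennGreenCurve(cfg$knee %||% 0.3)
    } else {
        cc <- complementaryCurves(cfg$control_range[2])
        redCurve <- cc$red
        greenCurve <- cc$green
    }
    new("Instrument", name = cfg$name,
        red = newPrimaryChannel(buildSpd(cfg$primaries$red), redCurve),
        green = newPrimaryChannel(buildSpd(cfg$primaries$green), greenCurve),
        amber = newPrimaryChannel(buildSpd(cfg$primaries$amber), function(i) i),
        controlRange = as.numeric(cfg$control_range),
        amberRange = as.numeric(cfg$amber_range %||% c(0, 2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Instrument accessors
#' @param instrument an [Instrument-class]
#' @return `controlRange` / `amberRange`: numeric length-2 intervals;
#'   `instrumentName`: the name string.
#' @name instrument-accessors
NULL

#' @rdname instrument-accessors
#' @export
controlRange <- function(instrument) instrument@controlRange

#' @rdname instrument-accessors
#' @export
amberRange <- function(instrument) instrument@amberRange

#' @rdname instrument-accessors
#' @export
instrumentName <- function(instrument) instrument@name

#' Mixture-field spectral power distribution
#'
#' The SPD presented in the mixture field at a control setting:
#' `r(lambda) * spd_red + g(lambda) * spd_green`, exact to linearity.
#'
#' @param instrument an [Instrument-class]
#' @param lambdaSetting mixture control setting, within [controlRange()]
#' @return a [Spectrum-class]
#' @export
mixtureSpd <- function(instrument, lambdaSetting) {
    cr <- instrument@controlRange
    if (lambdaSetting < cr[1] - 1e-12 || lambdaSetting > cr[2] + 1e-12)
        rmStop(sprintf("mixture setting %.4g outside control range [%g, %g]",
                       lambdaSetting, cr[1], cr[2]), "settingOutOfRange")
    r <- instrument@red@outputCurve(lambdaSetting)
    g <- instrument@green@outputCurve(lambdaSetting)
    newSpectrum(instrument@red@spd@grid,
                r * instrument@red@spd@values + g * instrument@green@spd@values)
}

#' Amber reference-field spectral power distribution
#'
#' @param instrument an [Instrument-class]
#' @param amberIntensity amber control value, within [amberRange()]
#' @return a [Spectrum-class]: `amberIntensity * spd_amber`
#' @export
referenceSpd <- function(instrument, amberIntensity = 1) {
    ar <- instrument@amberRange
    if (amberIntensity < ar[1] - 1e-12 || amberIntensity > ar[2] + 1e-12)
        rmStop(sprintf("amber intensity %.4g outside range [%g, %g]",
                       amberIntensity, ar[1], ar[2]), "settingOutOfRange")
    scaleSpectrum(instrument@amber@spd, instrument@amber@outputCurve(amberIntensity))
}

#' Replace the amber channel's SPD
#'
#' Substitutes an arbitrary spectrum for the amber primary (the identity
#' intensity curve is kept). Useful for physical-identity checks: with the
#' amber field set to `mixtureSpd(instrument, lambda0)`, every observer's
#' predicted match is `lambda0`.
#'
#' @param instrument an [Instrument-class]
#' @param spd a [Spectrum-class] on the instrument's grid
#' @return the modified [Instrument-class]
#' @export
setAmberSpd <- function(instrument, spd) {
    stopIfGridMismatch(instrument@red@spd, spd, "instrument and new amber SPD")
    instrument@amber <- newPrimaryChannel(spd, function(i) i)
    instrument
}
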