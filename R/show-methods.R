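#' @describeIn makeGrid show method
#' @param object a WavelengthGrid
#' @export
setMethod("show", "WavelengthGrid", function(object) {
    cat(sprintf("WavelengthGrid: %g-%g nm by %g nm (%d samples)\n",
                object@startNm, object@stopNm, object@stepNm,
                gridLength(object)))
})

#' @describeIn newSpectrum show method
#' @param object a Spectrum
#' @export
setMethod("show", "Spectrum", function(object) {
    wl <- wavelengths(object)
    cat(sprintf("%s on %g-%g nm: peak %.4g at %g nm, energy %.4g\n",
                class(object), wl[1], wl[length(wl)], max(object@values),
                wl[which.max(object@values)], spectrumEnergy(object)))
})

#' @describeIn buildNormalFundamentals show method for a single fundamental
#' @param object a ConeSensitivity
#' @export
setMethod("show", "ConeSensitivity", function(object) {
    wl <- wavelengths(object)
    cat(sprintf("ConeSensitivity %s: peak at %g nm\n", object@label,
                wl[which.max(object@values)]))
})

#' @describeIn makeNormalObserver show method
#' @param object an Observer
#' @export
setMethod("show", "Observer", function(object) {
    cat(sprintf("Observer: %s (%s/%s), shift %+.0f cm^-1\n", object@kind,
                object@coneA@label, object@coneB@label, object@shiftCm1))
})

#' @describeIn makeInstrument show method
#' @param object an Instrument
#' @export
setMethod("show", "Instrument", function(object) {
    peak <- function(ch) {
        wl <- wavelengths(ch@spd)
        wl[which.max(ch@spd@values)]
    }
    cat(sprintf("Instrument '%s': red %g nm, green %g nm, amber %g nm; mixture control [%g, %g]\n",
                object@name, peak(object@red), peak(object@green),
                peak(object@amber), object@controlRange[1],
                object@controlRange[2]))
})

#' @describeIn predictMatch show method
#' @param object a MatchPrediction
#' @export
setMethod("show", "MatchPrediction", function(object) {
    cat(sprintf("MatchPrediction: lambda* = %.6f (amber ratio %.5g, %d iterations)\n",
                object@lambdaStar, object@amberRatio, object@solverIterations))
    if (length(object@notes))
        cat(paste0("  note: ", object@notes, collapse = "\n"), "\n")
})

#' @describeIn matchingRange show method
#' @param object a MatchingRange
#' @export
setMethod("show", "MatchingRange", function(object) {
    cat(sprintf("MatchingRange: [%.5f, %.5f] around %.5f (delta %g)%s\n",
                object@lambdaLo, object@lambdaHi, object@lambdaStar,
                object@delta,
                if (object@touchesEnd) " - touches a scale end" else ""))
})
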