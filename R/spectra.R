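#' Construct a Spectrum
#'
#' @param grid a [WavelengthGrid-class]
#' @param values non-negative finite values, one per grid sample
#' @return a [Spectrum-class]
#' @export
newSpectrum <- function(grid, values) {
    v <- as.numeric(values)
    v[v < 0 & v > -1e-12] <- 0  # clamp interpolation dust
    new("Spectrum", grid = grid, values = v)
}

#' Construct a Transmittance
#'
#' @param grid a [WavelengthGrid-class]
#' @param values transmittance fractions in [0, 1]
#' @return a [Transmittance-class]
#' @export
newTransmittance <- function(grid, values) {
    v <- as.numeric(values)
    v[v < 0 & v > -1e-12] <- 0
    v[v > 1 & v < 1 + 1e-12] <- 1
    new("Transmittance", grid = grid, values = v)
}

#' Spectral values
#' @param x a [Spectrum-class] (or subclass)
#' @return numeric vector of sampled values
#' @export
specValues <- function(x) x@values

#' Synthesize a Gaussian LED spectral power distribution
#'
#' Narrowband LED primaries are modeled as Gaussians in wavelength,
#' parameterized by peak position and full width at half maximum, with the
#' peak value 1 before any intensity scaling. An optional second Gaussian
#' component models a long-wavelength shoulder (off by default).
#'
#' @param peakNm peak wavelength (nm); must lie within the grid
#' @param fwhmNm full width at half maximum (nm), > 0
#' @param grid a [WavelengthGrid-class]
#' @param shoulderAmplitude relative amplitude of an optional secondary
#'   component (default 0 = pure Gaussian)
#' @param shoulderPeakNm,shoulderFwhmNm secondary component position/width
#' @return a [Spectrum-class], unimodal for `shoulderAmplitude = 0`, with
#'   argmax at the grid point nearest `peakNm`
#' @examples
#' red <- synthesizeLedSpd(623, 20, defaultGrid())
#' wavelengths(red)[which.max(specValues(red))]  # 623
#' @export
synthesizeLedSpd <- function(peakNm, fwhmNm, grid = defaultGrid(),
                             shoulderAmplitude = 0, shoulderPeakNm = peakNm + 50,
                             shoulderFwhmNm = 2 * fwhmNm) {
    if (fwhmNm <= 0) rmStop("fwhmNm must be > 0", "badArgument")
    wl <- wavelengths(grid)
    if (peakNm < wl[1] || peakNm > wl[length(wl)])
        rmStop(sprintf("peak %.1f nm lies outside the grid [%g, %g]",
                       peakNm, wl[1], wl[length(wl)]), "peakOutsideGrid")
    sigma <- fwhmNm / (2 * sqrt(2 * log(2)))
    v <- exp(-((wl - peakNm)^2) / (2 * sigma^2))
    if (shoulderAmplitude > 0) {
        s2 <- shoulderFwhmNm / (2 * sqrt(2 * log(2)))
        v <- v + shoulderAmplitude * exp(-((wl - shoulderPeakNm)^2) / (2 * s2^2))
        v <- v / max(v)
    }
    newSpectrum(grid, v)
}

#' Synthesize a logistic cut-on filter transmittance
#'
#' Long-pass ("cut-on") gelatin filters are modeled by a logistic sigmoid
#' in wavelength: \eqn{T(\lambda) = t_{max} / (1 + e^{-k(\lambda - c)})},
#' monotone non-decreasing, with asymptote `tMax` at long wavelengths.
#'
#' @param cutonNm sigmoid midpoint (nm), where T = tMax/2
#' @param slopePerNm logistic steepness k (1/nm), > 0
#' @param tMax long-wavelength asymptote, in (0, 1]
#' @param grid a [WavelengthGrid-class]
#' @return a [Transmittance-class]
#' @seealso [wratten15Filter()] for the calibrated deep-yellow preset
#' @export
synthesizeCutonFilter <- function(cutonNm, slopePerNm, tMax = 1,
                                  grid = defaultGrid()) {
    if (tMax <= 0 || tMax > 1) rmStop("tMax must be in (0, 1]", "badArgument")
    if (slopePerNm <= 0) rmStop("slopePerNm must be > 0", "badArgument")
    wl <- wavelengths(grid)
    newTransmittance(grid, tMax / (1 + exp(-slopePerNm * (wl - cutonNm))))
}

#' Deep-yellow (Wratten-15-like) cut-on filter
#'
#' A logistic cut-on model calibrated analytically so that the transmission
#' at 590 nm is exactly 90%, the published single-point transmittance of
#' the Wratten 15 "Deep Yellow" gelatin filter used to screen the amber
#' primary.
#'
#' @param grid a [WavelengthGrid-class]
#' @param tMax long-wavelength asymptote (default 0.92)
#' @param slopePerNm logistic steepness (default 0.2 / nm)
#' @return a [Transmittance-class] with T(590) = 0.90
#' @export
wratten15Filter <- function(grid = defaultGrid(), tMax = 0.92,
                            slopePerNm = 0.2) {
    if (tMax <= 0.90) rmStop("tMax must exceed 0.90 to allow T(590) = 0.90",
                             "badArgument")
    cuton <- 590 + log(tMax / 0.90 - 1) / slopePerNm
    synthesizeCutonFilter(cuton, slopePerNm, tMax, grid)
}

#' Orange-screen (Roscolux-like) cut-on filter
#'
#' Default model of the orange gelatin screen over the bicolor channel:
#' cut-on near 540 nm, long-wavelength transmittance 0.95.
#'
#' @param grid a [WavelengthGrid-class]
#' @param cutonNm sigmoid midpoint (default 540 nm)
#' @param slopePerNm logistic steepness (default 0.15 / nm)
#' @param tMax asymptote (default 0.95)
#' @return a [Transmittance-class]
#' @export
orangeFilter <- function(grid = defaultGrid(), cutonNm = 540,
                         slopePerNm = 0.15, tMax = 0.95) {
    synthesizeCutonFilter(cutonNm, slopePerNm, tMax, grid)
}

#' Apply a filter to a spectrum
#'
#' Pointwise product of an SPD and a transmittance on a shared grid.
#'
#' @param spd a [Spectrum-class]
#' @param t a [Transmittance-class]
#' @return a [Spectrum-class] with `values = spd * t`
#' @export
applyFilter <- function(spd, t) {
    stopIfGridMismatch(spd, t, "spd and filter")
    newSpectrum(spd@grid, spd@values * t@values)
}

#' Scale a spectrum by a non-negative factor
#' @param spd a [Spectrum-class]
#' @param factor scalar >= 0
#' @return scaled [Spectrum-class]
#' @export
scaleSpectrum <- function(spd, factor) {
    if (factor < 0) rmStop("factor must be >= 0", "badArgument")
    newSpectrum(spd@grid, spd@values * factor)
}

#' Integrated spectral energy
#'
#' Riemann sum of the spectrum over its grid (values x step).
#' @param spd a [Spectrum-class]
#' @return scalar energy (arbitrary units)
#' @export
spectrumEnergy <- function(spd) sum(spd@values) * gridStep(spd)

#' Resample a spectrum onto a new grid
#'
#' Linear interpolation at the new sample points. Wavelengths outside the
#' support of the old grid extend as zero (primaries have compact support);
#' when that happens a message is emitted rather than an error.
#'
#' @param spectrum a [Spectrum-class] (or [Transmittance-class], preserved)
#' @param newGrid target [WavelengthGrid-class]
#' @return the resampled spectrum, same class as the input
#' @export
resampleSpectrum <- function(spectrum, newGrid) {
    oldWl <- wavelengths(spectrum)
    newWl <- wavelengths(newGrid)
    if (newWl[length(newWl)] < oldWl[1] || newWl[1] > oldWl[length(oldWl)])
        rmStop("new grid does not overlap the spectrum's support",
               "emptyOverlap")
    outside <- newWl < oldWl[1] | newWl > oldWl[length(oldWl)]
    if (any(outside))
        message(sprintf("resampleSpectrum: %d sample(s) outside [%g, %g] nm padded with 0",
                        sum(outside), oldWl[1], oldWl[length(oldWl)]))
    v <- stats::approx(oldWl, spectrum@values, xout = newWl, rule = 1)$y
    v[is.na(v)] <- 0
    if (is(spectrum, "Transmittance")) newTransmittance(newGrid, v)
    else newSpectrum(newGrid, v)
}

#' Measure full width at half maximum on the grid
#'
#' Scans the half-height crossings by linear interpolation between grid
#' samples. Used to verify synthesized LED shapes.
#'
#' @param spd a unimodal [Spectrum-class]
#' @return FWHM in nm
#' @export
measureFwhm <- function(spd) {
    wl <- wavelengths(spd)
    v <- spd@values
    half <- max(v) / 2
    above <- which(v >= half)
    if (length(above) < 1) rmStop("spectrum has no half-height support", "badArgument")
    iLo <- above[1]; iHi <- above[length(above)]
    lo <- if (iLo == 1) wl[1] else {
        stats::approx(v[c(iLo - 1, iLo)], wl[c(iLo - 1, iLo)], xout = half)$y
    }
    hi <- if (iHi == length(v)) wl[length(v)] else {
        stats::approx(v[c(iHi + 1, iHi)], wl[c(iHi + 1, iHi)], xout = half)$y
    }
    hi - lo
}

#' Read a spectrum from CSV
#'
#' Expects the two-column dialect `wavelength_nm,value` with strictly
#' increasing wavelengths and non-negative values. A non-uniform wavelength
#' column is accepted and resampled onto the declared uniform grid (a
#' message notes this); malformed rows are rejected with their row number.
#'
#' @param path file path
#' @param grid target grid; default: a uniform grid inferred from the file
#'   (for uniform files) or the file's range at 1 nm (for non-uniform files)
#' @param transmittance logical; validate into [0,1] and return a
#'   [Transmittance-class]
#' @return a [Spectrum-class] or [Transmittance-class]
#' @export
readSpectrumCsv <- function(path, grid = NULL, transmittance = FALSE) {
    df <- utils::read.csv(path, check.names = FALSE)
    if (ncol(df) < 2 || !identical(names(df)[1:2], c("wavelength_nm", "value")))
        rmStop(sprintf("%s: header must be 'wavelength_nm,value'", path),
               "malformedCsv")
    wl <- df[[1]]; v <- df[[2]]
    bad <- which(!is.finite(wl) | !is.finite(v))
    if (length(bad))
        rmStop(sprintf("%s: malformed value at data row %d", path, bad[1]),
               "malformedCsv", row = bad[1])
    neg <- which(v < 0)
    if (length(neg))
        rmStop(sprintf("%s: negative value at data row %d", path, neg[1]),
               "malformedCsv", row = neg[1])
    if (transmittance) {
        over <- which(v > 1)
        if (length(over))
            rmStop(sprintf("%s: transmittance > 1 at data row %d", path, over[1]),
                   "malformedCsv", row = over[1])
    }
    nonMono <- which(diff(wl) <= 0)
    if (length(nonMono))
        rmStop(sprintf("%s: wavelengths not strictly increasing at data row %d",
                       path, nonMono[1] + 1L), "malformedCsv", row = nonMono[1] + 1L)
    steps <- diff(wl)
    uniform <- max(abs(steps - steps[1])) < 1e-9
    if (is.null(grid)) {
        grid <- if (uniform) makeGrid(wl[1], wl[length(wl)], steps[1])
                else makeGrid(ceiling(wl[1]), floor(wl[length(wl)]), 1)
    }
    newWl <- wavelengths(grid)
    if (uniform && length(newWl) == length(wl) && max(abs(newWl - wl)) < 1e-9) {
        out <- v
    } else {
        message(sprintf("readSpectrumCsv: resampling %d samples onto the %g-%g nm grid",
                        length(wl), grid@startNm, grid@stopNm))
        out <- stats::approx(wl, v, xout = newWl, rule = 1)$y
        out[is.na(out)] <- 0
    }
    if (transmittance) newTransmittance(grid, out) else newSpectrum(grid, out)
}

#' Write a spectrum to CSV
#'
#' Writes the `wavelength_nm,value` dialect; the round trip through
#' [readSpectrumCsv()] is lossless to better than 1e-9 relative.
#'
#' @param spectrum a [Spectrum-class]
#' @param path file path
#' @return `path`, invisibly
#' @export
writeSpectrumCsv <- function(spectrum, path) {
    df <- data.frame(wavelength_nm = wavelengths(spectrum),
                     value = spectrum@values)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
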