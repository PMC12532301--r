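#' Construct a uniform wavelength grid
#'
#' @param startNm,stopNm grid bounds in nm, `startNm < stopNm`
#' @param stepNm sample spacing in nm; must divide `stopNm - startNm`
#' @return a [WavelengthGrid-class]
#' @examples
#' g <- makeGrid(390, 780, 1)
#' length(wavelengths(g))  # 391
#' @export
makeGrid <- function(startNm, stopNm, stepNm = 1) {
    new("WavelengthGrid", startNm = as.numeric(startNm),
        stopNm = as.numeric(stopNm), stepNm = as.numeric(stepNm))
}

#' Default spectral grid
#'
#' 390-780 nm at 1 nm, covering the support of all modeled primaries.
#' @return a [WavelengthGrid-class]
#' @export
defaultGrid <- function() makeGrid(390, 780, 1)

gridLength <- function(grid)
    as.integer(round((grid@stopNm - grid@startNm) / grid@stepNm)) + 1L

gridDef <- function(grid) c(grid@startNm, grid@stopNm, grid@stepNm)

sameGrid <- function(a, b) isTRUE(all.equal(gridDef(a), gridDef(b)))

#' Grid sample wavelengths
#'
#' @param grid a [WavelengthGrid-class], or any object carrying one
#'   (Spectrum, ConeSensitivity, PrereceptoralFilter)
#' @return numeric vector of sample wavelengths (nm)
#' @export
wavelengths <- function(grid) {
    if (!is(grid, "WavelengthGrid")) grid <- grid@grid
    seq(grid@startNm, grid@stopNm, by = grid@stepNm)
}

#' Grid step
#' @param grid a [WavelengthGrid-class] or object carrying one
#' @return sample spacing in nm
#' @export
gridStep <- function(grid) {
    if (!is(grid, "WavelengthGrid")) grid <- grid@grid
    grid@stepNm
}

stopIfGridMismatch <- function(a, b, what = "operands") {
    ga <- if (is(a, "WavelengthGrid")) a else a@grid
    gb <- if (is(b, "WavelengthGrid")) b else b@grid
    if (!sameGrid(ga, gb))
        rmStop(sprintf("%s must share one wavelength grid (got [%s] and [%s])",
                       what, paste(gridDef(ga), collapse = ", "),
                       paste(gridDef(gb), collapse = ", ")),
               "gridMismatch")
    invisible(TRUE)
}

# classed conditions so callers can distinguish model errors from bugs
rmStop <- function(msg, class, ...) {
    stop(structure(class = c(class, "rayleighMatchError", "error", "condition"),
                   list(message = msg, call = sys.call(-1), ...)))
}
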