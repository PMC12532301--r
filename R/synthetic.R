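#' Cohort specification for simulated studies
#'
#' Bundles the parameters of a simulated Rayleigh-match study: class
#' counts, the wavenumber-shift distributions that generate anomalous
#' pigments, the small pigment jitter that produces normal individual
#' differences, and the per-setting adjustment noise.
#'
#' Defaults mirror the structure of a typical laboratory cohort: 24
#' normals and 8 anomalous trichromats (4 protanomalous, 4
#' deuteranomalous), at least three settings per session, two sessions on
#' the primary instrument. Shift signs follow the package convention
#' (positive = pigment peak toward shorter wavelengths): protanomalous
#' M' sits long of M (negative shift; the default -220 cm^-1 puts M' near
#' 536 nm), deuteranomalous L' short of L (positive shift; +240 cm^-1
#' puts L' near 552 nm) — the classic anomalous pigment positions. The
#' normal jitter default (60 cm^-1, about 2 nm of lambda-max spread)
#' stands for the polymorphic variation among normal L pigments.
#'
#' @param nNormal,nProtan,nDeutan class counts (>= 0)
#' @param protanShiftMeanCm1,protanShiftSdCm1 protan M'-shift distribution
#'   (cm^-1)
#' @param deutanShiftMeanCm1,deutanShiftSdCm1 deutan L'-shift distribution
#'   (cm^-1)
#' @param normalJitterSdCm1 SD of the small L-pigment jitter giving normal
#'   individual differences (cm^-1)
#' @param settingNoiseSd SD of per-setting adjustment noise, expressed on
#'   a unit control scale and rescaled by each instrument's control-range
#'   width
#' @param amberNoiseRel relative SD of the amber-intensity setting noise
#' @param settingsPerSession settings per session (>= 1)
#' @param seed master RNG seed
#' @return a validated list of class `"CohortSpec"`
#' @export
cohortSpec <- function(nNormal = 24, nProtan = 4, nDeutan = 4,
                       protanShiftMeanCm1 = -220, protanShiftSdCm1 = 60,
                       deutanShiftMeanCm1 = 240, deutanShiftSdCm1 = 60,
                       normalJitterSdCm1 = 60, settingNoiseSd = 0.005,
                       amberNoiseRel = 0.05, settingsPerSession = 3,
                       seed = 1L) {
    spec <- list(nNormal = nNormal, nProtan = nProtan, nDeutan = nDeutan,
                 protanShiftMeanCm1 = protanShiftMeanCm1,
                 protanShiftSdCm1 = protanShiftSdCm1,
                 deutanShiftMeanCm1 = deutanShiftMeanCm1,
                 deutanShiftSdCm1 = deutanShiftSdCm1,
                 normalJitterSdCm1 = normalJitterSdCm1,
                 settingNoiseSd = settingNoiseSd,
                 amberNoiseRel = amberNoiseRel,
                 settingsPerSession = settingsPerSession,
                 seed = as.integer(seed))
    counts <- c(nNormal, nProtan, nDeutan)
    if (any(counts < 0) || any(counts != round(counts)))
        rmStop("class counts must be non-negative integers", "badArgument")
    if (any(c(protanShiftSdCm1, deutanShiftSdCm1, normalJitterSdCm1,
              settingNoiseSd, amberNoiseRel) < 0))
        rmStop("SDs must be >= 0", "badArgument")
    if (settingsPerSession < 1)
        rmStop("settingsPerSession must be >= 1", "badArgument")
    structure(spec, class = "CohortSpec")
}

# stable string hash -> seed in [0, 2^31 - 2]; keeps per-cell streams
# reproducible independently of simulation order
deriveSeed <- function(masterSeed, ...) {
    s <- paste(masterSeed, ..., sep = "|")
    h <- 0
    for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
    as.integer(h)
}

#' Sample a cohort of observers
#'
#' Draws per-observer pigment shifts from the class-specific normal
#' distributions in the spec and materializes each observer by the
#' strip-shift-restore construction. Normal observers receive a small
#' jitter shift on the L branch, so individual differences (and hence
#' cross-instrument behavior) arise spectrally rather than as additive
#' offsets on any one instrument's scale. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec a [cohortSpec()]
#' @param fundamentals output of [buildNormalFundamentals()]
#' @param pre a [PrereceptoralFilter-class]
#' @param buildObservers materialize the [Observer-class] objects (set
#'   FALSE to draw only ids/kinds/shifts, e.g. for large statistical
#'   checks of the shift distributions)
#' @return list, one element per observer, each with `id`, `kind`,
#'   `shiftCm1`, and (when built) the [Observer-class] in `observer`
#' @export
sampleCohort <- function(spec, fundamentals = buildNormalFundamentals(),
                         pre = prereceptoralTemplate(fundamentals$L@grid),
                         buildObservers = TRUE) {
    stopifnot(inherits(spec, "CohortSpec"))
    set.seed(deriveSeed(spec$seed, "cohort"))
    kinds <- c(rep("normal", spec$nNormal),
               rep("protanomalous", spec$nProtan),
               rep("deuteranomalous", spec$nDeutan))
    shifts <- c(stats::rnorm(spec$nNormal, 0, spec$normalJitterSdCm1),
                stats::rnorm(spec$nProtan, spec$protanShiftMeanCm1,
                             spec$protanShiftSdCm1),
                stats::rnorm(spec$nDeutan, spec$deutanShiftMeanCm1,
                             spec$deutanShiftSdCm1))
    out <- vector("list", length(kinds))
    for (i in seq_along(kinds)) {
        out[[i]] <- list(id = sprintf("obs%03d", i), kind = kinds[i],
                         shiftCm1 = shifts[i])
        if (buildObservers)
            out[[i]]$observer <- makeAnomalousObserver(fundamentals, kinds[i],
                                                       shifts[i], pre)
    }
    out
}

#' Simulate one session of repeated settings
#'
#' Draws `nSettings` independent match settings around the observer's
#' predicted match: lambda* plus Gaussian adjustment noise, clipped to the
#' control range (clipping flagged, never silent). The recorded amber
#' intensity is the brightness-equating intensity at the set lambda with
#' proportional noise. An observer with no match inside the control range
#' raises the `noMatchInRange` condition — the extreme-anomalous case.
#'
#' @param observer an [Observer-class]
#' @param instrument an [Instrument-class]
#' @param nSettings settings to draw (>= 1)
#' @param noiseSd setting noise SD on this instrument's control scale
#' @param seed RNG seed for this session
#' @param amberNoiseRel relative SD of amber-intensity noise
#' @return data.frame with columns `repetition`, `lambda`,
#'   `amber_intensity`, `clipped`
#' @export
simulateSession <- function(observer, instrument, nSettings = 3,
                            noiseSd = 0.005, seed = 1L,
                            amberNoiseRel = 0.05) {
    if (nSettings < 1) rmStop("nSettings must be >= 1", "badArgument")
    lamStar <- lambdaStar(predictMatch(instrument, observer))
    set.seed(seed)
    raw <- lamStar + stats::rnorm(nSettings, 0, noiseSd)
    cr <- controlRange(instrument)
    clipped <- raw < cr[1] | raw > cr[2]
    lam <- pmin(pmax(raw, cr[1]), cr[2])
    amber <- vapply(lam, function(l) {
        as.numeric(brightnessMatchIntensity(instrument, observer, l))
    }, numeric(1))
    amber <- pmax(amber * (1 + stats::rnorm(nSettings, 0, amberNoiseRel)), 0)
    data.frame(repetition = seq_len(nSettings), lambda = lam,
               amber_intensity = amber, clipped = clipped)
}

#' Simulate a full multi-instrument study
#'
#' Runs the session plan over a cohort: by default the first instrument
#' is tested in two sessions (test-retest) and every further instrument
#' in one session, mirroring a two-visit protocol. Observers for whom an
#' instrument yields no match inside its control range are excluded: they
#' contribute no settings and are listed in the `"exclusions"` attribute,
#' the analogue of excluding extreme anomalous observers from a cohort.
#'
#' Per-cell RNG streams are derived by stable hashing of
#' (observer id, instrument, session), so any sub-table regenerates
#' identically.
#'
#' @param cohort output of [sampleCohort()]
#' @param instruments named list of [Instrument-class] (>= 1)
#' @param spec the [cohortSpec()] (noise and session parameters)
#' @param sessionPlan named integer vector: sessions per instrument;
#'   default `c(2, 1, 1, ...)` over `instruments`
#' @return a `StudyTable` data.frame with columns `observer_id`,
#'   `true_label`, `instrument`, `session`, `repetition`, `lambda`,
#'   `amber_intensity`, `clipped`, `excluded`; attribute `"exclusions"`
#'   records (observer_id, instrument, reason)
#' @export
simulateStudy <- function(cohort, instruments, spec, sessionPlan = NULL) {
    if (length(instruments) < 1)
        rmStop("need at least one instrument", "badArgument")
    if (is.null(names(instruments)))
        names(instruments) <- vapply(instruments, instrumentName, character(1))
    if (is.null(sessionPlan)) {
        sessionPlan <- c(2L, rep(1L, length(instruments) - 1L))
        names(sessionPlan) <- names(instruments)
    }
    excl <- data.frame(observer_id = character(0), instrument = character(0),
                       reason = character(0))
    rows <- list()
    excludedIds <- character(0)
    for (obs in cohort) {
        for (instName in names(instruments)) {
            inst <- instruments[[instName]]
            noiseSd <- spec$settingNoiseSd * diff(controlRange(inst))
            for (sess in seq_len(sessionPlan[[instName]])) {
                res <- tryCatch(
                    simulateSession(obs$observer, inst,
                                    spec$settingsPerSession, noiseSd,
                                    seed = deriveSeed(spec$seed, obs$id,
                                                      instName, sess),
                                    amberNoiseRel = spec$amberNoiseRel),
                    noMatchInRange = function(e) e)
                if (inherits(res, "condition")) {
                    excl <- rbind(excl, data.frame(
                        observer_id = obs$id, instrument = instName,
                        reason = conditionMessage(res)))
                    excludedIds <- union(excludedIds, obs$id)
                    break
                }
                res$observer_id <- obs$id
                res$true_label <- obs$kind
                res$instrument <- instName
                res$session <- sess
                rows[[length(rows) + 1L]] <- res
            }
        }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
        data.frame(repetition = integer(0), lambda = numeric(0),
                   amber_intensity = numeric(0), clipped = logical(0),
                   observer_id = character(0), true_label = character(0),
                   instrument = character(0), session = integer(0))
    tab$excluded <- tab$observer_id %in% excludedIds
    tab <- tab[, c("observer_id", "true_label", "instrument", "session",
                   "repetition", "lambda", "amber_intensity", "clipped",
                   "excluded")]
    rownames(tab) <- NULL
    attr(tab, "exclusions") <- excl
    tab
}

#' Write / read a study table CSV
#'
#' Header: `observer_id,true_label,instrument,session,repetition,lambda,`
#' `amber_intensity,clipped,excluded`.
#'
#' @param table a study table from [simulateStudy()]
#' @param path file path
#' @return `writeStudyCsv`: `path` invisibly; `readStudyCsv`: the table
#' @export
writeStudyCsv <- function(table, path) {
    utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeStudyCsv
#' @export
readStudyCsv <- function(path) {
    need <- c("observer_id", "true_label", "instrument", "session",
              "repetition", "lambda", "amber_intensity", "clipped", "excluded")
    df <- utils::read.csv(path)
    miss <- setdiff(need, names(df))
    if (length(miss))
        rmStop(sprintf("%s: missing column(s) %s", path,
                       paste(miss, collapse = ", ")), "malformedCsv")
    df
}

#' Calibrate pigment jitter for a target between-observer SD
#'
#' The small-jitter map from L-pigment shift to predicted match is locally
#' linear; this measures its slope by central difference and returns the
#' jitter SD (cm^-1) that induces the requested SD of true matches on the
#' given instrument's control scale.
#'
#' @param instrument an [Instrument-class]
#' @param targetLambdaSd desired SD of true lambda* across normals
#' @param fundamentals output of [buildNormalFundamentals()]
#' @param pre a [PrereceptoralFilter-class]
#' @param probeCm1 half-width of the central difference (default 50 cm^-1)
#' @return jitter SD in cm^-1; attribute `"slope"` carries d(lambda*)/d(shift)
#' @export
jitterSdForLambdaSd <- function(instrument, targetLambdaSd,
                                fundamentals = buildNormalFundamentals(),
                                pre = prereceptoralTemplate(fundamentals$L@grid),
                                probeCm1 = 50) {
    lam <- function(s) lambdaStar(predictMatch(
        instrument, makeAnomalousObserver(fundamentals, "normal", s, pre)))
    slope <- (lam(probeCm1) - lam(-probeCm1)) / (2 * probeCm1)
    if (abs(slope) < 1e-12)
        rmStop("match is insensitive to pigment shift on this instrument",
               "degenerateField")
    structure(targetLambdaSd / abs(slope), slope = slope)
}
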