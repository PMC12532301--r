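#' Summarize sessions of a study table
#'
#' Collapses repeated settings to per-(observer, instrument, session)
#' means — the analysis unit for all correlations. Excluded observers are
#' carried through with their flag and dropped only when correlations are
#' formed.
#'
#' @param table a study table (see [simulateStudy()])
#' @return data.frame with columns `observer_id`, `true_label`,
#'   `instrument`, `session`, `meanLambda`, `sdLambda`, `n`, `excluded`
#' @export
summarizeSessions <- function(table) {
    if (is.null(table) || nrow(table) == 0)
        rmStop("study table is empty", "badArgument")
    key <- interaction(table$observer_id, table$instrument, table$session,
                       drop = TRUE)
    split_ <- split(table, key)
    out <- do.call(rbind, lapply(split_, function(d) {
        data.frame(observer_id = d$observer_id[1],
                   true_label = d$true_label[1],
                   instrument = d$instrument[1], session = d$session[1],
                   meanLambda = mean(d$lambda),
                   sdLambda = if (nrow(d) > 1) stats::sd(d$lambda) else 0,
                   n = nrow(d), excluded = d$excluded[1])
    }))
    rownames(out) <- NULL
    out[order(out$observer_id, out$instrument, out$session), ]
}

#' Correlation coefficient with t-approximation p-value
#'
#' Pearson is the product-moment coefficient; Spearman is Pearson applied
#' to midrank-transformed data (ties get midranks). The two-sided p-value
#' uses the t approximation with n - 2 degrees of freedom. For small
#' samples (n <= 8) an exact permutation p-value is available as a
#' cross-check.
#'
#' @param x,y numeric vectors of equal length >= 3, finite, non-constant
#' @param method `"pearson"` or `"spearman"`
#' @param exact also compute the exact permutation p (n <= 8 only)
#' @return list with `estimate`, `p.value`, `n`, `method` (and
#'   `p.permutation` when `exact`)
#' @export
correlationTest <- function(x, y, method = c("pearson", "spearman"),
                            exact = FALSE) {
    method <- match.arg(method)
    if (length(x) != length(y)) rmStop("x and y must have equal length",
                                       "badArgument")
    n <- length(x)
    if (n < 3) rmStop("need at least 3 pairs", "badArgument")
    if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
        rmStop("values must be finite", "badArgument")
    if (method == "spearman") { x <- rank(x); y <- rank(y) }
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        rmStop("correlation undefined: zero variance", "zeroVariance")
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    p <- if (abs(r) >= 1) 0 else {
        tstat <- r * sqrt((n - 2) / (1 - r^2))
        2 * stats::pt(-abs(tstat), df = n - 2)
    }
    out <- list(estimate = r, p.value = p, n = n, method = method)
    if (exact) {
        if (n > 8) rmStop("exact permutation p is limited to n <= 8",
                          "badArgument")
        perms <- permutationsOf(n)
        xc <- x - mean(x)
        yc <- y - mean(y)
        denom <- sqrt(sum(xc^2) * sum(yc^2))
        robs <- sum(xc * yc) / denom
        rperm <- apply(perms, 1, function(p_) sum(xc * yc[p_]) / denom)
        out$p.permutation <- mean(abs(rperm) >= abs(robs) - 1e-12)
    }
    out
}

permutationsOf <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- permutationsOf(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
        rest <- seq_len(n)[-i]
        cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
    }))
}

#' Closed-form expected test-retest correlation
#'
#' For session means of n settings with between-observer SD `sigmaB` of
#' true matches and within-observer setting SD `sigmaW`, the expected
#' Pearson correlation between two session means is
#' sigmaB^2 / (sigmaB^2 + sigmaW^2 / n).
#'
#' @param sigmaB between-observer SD of true matches
#' @param sigmaW within-observer per-setting SD
#' @param n settings per session
#' @return expected Pearson R
#' @export
expectedRetestR <- function(sigmaB, sigmaW, n)
    sigmaB^2 / (sigmaB^2 + sigmaW^2 / n)

#' Classification reference for an instrument
#'
#' Derives the normal range and the side-to-phenotype mapping from the
#' model itself: the center is the textbook normal observer's predicted
#' match; the halfwidth defaults to 4x the between-observer SD that the
#' cohort spec's normal pigment jitter induces on this instrument's
#' scale; and the direction each anomaly moves the match is computed from
#' archetype observers (never hard-coded).
#'
#' @param instrument an [Instrument-class]
#' @param fundamentals output of [buildNormalFundamentals()]
#' @param pre a [PrereceptoralFilter-class]
#' @param normalJitterSdCm1 jitter SD of the cohort's normals (cm^-1)
#' @param halfwidth override the normal-range halfwidth (control units)
#' @param archetypeShiftCm1 |shift| of the archetype anomalous observers
#' @return list with `center`, `halfwidth`, `protanSide`, `deutanSide`
#'   (+1 / -1 on the control scale), `instrument`
#' @export
classificationReference <- function(instrument,
                                    fundamentals = buildNormalFundamentals(),
                                    pre = prereceptoralTemplate(fundamentals$L@grid),
                                    normalJitterSdCm1 = 60, halfwidth = NULL,
                                    archetypeShiftCm1 = 230) {
    center <- lambdaStar(predictMatch(instrument,
                                      makeNormalObserver(fundamentals)))
    if (is.null(halfwidth)) {
        slope <- attr(jitterSdForLambdaSd(instrument, 1, fundamentals, pre),
                      "slope")
        halfwidth <- 4 * normalJitterSdCm1 * abs(slope)
    }
    side <- function(kind, s) {
        lam <- lambdaStar(predictMatch(
            instrument, makeAnomalousObserver(fundamentals, kind, s, pre)))
        sign(lam - center)
    }
    protanSide <- side("protanomalous", -archetypeShiftCm1)
    deutanSide <- side("deuteranomalous", archetypeShiftCm1)
    if (protanSide == deutanSide)
        rmStop("archetype anomalies fall on the same side of the normal match",
               "degenerateField")
    list(center = center, halfwidth = halfwidth, protanSide = protanSide,
         deutanSide = deutanSide, instrument = instrumentName(instrument))
}

#' Classify an observer from a session-mean setting
#'
#' Within the closed normal interval [center - halfwidth,
#' center + halfwidth] the label is `"normal"` (boundary values inclusive);
#' outside it, the side determines `"protan-side"` or `"deutan-side"` via
#' the reference's computed side mapping. Missing or excluded settings are
#' `"unclassifiable"`.
#'
#' @param meanLambda session-mean setting (NA allowed)
#' @param reference a [classificationReference()]
#' @param excluded logical; force `"unclassifiable"`
#' @return one of `"normal"`, `"protan-side"`, `"deutan-side"`,
#'   `"unclassifiable"`
#' @export
classifyObserver <- function(meanLambda, reference, excluded = FALSE) {
    if (excluded || is.na(meanLambda)) return("unclassifiable")
    d <- meanLambda - reference$center
    if (abs(d) <= reference$halfwidth) return("normal")
    if (sign(d) == reference$protanSide) "protan-side" else "deutan-side"
}

sessionMeans <- function(summaries, instrument, session, dropExcluded = TRUE) {
    s <- summaries[summaries$instrument == instrument &
                   summaries$session == session, ]
    if (dropExcluded) s <- s[!s$excluded, ]
    s
}

#' Test-retest reliability report
#'
#' Pearson and Spearman correlations between two sessions' per-observer
#' mean settings on one instrument, for the normals-only subset or the
#' full sample. Excluded observers never enter a correlation.
#'
#' @param summaries output of [summarizeSessions()]
#' @param instrument instrument name
#' @param sessions length-2 integer vector (default 1:2)
#' @param subset `"all"` or `"normals"`
#' @return list of class `"ReliabilityReport"`: `pearson_r`,
#'   `pearson_p`, `spearman_rho`, `spearman_p`, `n_observers`, `subset`,
#'   `pairs` (the scatter-pair table)
#' @export
reliabilityReport <- function(summaries, instrument, sessions = c(1, 2),
                              subset = c("all", "normals")) {
    subset <- match.arg(subset)
    s1 <- sessionMeans(summaries, instrument, sessions[1])
    s2 <- sessionMeans(summaries, instrument, sessions[2])
    if (subset == "normals") {
        s1 <- s1[s1$true_label == "normal", ]
        s2 <- s2[s2$true_label == "normal", ]
    }
    ids <- intersect(s1$observer_id, s2$observer_id)
    if (length(ids) < 3)
        rmStop("need >= 3 non-excluded observers with both sessions",
               "insufficientData")
    x <- s1$meanLambda[match(ids, s1$observer_id)]
    y <- s2$meanLambda[match(ids, s2$observer_id)]
    pe <- correlationTest(x, y, "pearson")
    sp <- correlationTest(x, y, "spearman")
    structure(list(pearson_r = pe$estimate, pearson_p = pe$p.value,
                   spearman_rho = sp$estimate, spearman_p = sp$p.value,
                   n_observers = length(ids), subset = subset,
                   instrument = instrument,
                   pairs = data.frame(observer_id = ids, session1 = x,
                                      session2 = y)),
              class = "ReliabilityReport")
}

#' Cross-instrument report
#'
#' Correlates per-observer session means across two instruments on their
#' raw scales (no anomalous-quotient transform: those presume identical
#' primaries), classifies every observer on each instrument, and tabulates
#' agreement. The contradictory-diagnosis count is the number of observers
#' labeled on opposite anomalous sides by the two instruments.
#'
#' @param summaries output of [summarizeSessions()]
#' @param instrumentA,instrumentB instrument names
#' @param referenceA,referenceB [classificationReference()]s for the two
#'   instruments
#' @param session session number to compare (default 1)
#' @return list of class `"CrossInstrumentReport"`: `pearson_r`,
#'   `pearson_p`, `spearman_rho`, `spearman_p`, `n_observers`,
#'   `agreement` (3x3 label matrix), `contradictory` (count),
#'   `offDiagonal` (count), `pairs`
#' @export
crossInstrumentReport <- function(summaries, instrumentA, instrumentB,
                                  referenceA, referenceB, session = 1) {
    sA <- sessionMeans(summaries, instrumentA, session)
    sB <- sessionMeans(summaries, instrumentB, session)
    ids <- intersect(sA$observer_id, sB$observer_id)
    if (length(ids) < 3)
        rmStop("need >= 3 observers measured on both instruments",
               "insufficientData")
    x <- sA$meanLambda[match(ids, sA$observer_id)]
    y <- sB$meanLambda[match(ids, sB$observer_id)]
    pe <- correlationTest(x, y, "pearson")
    sp <- correlationTest(x, y, "spearman")
    labA <- vapply(x, classifyObserver, character(1), reference = referenceA)
    labB <- vapply(y, classifyObserver, character(1), reference = referenceB)
    lvls <- c("normal", "protan-side", "deutan-side")
    agreement <- table(factor(labA, lvls), factor(labB, lvls),
                       dnn = c(instrumentA, instrumentB))
    contradictory <- sum((labA == "protan-side" & labB == "deutan-side") |
                         (labA == "deutan-side" & labB == "protan-side"))
    structure(list(pearson_r = pe$estimate, pearson_p = pe$p.value,
                   spearman_rho = sp$estimate, spearman_p = sp$p.value,
                   n_observers = length(ids), agreement = agreement,
                   contradictory = contradictory,
                   offDiagonal = sum(agreement) - sum(diag(agreement)),
                   pairs = data.frame(observer_id = ids, a = x, b = y,
                                      labelA = labA, labelB = labB)),
              class = "CrossInstrumentReport")
}

#' Scatter plot of paired session means
#'
#' Base-graphics scatter of the pairs in a reliability or cross-instrument
#' report, one point per observer.
#'
#' @param report a `"ReliabilityReport"` or `"CrossInstrumentReport"`
#' @param ... passed to [graphics::plot()]
#' @return invisibly, the pair table plotted
#' @export
plotPairs <- function(report, ...) {
    p <- report$pairs
    xy <- p[, 2:3]
    graphics::plot(xy[[1]], xy[[2]], xlab = names(xy)[1], ylab = names(xy)[2],
                   pch = 19, ...)
    graphics::abline(0, 1, lty = 2)
    invisible(p)
}
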