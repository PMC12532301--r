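makeTable <- function(lambdas, observer = "obs001", label = "normal",
                      instrument = "penn", session = 1L) {
    data.frame(observer_id = observer, true_label = label,
               instrument = instrument, session = session,
               repetition = seq_along(lambdas), lambda = lambdas,
               amber_intensity = 1, clipped = FALSE, excluded = FALSE)
}

test_that("session summaries are per-cell means and SDs with honest bookkeeping", {
    tab <- makeTable(c(0.4, 0.5, 0.6))
    s <- summarizeSessions(tab)
    expect_equal(s$meanLambda, 0.5)
    expect_equal(s$sdLambda, 0.1)
    expect_identical(s$n, 3L)
    doubled <- summarizeSessions(rbind(tab, tab))
    expect_identical(doubled$n, 6L)
    expect_equal(doubled$meanLambda, 0.5)
    expect_error(summarizeSessions(tab[0, ]), "empty")
})

test_that("correlation: exact values, rank invariance, and failure on zero variance", {
    x <- c(0.1, 0.4, 0.2, 0.9, 0.5)
    pe <- correlationTest(x, 2 * x + 1, "pearson")
    expect_equal(pe$estimate, 1.0)
    expect_equal(correlationTest(c(1, 2, 3), c(1, 3, 2), "pearson")$estimate,
                 0.5)
    sp <- correlationTest(x, exp(x) + x^3, "spearman")
    expect_equal(sp$estimate, 1.0)
    expect_error(correlationTest(x, rep(1, 5)), class = "zeroVariance")
    expect_error(correlationTest(x, x[1:3]), "equal length")
    expect_error(correlationTest(x[1:2], x[1:2]), "at least 3")
})

test_that("correlation matches the reference implementation on random data", {
    set.seed(4)
    x <- rnorm(20)
    y <- 0.6 * x + rnorm(20, sd = 0.5)
    pe <- correlationTest(x, y, "pearson")
    ref <- cor.test(x, y, method = "pearson")
    expect_equal(pe$estimate, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(pe$p.value, ref$p.value, tolerance = 1e-12)
    sp <- correlationTest(x, y, "spearman")
    expect_equal(sp$estimate,
                 unname(cor.test(x, y, method = "spearman")$estimate),
                 tolerance = 1e-12)
})

test_that("pearson is invariant to positive affine transforms", {
    set.seed(9)
    x <- rnorm(12)
    y <- rnorm(12)
    base <- correlationTest(x, y)$estimate
    expect_equal(correlationTest(3 * x + 7, y)$estimate, base,
                 tolerance = 1e-12)
    expect_equal(correlationTest(x, 0.01 * y - 2)$estimate, base,
                 tolerance = 1e-12)
})

test_that("the exact permutation p-value matches enumeration for a strictly monotone pair", {
    x <- c(1, 2, 3, 4)
    out <- correlationTest(x, x^2, exact = TRUE)
    # by the rearrangement inequality only the sorted order attains +|r_obs|
    # and (x being equally spaced) only the reversed order attains -|r_obs|
    expect_equal(out$p.permutation, 2 / 24)
    expect_error(correlationTest(rnorm(9), rnorm(9), exact = TRUE), "n <= 8")
})

test_that("classification uses model-derived sides and a closed normal interval", {
    refP <- classificationReference(fixPenn, fixFund, fixPre)
    expect_identical(classifyObserver(refP$center, refP), "normal")
    expect_identical(classifyObserver(refP$center + refP$halfwidth, refP),
                     "normal")  # boundary is inclusive
    expect_identical(classifyObserver(NA, refP), "unclassifiable")
    expect_identical(classifyObserver(0.5, refP, excluded = TRUE),
                     "unclassifiable")
    expect_true(refP$protanSide != refP$deutanSide)
    # a deutan-constructed observer lands on the deutan archetype's side
    for (s in c(240, -800)) {
        lam <- lambdaStar(predictMatch(fixPenn, anomObs("deuteranomalous", s)))
        expect_identical(classifyObserver(lam, refP), "deutan-side")
    }
    lamProt <- lambdaStar(predictMatch(fixPenn, anomObs("protanomalous", -220)))
    expect_identical(classifyObserver(lamProt, refP), "protan-side")
})

test_that("noiseless studies give perfect test-retest reliability", {
    spec <- cohortSpec(nNormal = 6, nProtan = 0, nDeutan = 0,
                       settingNoiseSd = 0, amberNoiseRel = 0, seed = 31)
    st <- simulateStudy(sampleCohort(spec, fixFund, fixPre),
                        list(penn = fixPenn), spec)
    rep1 <- reliabilityReport(summarizeSessions(st), "penn")
    expect_equal(rep1$pearson_r, 1.0)
    expect_identical(rep1$n_observers, 6L)
    # regenerating the report from the same table is identical
    rep2 <- reliabilityReport(summarizeSessions(st), "penn")
    expect_identical(rep1, rep2)
})

test_that("excluded observers never enter correlations", {
    spec <- cohortSpec(nNormal = 4, nProtan = 0, nDeutan = 0, seed = 63)
    coh <- sampleCohort(spec, fixFund, fixPre)
    st <- simulateStudy(coh, list(penn = fixPenn, offgamut = offGamutPenn),
                        spec)
    s <- summarizeSessions(st)
    expect_true(all(s$excluded))
    expect_error(reliabilityReport(s, "penn"), class = "insufficientData")
})

test_that("cross-instrument self-comparison is perfect and scale-invariant", {
    spec <- cohortSpec(nNormal = 5, nProtan = 2, nDeutan = 2, seed = 17)
    coh <- sampleCohort(spec, fixFund, fixPre)
    st <- simulateStudy(coh, list(penn = fixPenn, penn2 = fixPenn), spec,
                        sessionPlan = c(penn = 1L, penn2 = 1L))
    s <- summarizeSessions(st)
    refP <- classificationReference(fixPenn, fixFund, fixPre)
    # same instrument on both axes but independent noise: near-perfect, not
    # contradictory; for exactness compare the instrument with itself
    sSelf <- s
    rep <- crossInstrumentReport(rbind(
        sSelf, transform(sSelf, instrument = "copy")), "penn", "copy",
        refP, refP)
    expect_equal(rep$pearson_r, 1.0)
    expect_identical(rep$contradictory, 0L)
    expect_identical(rep$offDiagonal, 0L)
    # pearson r is unchanged by expressing one axis on a 0-73-like scale
    s73 <- transform(sSelf, instrument = "scaled", meanLambda = 73 * meanLambda)
    ref73 <- refP
    ref73$center <- 73 * refP$center
    ref73$halfwidth <- 73 * refP$halfwidth
    repScaled <- crossInstrumentReport(rbind(sSelf, s73), "penn", "scaled",
                                       refP, ref73)
    expect_equal(repScaled$pearson_r, 1.0, tolerance = 1e-12)
    expect_identical(repScaled$contradictory, 0L)
})

test_that("zero-noise cohorts are classified identically on both instruments", {
    spec <- cohortSpec(nNormal = 6, nProtan = 3, nDeutan = 3,
                       settingNoiseSd = 0, amberNoiseRel = 0, seed = 29)
    coh <- sampleCohort(spec, fixFund, fixPre)
    st <- simulateStudy(coh, list(penn = fixPenn, oculus = fixOculus), spec)
    s <- summarizeSessions(st)
    refP <- classificationReference(fixPenn, fixFund, fixPre,
                                    normalJitterSdCm1 = spec$normalJitterSdCm1)
    refO <- classificationReference(fixOculus, fixFund, fixPre,
                                    normalJitterSdCm1 = spec$normalJitterSdCm1)
    rep <- crossInstrumentReport(s, "penn", "oculus", refP, refO)
    expect_identical(rep$contradictory, 0L)
    expect_identical(rep$offDiagonal, 0L)
    truth <- vapply(coh, `[[`, character(1), "kind")
    lab <- rep$pairs$labelA[match(vapply(coh, `[[`, character(1), "id"),
                                  rep$pairs$observer_id)]
    expect_identical(unname(lab[truth == "protanomalous"]),
                     rep("protan-side", 3))
    expect_identical(unname(lab[truth == "deuteranomalous"]),
                     rep("deutan-side", 3))
})

test_that("the closed-form retest correlation is recovered by simulation", {
    # one modest regime as a unit check; the acceptance suite sweeps more
    sigmaB <- 0.02; sigmaW <- 0.005; n <- 3
    jit <- as.numeric(jitterSdForLambdaSd(fixPenn, sigmaB, fixFund, fixPre))
    rs <- vapply(1:40, function(i) {
        spec <- cohortSpec(nNormal = 30, nProtan = 0, nDeutan = 0,
                           normalJitterSdCm1 = jit, settingNoiseSd = sigmaW,
                           settingsPerSession = n, seed = 1000 + i)
        st <- simulateStudy(sampleCohort(spec, fixFund, fixPre),
                            list(penn = fixPenn), spec)
        reliabilityReport(summarizeSessions(st), "penn")$pearson_r
    }, numeric(1))
    expect_lt(abs(mean(rs) - expectedRetestR(sigmaB, sigmaW, n)), 0.05)
})
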