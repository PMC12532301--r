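test_that("cone excitation is the energy inner product: annihilation, linearity, impulse", {
    zero <- newSpectrum(fixGrid, rep(0, 391))
    expect_identical(coneExcitation(zero, fixFund$L), 0)
    spd <- synthesizeLedSpd(592, 16, fixGrid)
    expect_identical(coneExcitation(scaleSpectrum(spd, 2), fixFund$L),
                     2 * coneExcitation(spd, fixFund$L))
    # single-sample impulse: direct lookup oracle
    v <- rep(0, 391)
    i560 <- match(560, wavelengths(fixGrid))
    v[i560] <- 3.7
    expect_equal(coneExcitation(newSpectrum(fixGrid, v), fixFund$M),
                 3.7 * specValues(fixFund$M)[i560] * 1)
    expect_error(coneExcitation(synthesizeLedSpd(592, 16, makeGrid(400, 700, 1)),
                                fixFund$M), class = "gridMismatch")
})

test_that("ratio curves: identical cones give unity, the normal penn curve rises with red", {
    twin <- anomObs("deuteranomalous", 0)  # L paired with an identical copy
    rc <- excitationRatioCurve(fixPenn, twin, 51)
    expect_equal(rc$ratio, rep(1, 51), tolerance = 1e-9)
    rcN <- excitationRatioCurve(fixPenn, fixNormal, 101)
    expect_true(all(diff(rcN$ratio) > 0))
    expect_false(any(rcN$flagged))
    expect_error(excitationRatioCurve(fixPenn, fixNormal, 1), "nPoints")
})

test_that("the excitation ratio is invariant to common rescaling of the mixture channels", {
    scaled <- fixPenn
    scaled@red <- newPrimaryChannel(scaled@red@spd,
                                    function(l) 3 * l)
    scaled@green <- newPrimaryChannel(scaled@green@spd,
                                      local({
                                          base <- fixPenn@green@outputCurve
                                          function(l) 3 * base(l)
                                      }))
    a <- excitationRatioCurve(fixPenn, fixNormal, 41)$ratio
    b <- excitationRatioCurve(scaled, fixNormal, 41)$ratio
    expect_equal(a, b, tolerance = 1e-12)
})

test_that("the amber ratio is intensity-invariant and consistent with the mixture ratio", {
    expect_equal(referenceRatio(fixPenn, fixNormal, 1),
                 referenceRatio(fixPenn, fixNormal, 10 / 10 * 1.9),
                 tolerance = 1e-12)
    expect_equal(referenceRatio(fixPenn, anomObs("deuteranomalous", 0)), 1,
                 tolerance = 1e-9)
    expect_error(referenceRatio(fixPenn, fixNormal, 0), "amberIntensity")
    # amber physically equal to a mixture: same spectrum, same ratio
    lam0 <- 0.35
    phys <- setAmberSpd(fixPenn, mixtureSpd(fixPenn, lam0))
    rc <- excitationRatioCurve(fixPenn, fixNormal, 3)
    e <- mixtureSpd(fixPenn, lam0)
    expect_equal(referenceRatio(phys, fixNormal),
                 coneExcitation(e, coneA(fixNormal)) /
                     coneExcitation(e, coneB(fixNormal)),
                 tolerance = 1e-12)
})

test_that("physical-identity ambers force every observer type to match at lambda0", {
    observers <- list(fixNormal, anomObs("protanomalous", -220),
                      anomObs("deuteranomalous", 240))
    for (lam0 in c(0.25, 0.6)) {
        phys <- setAmberSpd(fixPenn, mixtureSpd(fixPenn, lam0))
        for (obs in observers)
            expect_equal(lambdaStar(predictMatch(phys, obs)), lam0,
                         tolerance = 1e-6)
        expect_lt(abs(bruteForceMatch(phys, fixNormal, 1e-3) - lam0), 1e-3 + 1e-12)
    }
})

test_that("predicted matches are amber-intensity invariant and agree with the grid oracle", {
    base <- lambdaStar(predictMatch(fixPenn, fixNormal, amberIntensity = 1))
    expect_lt(abs(lambdaStar(predictMatch(fixPenn, fixNormal, amberIntensity = 1.9)) -
                  base), 1e-9)
    set.seed(11)
    shifts <- runif(10, -1500, 1500)
    kinds <- sample(c("protanomalous", "deuteranomalous"), 10, replace = TRUE)
    for (i in seq_along(shifts)) {
        obs <- anomObs(kinds[i], shifts[i])
        expect_lt(abs(lambdaStar(predictMatch(fixPenn, obs)) -
                      bruteForceMatch(fixPenn, obs, 1e-4)), 1e-4 + 1e-12)
    }
})

test_that("the no-match condition reports which scale end the match lies beyond", {
    err <- tryCatch(predictMatch(offGamutPenn, fixNormal), error = identity)
    expect_s3_class(err, "noMatchInRange")
    expect_identical(err$signLow, err$signHigh)
    expect_error(predictMatch(fixPenn, anomObs("deuteranomalous", 0)),
                 class = "degenerateMatch")
})

test_that("brute force granularity: coarsening the grid moves the answer by at most one step", {
    obs <- anomObs("deuteranomalous", 240)
    fine <- bruteForceMatch(fixPenn, obs, 1e-3)
    coarse <- bruteForceMatch(fixPenn, obs, 1e-2)
    expect_lte(abs(fine - coarse), 1e-2)
})

test_that("matching ranges are nested in delta, degenerate at zero, and end-touching when huge", {
    obs <- anomObs("deuteranomalous", 240)
    mr0 <- matchingRange(fixPenn, obs, 0)
    expect_identical(rangeWidth(mr0), 0)
    expect_false(touchesEnd(mr0))
    widths <- vapply(c(0.001, 0.01, 0.1), function(d)
        rangeWidth(matchingRange(fixPenn, obs, d)), numeric(1))
    expect_true(all(diff(widths) >= 0))
    huge <- matchingRange(fixPenn, obs, 100)
    expect_true(touchesEnd(huge))
    expect_equal(c(huge@lambdaLo, huge@lambdaHi), controlRange(fixPenn))
})

test_that("the brightness-equating amber intensity reproduces the mixture's summed excitation", {
    for (lam in c(0.8, 0.9, 0.95)) {
        it <- brightnessMatchIntensity(fixPenn, fixNormal, lam)
        mix <- mixtureSpd(fixPenn, lam)
        amber <- referenceSpd(fixPenn, as.numeric(it))
        mixSum <- coneExcitation(mix, coneA(fixNormal)) +
            coneExcitation(mix, coneB(fixNormal))
        ambSum <- coneExcitation(amber, coneA(fixNormal)) +
            coneExcitation(amber, coneB(fixNormal))
        expect_equal(ambSum, mixSum, tolerance = 1e-9)
        expect_false(attr(it, "clamped"))
    }
    # a green-heavy mixture needs more amber than the control allows: clamped
    bright <- brightnessMatchIntensity(fixPenn, fixNormal, 0.3)
    expect_true(attr(bright, "clamped"))
    expect_equal(as.numeric(bright), amberRange(fixPenn)[2])
    expect_gt(attr(bright, "rawIntensity"), amberRange(fixPenn)[2])
    # doubling both channel outputs doubles the required amber intensity
    doubled <- fixPenn
    doubled@red <- newPrimaryChannel(fixPenn@red@spd, function(l) 2 * l)
    doubled@green <- newPrimaryChannel(fixPenn@green@spd,
                                       local({
                                           base <- fixPenn@green@outputCurve
                                           function(l) 2 * base(l)
                                       }))
    i1 <- brightnessMatchIntensity(fixPenn, fixNormal, 0.5)
    i2 <- brightnessMatchIntensity(doubled, fixNormal, 0.5)
    expect_equal(attr(i2, "rawIntensity"), 2 * attr(i1, "rawIntensity"),
                 tolerance = 1e-12)
})

test_that("predictions are invariant to common rescaling of mixture channels", {
    scaled <- fixPenn
    scaled@red <- newPrimaryChannel(fixPenn@red@spd, function(l) 5 * l)
    scaled@green <- newPrimaryChannel(fixPenn@green@spd,
                                      local({
                                          base <- fixPenn@green@outputCurve
                                          function(l) 5 * base(l)
                                      }))
    expect_lt(abs(lambdaStar(predictMatch(scaled, fixNormal)) -
                  lambdaStar(predictMatch(fixPenn, fixNormal))), 1e-9)
})
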