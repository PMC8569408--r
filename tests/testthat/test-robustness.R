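test_that("combination counts match brute-force enumeration", {
    grid <- electrodeGrid()
    for (n in 1:3) {
        combos <- enumerateCombinations(grid, n)
        brute <- bruteCombos(n)
        expect_length(combos, c(9L, 81L, 675L)[n])
        expect_setequal(vapply(combos, paste, character(1L),
                               collapse = "-"),
                        vapply(brute, paste, character(1L),
                               collapse = "-"))
        expect_false(any(vapply(combos, anyDuplicated, integer(1L)) > 0))
    }
    # deterministic order
    expect_identical(enumerateCombinations(grid, 3L),
                     enumerateCombinations(grid, 3L))
    expect_equal(enumerateCombinations(grid, 2L)[[1L]], c(1L, 13L))
    expect_error(enumerateCombinations(grid, 4L), "nChannels")
})

test_that("the overlap exclusion removes exactly 54 tuples", {
    # 9^3 minus left=middle collisions (3 shared channels x 9 rights)
    # minus middle=right collisions (3 shared x 9 lefts); no triple overlap
    expect_equal(9^3 - 27L - 27L, 675L)
    grid <- electrodeGrid()
    tup <- enumerateCombinations(grid, 3L)
    shared <- vapply(tup, function(t)
        t[1L] == t[2L] || t[2L] == t[3L] || t[1L] == t[3L], logical(1L))
    expect_false(any(shared))
})

test_that("ACA and RES arithmetic match their definitions", {
    expect_equal(computeAca(c(0.5, 1.0)), 0.75)
    expect_equal(computeAca(rep(0.37, 10L)), 0.37)
    set.seed(5)
    v <- stats::runif(100)
    expect_equal(computeAca(v), sum(v) / length(v))
    expect_equal(computeRes(rep(0.6, 9L)), 1)
    expect_equal(computeRes(c(0.4, 0.6)),
                 1 - stats::sd(c(0.4, 0.6)) / 0.5)
    expect_equal(computeRes(c(0.4, 0.6)), 0.7171573, tolerance = 1e-6)
    expect_equal(computeRes(c(0.4, 0.6), sd = "population"), 0.8)
    expect_error(computeRes(rep(0, 5L)), "undefined")
    expect_error(computeAca(numeric()), "empty")
    # perturbing a constant field strictly lowers RES
    base <- rep(0.8, 20L)
    pert <- base; pert[1L] <- 0.7
    expect_lt(computeRes(pert), computeRes(base))
})

test_that("per-combination accuracies are an elementwise map", {
    rec <- extractWindow(highSnrRec(), 2)
    combos <- list(11L, c(5L, 17L), c(5L, 11L, 17L))
    cc <- classifierConfig("MSI")
    acc <- accuracyPerCombination(rec, combos, cc)
    expect_length(acc, 3L)
    expect_equal(accuracyPerCombination(rec, rev(combos), cc), rev(acc))
    expect_error(accuracyPerCombination(rec, list(99L), cc), "absent")
    # denominator-one case: a single correctly classified trial
    tone <- pureToneRec(7.5)
    expect_equal(accuracyPerCombination(tone, list(1L, c(1L, 2L)),
                                        classifierConfig("CCA")),
                 c(1, 1))
})

test_that("subset scoring equals whole-recording scoring per algorithm", {
    rec <- extractWindow(midSnrRec(), 2)
    combos <- list(8L, c(3L, 19L), c(5L, 11L, 17L), c(9L, 9L + 4L, 21L))
    for (alg in c("CCA", "ECCA", "FBCCA", "MSI", "EMSI")) {
        cc <- classifierConfig(alg)
        fast <- accuracyPerCombination(rec, combos, cc)
        direct <- vapply(combos, function(ch)
            classificationAccuracy(rec, cc, channels = ch), numeric(1L))
        expect_identical(fast, direct, info = alg)
    }
})

test_that("robustness evaluation is reproducible and well-formed", {
    cfg <- simulationConfig(trialsPerFrequency = 3L, seed = 77L)
    rec <- extractWindow(bandpassRecording(simulateRecording(cfg)), 2)
    r1 <- evaluateRobustness(rec, electrodeGrid(),
                             classifierConfig("MSI"), 1L)
    expect_s4_class(r1, "RobustnessResult")
    expect_length(comboAccuracies(r1), 9L)
    expect_equal(aca(r1), mean(comboAccuracies(r1)))
    expect_equal(res(r1),
                 1 - stats::sd(comboAccuracies(r1)) /
                     mean(comboAccuracies(r1)))
    rec2 <- extractWindow(bandpassRecording(simulateRecording(cfg)), 2)
    r2 <- evaluateRobustness(rec2, electrodeGrid(),
                             classifierConfig("MSI"), 1L)
    expect_identical(comboAccuracies(r1), comboAccuracies(r2))
    # down-sampling keeps a deterministic subset
    r3 <- evaluateRobustness(rec, electrodeGrid(),
                             classifierConfig("MSI"), 3L, maxCombos = 10L)
    expect_lte(length(comboAccuracies(r3)), 10L)
})

test_that("same-direction shift map is anchored and normalized", {
    rec <- extractWindow(midSnrRec(), 2)
    m <- shiftDirectionMap(list(rec), config = classifierConfig("EMSI"))
    expect_equal(dim(m), c(3L, 3L))
    expect_true(all(m >= 0 & m <= 1))
    degenerateOrNormalized <- all(m == 0) ||
        (sum(m == 0) >= 1L && sum(m == 1) >= 1L)
    expect_true(degenerateOrNormalized)
    # the zero-shift cell uses exactly the anchor channels: verify by
    # comparing against a direct evaluation of (5, 11, 17)
    anchorsAcc <- accuracyPerCombination(rec, list(c(5L, 11L, 17L)),
                                         classifierConfig("EMSI"))
    allAcc <- vapply(
        list(c(4L, 10L, 16L), c(5L, 11L, 17L), c(6L, 12L, 18L),
             c(7L, 13L, 19L), c(2L, 8L, 14L), c(8L, 14L, 20L),
             c(1L, 7L, 13L), c(3L, 9L, 15L), c(9L, 15L, 21L)),
        function(ch) accuracyPerCombination(rec, list(ch),
                                            classifierConfig("EMSI")),
        numeric(1L))
    rng <- range(allAcc)
    if (rng[2L] > rng[1L])
        expect_equal(m["0", "0"],
                     (anchorsAcc - rng[1L]) / (rng[2L] - rng[1L]))
})

test_that("degenerate all-equal shift map warns and zeroes", {
    tone <- pureToneRec(7.5, nCh = 21L)   # every combo classifies right
    expect_warning(m <- shiftDirectionMap(list(tone)), "equal")
    expect_true(all(m == 0))
})
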