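test_that("reference matrices follow the harmonic sin/cos construction", {
    Y <- makeReference(6, 4L, 256, 512L)
    expect_equal(dim(Y), c(8L, 512L))
    expect_equal(Y[1L, 1L], sin(2 * pi * 6 * 1 / 256))
    expect_equal(Y[2L, 3L], cos(2 * pi * 6 * 3 / 256))
    expect_equal(Y[7L, 5L], sin(2 * pi * 4 * 6 * 5 / 256))
    # integer number of cycles: every row averages to zero
    expect_true(all(abs(rowMeans(makeReference(8, 4L, 256, 256L)))
                    < 1e-10))
    # distinct harmonics are orthogonal over near-integer cycle counts
    Y10 <- makeReference(10, 4L, 256, 1280L)
    G <- Y10 %*% t(Y10)
    expect_equal(diag(G), rep(640, 8L), tolerance = 1e-8)
    offDiag <- G - diag(diag(G))
    expect_lt(max(abs(offDiag)), 1e-6 * 1280)
    expect_error(makeReference(40, 4L, 256, 512L), "Nyquist")
})

test_that("canonical correlation is exact on spanned and oracle cases", {
    Y <- makeReference(7.5, 3L, 256, 640L)
    X <- Y[1:2, ]                      # X inside the span of Y
    expect_equal(ccaCoefficient(X, Y), 1, tolerance = 1e-8)
    set.seed(42)
    for (i in 1:25) {
        inst <- randomInstance(n = sample(1:3, 1L), nh = sample(2:4, 1L),
                               m = sample(c(64L, 128L, 256L), 1L))
        expect_equal(ccaCoefficient(inst$X, inst$Y),
                     ccaOracle(inst$X, inst$Y), tolerance = 1e-8)
    }
    # agreement with the standard CCA solver on one instance
    inst <- randomInstance(n = 3L, nh = 3L, m = 256L)
    expect_equal(ccaCoefficient(inst$X, inst$Y),
                 stats::cancor(t(inst$X), t(inst$Y))$cor[1L],
                 tolerance = 1e-8)
})

test_that("canonical correlation is invariant to invertible mixing", {
    set.seed(7)
    inst <- randomInstance(n = 3L, nh = 3L, m = 200L)
    rho <- ccaCoefficient(inst$X, inst$Y)
    for (i in 1:5) {
        A <- matrix(stats::rnorm(9), 3L)
        while (abs(det(A)) < 0.1) A <- matrix(stats::rnorm(9), 3L)
        expect_equal(ccaCoefficient(A %*% inst$X, inst$Y), rho,
                     tolerance = 1e-8)
    }
    expect_equal(ccaCoefficient(inst$X * 1000, inst$Y), rho,
                 tolerance = 1e-8)
})

test_that("delay embedding applies the circular-shift rule", {
    X <- matrix(c(1, 2, 3), 1L)
    expect_equal(delayEmbed(X, 1L), rbind(c(1, 2, 3), c(3, 1, 2)))
    expect_equal(delayEmbed(X, 0L), rbind(c(1, 2, 3), c(1, 2, 3)))
    # shifting by tau then by M - tau returns to the original
    X2 <- matrix(stats::rnorm(10), 2L)
    once <- delayEmbed(X2, 2L)[3:4, ]
    back <- delayEmbed(once, 3L)[3:4, ]
    expect_equal(back, X2)
    expect_error(delayEmbed(X, 3L), "tau")
})

test_that("synchronization index matches the definitional oracle", {
    set.seed(11)
    for (i in 1:25) {
        inst <- randomInstance(n = sample(1:3, 1L), nh = sample(2:4, 1L),
                               m = sample(c(64L, 128L, 256L), 1L))
        expect_equal(msiIndex(inst$X, inst$Y),
                     msiOracle(inst$X, inst$Y), tolerance = 1e-8)
    }
})

test_that("synchronization index hits its theoretical extremes", {
    # zero entropy: a perfectly synchronized scalar pair gives S = 1
    expect_equal(ssvepShift:::msiFromGrams(matrix(1), matrix(1),
                                           matrix(1)), 1)
    # independence: S shrinks toward 0 as the sample count grows
    set.seed(13)
    sAt <- function(m) {
        mean(vapply(1:8, function(i) {
            X <- matrix(stats::rnorm(2L * m), 2L)
            msiIndex(X, makeReference(10, 2L, 256, m))
        }, numeric(1L)))
    }
    s1 <- sAt(1280L)
    s2 <- sAt(12800L)
    expect_lt(s2, s1)
    expect_lt(s2, 0.02)
})

test_that("synchronization index is invariant to channel mixing/scaling", {
    set.seed(19)
    inst <- randomInstance(n = 3L, nh = 2L, m = 256L)
    s <- msiIndex(inst$X, inst$Y)
    A <- matrix(stats::rnorm(9), 3L)
    while (abs(det(A)) < 0.1) A <- matrix(stats::rnorm(9), 3L)
    expect_equal(msiIndex(A %*% inst$X, inst$Y), s, tolerance = 1e-6)
    expect_equal(msiIndex(inst$X * 1000, inst$Y), s, tolerance = 1e-6)
})

test_that("filter-bank weights and single-band reduction are exact", {
    cfg <- classifierConfig("FBCCA")
    w <- ssvepShift:::fbccaWeights(cfg)
    expect_equal(w[1L], 1.25)
    expect_equal(w[2L], 2^(-1.25) + 0.25, tolerance = 1e-12)
    expect_length(w, 5L)
    # one sub-band spanning the analysis band: decisions match plain CCA
    rec <- highSnrRec()
    one <- classifierConfig("FBCCA", fbBands = list(c(4, 52)))
    fb <- classifyRecording(extractWindow(rec, 2), one, channels = 10:12)
    cca <- classifyRecording(
        bandpassRecording(extractWindow(rec, 2), c(4, 52)),
        classifierConfig("CCA"), channels = 10:12)
    expect_equal(fb, cca)
})

test_that("all five classifiers recover a clean tone and break ties low", {
    rec <- pureToneRec(7.5)
    for (alg in c("CCA", "ECCA", "FBCCA", "MSI", "EMSI")) {
        pred <- classifyRecording(rec, classifierConfig(alg))
        expect_equal(pred, trialLabels(rec), info = alg)
    }
    # an all-zero trial must classify deterministically to index 1
    zero <- matrix(0, 2L, 512L)
    for (alg in c("CCA", "MSI"))
        expect_equal(classifyTrial(zero, 60 / c(10, 9, 8, 6), 256,
                                   classifierConfig(alg)), 1L)
})

test_that("scaling one channel changes no decision", {
    rec <- midSnrRec()
    short <- extractWindow(rec, 2)
    scaled <- recData(short)
    scaled[, 11L, ] <- scaled[, 11L, ] * 1000
    recS <- epochedRecording(scaled, samplingRate(short),
                             channelIds(short), trialLabels(short),
                             stimulusFrequencies(short), "scaled")
    for (alg in c("CCA", "MSI")) {
        cc <- classifierConfig(alg)
        expect_equal(
            classifyRecording(recS, cc, channels = c(10L, 11L, 12L)),
            classifyRecording(short, cc, channels = c(10L, 11L, 12L)),
            info = alg)
    }
})

test_that("delay-embedded variants reduce to their base at tau = 0", {
    rec <- extractWindow(midSnrRec(), 2)
    ch <- c(5L, 11L, 17L)
    expect_equal(
        classifyRecording(rec, classifierConfig("ECCA", tau = 0L), ch),
        classifyRecording(rec, classifierConfig("CCA"), ch))
    expect_equal(
        classifyRecording(rec, classifierConfig("EMSI", tau = 0L), ch),
        classifyRecording(rec, classifierConfig("MSI"), ch))
})

test_that("scores stay in bounds on random inputs", {
    set.seed(23)
    for (i in 1:20) {
        inst <- randomInstance(n = sample(1:3, 1L), nh = sample(1:4, 1L),
                               m = sample(c(32L, 64L, 128L), 1L))
        rho <- ccaCoefficient(inst$X, inst$Y)
        s <- msiIndex(inst$X, inst$Y)
        expect_gte(rho, 0); expect_lte(rho, 1)
        expect_gte(s, 0); expect_lte(s, 1)
    }
})
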