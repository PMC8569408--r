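toneRecording <- function(f, fs, seconds = 5, amp = 1) {
    m <- as.integer(seconds * fs)
    data <- array(amp * sin(2 * pi * f * seq_len(m) / fs), c(1L, 1L, m))
    epochedRecording(data, fs, 1L, 1L, 60 / c(10, 9, 8, 6), "tone")
}

spectrumAmp <- function(x, f, fs) {
    m <- length(x)
    2 * Mod(stats::fft(x))[round(f * m / fs) + 1L] / m
}

test_that("decimation keeps sample arithmetic and tone amplitude", {
    rec <- toneRecording(10, 2048)
    expect_equal(nSamples(rec), 10240L)
    dec <- decimateRecording(rec, 256)
    expect_equal(nSamples(dec), 1280L)
    expect_equal(samplingRate(dec), 256)
    expect_identical(trialLabels(dec), trialLabels(rec))
    # 10 Hz amplitude preserved within 1 percent
    a <- spectrumAmp(recData(dec)[1L, 1L, ], 10, 256)
    expect_equal(a, 1, tolerance = 0.01)
    # same rate is the identity
    expect_identical(decimateRecording(dec, 256), dec)
    expect_error(decimateRecording(toneRecording(10, 1000), 256),
                 "integer multiple")
})

test_that("band-pass is zero-phase in the passband", {
    rec <- toneRecording(10, 256)
    filt <- bandpassRecording(rec, c(4, 52), 3L)
    x <- recData(rec)[1L, 1L, ]
    y <- recData(filt)[1L, 1L, ]
    # phase at 10 Hz
    m <- length(x)
    bin <- round(10 * m / 256) + 1L
    dphi <- Arg(stats::fft(y)[bin]) - Arg(stats::fft(x)[bin])
    expect_lt(abs(dphi), 0.01)
    # cross-correlation peaks at zero lag
    cc <- stats::ccf(y, x, lag.max = 10, plot = FALSE)
    expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("band edges attenuate as the Butterworth design predicts", {
    passAmp <- spectrumAmp(
        recData(bandpassRecording(toneRecording(10, 256)))[1L, 1L, ],
        10, 256)
    driftAmp <- spectrumAmp(
        recData(bandpassRecording(toneRecording(1, 256)))[1L, 1L, ],
        1, 256)
    mainsAmp <- spectrumAmp(
        recData(bandpassRecording(toneRecording(60, 256)))[1L, 1L, ],
        60, 256)
    expect_lt(20 * log10(driftAmp / passAmp), -20)
    expect_lt(20 * log10(mainsAmp / passAmp), -6)
    expect_error(bandpassRecording(toneRecording(10, 256), c(4, 200)),
                 "invalid band")
})

test_that("stopband leakage for white noise is small", {
    set.seed(4)
    m <- 2560L
    data <- array(stats::rnorm(m), c(1L, 1L, m))
    rec <- epochedRecording(data, 256, 1L, 1L, 60 / c(10, 9, 8, 6), "wn")
    y <- recData(bandpassRecording(rec))[1L, 1L, ]
    spec <- Mod(stats::fft(y))^2
    freq <- (seq_len(m) - 1L) * 256 / m
    half <- freq <= 128
    stop1 <- sum(spec[half & freq < 2])
    stop2 <- sum(spec[half & freq > 80])
    passb <- sum(spec[half & freq >= 4 & freq <= 52])
    expect_lt((stop1 + stop2) / passb, 0.01)
})

test_that("window extraction slices trials and guards bounds", {
    cfg <- simulationConfig(trialsPerFrequency = 1L, seed = 12L)
    rec <- simulateRecording(cfg)
    w <- extractWindow(rec, 2)
    expect_equal(nSamples(w), 512L)
    expect_equal(recData(w)[1L, 1L, ], recData(rec)[1L, 1L, 1:512])
    off <- extractWindow(rec, 2, 0.5)
    expect_equal(recData(off)[1L, 1L, ], recData(rec)[1L, 1L, 129:640])
    expect_identical(extractWindow(rec, 5), rec)
    expect_error(extractWindow(rec, 5, 0.5), "exceeds")
})

test_that("per-trial filtering has no cross-trial leakage", {
    cfg <- simulationConfig(trialsPerFrequency = 2L, seed = 21L)
    rec <- simulateRecording(cfg)
    whole <- bandpassRecording(rec)
    one <- epochedRecording(recData(rec)[2L, , , drop = FALSE],
                            samplingRate(rec), channelIds(rec),
                            trialLabels(rec)[2L],
                            stimulusFrequencies(rec), "t2")
    alone <- bandpassRecording(one)
    expect_equal(recData(whole)[2L, , ], recData(alone)[1L, , ])
})
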