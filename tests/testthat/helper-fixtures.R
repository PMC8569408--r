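# Shared fixtures, built once per test run.  All recordings are synthetic
# and seeded; the cache avoids re-simulating across test files.

fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
    if (is.null(fixtureCache[[name]]))
        fixtureCache[[name]] <- build()
    fixtureCache[[name]]
}

# small high-SNR recording, preprocessed, for decision-level checks
highSnrRec <- function() {
    fixture("highSnr", function() {
        cfg <- simulationConfig(trialsPerFrequency = 3L, snrDb = 20,
                                seed = 101L)
        bandpassRecording(simulateRecording(cfg))
    })
}

# moderate-SNR recording for ordering / robustness checks
midSnrRec <- function() {
    fixture("midSnr", function() {
        cfg <- simulationConfig(trialsPerFrequency = 5L, seed = 202L)
        bandpassRecording(simulateRecording(cfg))
    })
}

# a noiseless single-trial recording at an exact stimulus frequency
pureToneRec <- function(f = 7.5, fs = 256, nCh = 3L, seconds = 2) {
    m <- seconds * fs
    tIdx <- seq_len(m)
    freqs <- 60 / c(10, 9, 8, 6)
    fi <- match(f, round(freqs, 6))
    wave <- sin(2 * pi * f * tIdx / fs) +
        0.5 * sin(2 * pi * 2 * f * tIdx / fs)
    data <- array(0, c(1L, nCh, m))
    for (ch in seq_len(nCh)) data[1L, ch, ] <- wave * ch
    epochedRecording(data, fs, seq_len(nCh), fi, freqs, "tone")
}
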