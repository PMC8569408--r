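#' Configure the synthetic SSVEP study
#'
#' Bundles and validates the parameters of the synthetic generator. Defaults
#' reproduce the study conditions the analysis assumes: four checkerboard
#' reversal frequencies 60/10, 60/9, 60/8 and 60/6 Hz (6, 6.666..., 7.5 and
#' 10 Hz, stored as exact rationals of the 60 Hz refresh rate), 5 s trials,
#' 25 trials per frequency per subject (20 trials x 5 sessions pooled), a
#' 256 Hz post-preprocessing sampling rate, and an SSVEP whose amplitude
#' falls off as a spatial Gaussian away from a focus electrode so that
#' displaced electrodes see a lower SNR.
#'
#' @param nSubjects number of subjects to simulate.
#' @param trialsPerFrequency trials per stimulus frequency per subject.
#' @param stimulusFrequencies stimulus frequencies in Hz.
#' @param trialLength trial duration in seconds.
#' @param fs sampling rate in Hz; `trialLength * fs` must be an integer.
#'   Use 2048 to exercise the decimation stage.
#' @param nHarmonicsSignal number of harmonics in the simulated SSVEP.
#' @param harmonicDecay exponent gamma >= 0; harmonic k has amplitude
#'   proportional to k^-gamma.
#' @param snrDb signal-to-noise ratio in dB at the focus channel: total
#'   SSVEP power there over total background-noise power. `-Inf` yields
#'   pure noise.
#' @param gainSigma spatial spread (cm) of the SSVEP gain Gaussian.
#' @param focusPosition `(row, col)` of the gain maximum on the grid.
#' @param noiseExponent beta of the 1/f^beta background noise.
#' @param phaseJitter width (radians) of the uniform per-trial phase offset,
#'   shared across harmonics and channels (phase-locked SSVEP).
#' @param commonModeWeight amplitude of a noise component shared uniformly
#'   by all channels, relative to the per-channel noise.
#' @param latencyGradient ms of SSVEP response latency per cm of distance
#'   from the focus electrode (default 10). Scalp SSVEPs show a phase
#'   topography; the resulting inter-channel phase diversity is what lets
#'   multichannel synchronization measures outperform single electrodes.
#'   Set 0 for a perfectly phase-locked (spatially rank-1) response.
#' @param nNoiseSources number of spatially coherent background sources
#'   (random Gaussian-blob topographies, fixed per subject).
#' @param noiseSourceSigma spatial width (cm) of the background-source
#'   topographies.
#' @param structuredNoiseFraction fraction of the background power at the
#'   focus channel carried by the coherent sources plus common mode (the
#'   rest is channel-independent sensor/cortical noise).
#' @param alphaWeight amplitude of an optional spontaneous 10 Hz alpha
#'   oscillation (default 0 = off: alpha would alias into the 10 Hz
#'   stimulus class and confound chance-level checks; enable for stress
#'   tests only).
#' @param seed integer seed; the generator is fully reproducible from it,
#'   with independent substreams per subject.
#' @return A validated list of class `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig(trialsPerFrequency = 2, seed = 1)
#' rec <- simulateRecording(cfg)
#' rec
#' @export
simulationConfig <- function(nSubjects = 1L,
                             trialsPerFrequency = 25L,
                             stimulusFrequencies = 60 / c(10, 9, 8, 6),
                             trialLength = 5,
                             fs = 256,
                             nHarmonicsSignal = 4L,
                             harmonicDecay = 1,
                             snrDb = -20,
                             gainSigma = 4.0,
                             focusPosition = c(2L, 4L),
                             noiseExponent = 1,
                             phaseJitter = 2 * pi,
                             commonModeWeight = 0.3,
                             latencyGradient = 10,
                             nNoiseSources = 4L,
                             noiseSourceSigma = 2.5,
                             structuredNoiseFraction = 0.5,
                             alphaWeight = 0,
                             seed = 1L) {
    cfg <- list(
        nSubjects = as.integer(nSubjects),
        trialsPerFrequency = as.integer(trialsPerFrequency),
        stimulusFrequencies = as.numeric(stimulusFrequencies),
        trialLength = trialLength,
        fs = fs,
        nHarmonicsSignal = as.integer(nHarmonicsSignal),
        harmonicDecay = harmonicDecay,
        snrDb = snrDb,
        gainSigma = gainSigma,
        focusPosition = as.integer(focusPosition),
        noiseExponent = noiseExponent,
        phaseJitter = phaseJitter,
        commonModeWeight = commonModeWeight,
        latencyGradient = latencyGradient,
        nNoiseSources = as.integer(nNoiseSources),
        noiseSourceSigma = noiseSourceSigma,
        structuredNoiseFraction = structuredNoiseFraction,
        alphaWeight = alphaWeight,
        seed = as.integer(seed)
    )
    m <- cfg$trialLength * cfg$fs
    if (abs(m - round(m)) > 1e-9)
        stop("trialLength * fs must be an integer sample count")
    if (cfg$harmonicDecay < 0)
        stop("harmonicDecay must be >= 0")
    if (is.na(cfg$gainSigma) || cfg$gainSigma <= 0)
        stop("gainSigma must be > 0")
    if (cfg$structuredNoiseFraction < 0 || cfg$structuredNoiseFraction >= 1)
        stop("structuredNoiseFraction must lie in [0, 1)")
    if (cfg$latencyGradient < 0)
        stop("latencyGradient must be >= 0")
    if (is.na(cfg$snrDb) || cfg$snrDb == Inf)
        stop("snrDb must be finite or -Inf")
    top <- max(cfg$stimulusFrequencies) * cfg$nHarmonicsSignal
    if (top >= cfg$fs / 2)
        stop("highest harmonic (", top, " Hz) is at or above Nyquist (",
             cfg$fs / 2, " Hz)")
    class(cfg) <- "SimulationConfig"
    cfg
}

# 1/f^beta colored noise, unit variance, length m; beta = 0 is white.
coloredNoise <- function(m, beta) {
    w <- stats::rnorm(m)
    if (beta == 0) return(w)
    f <- c(0, seq_len(m - 1))
    f <- pmin(f, m - f)                 # two-sided frequency index
    shape <- c(0, f[-1]^(-beta / 2))    # kill DC
    z <- stats::fft(w) * shape
    x <- Re(stats::fft(z, inverse = TRUE)) / m
    x / stats::sd(x)
}

# counterbalanced label sequence: each block of nf trials is a random
# permutation of the nf frequencies
counterbalancedLabels <- function(trialsPerFrequency, nf) {
    unlist(lapply(seq_len(trialsPerFrequency),
                  function(b) sample.int(nf)))
}

subjectSeeds <- function(cfg) {
    set.seed(cfg$seed)
    sample.int(.Machine$integer.max - 1L, cfg$nSubjects)
}

#' Simulate one subject's epoched SSVEP recording
#'
#' Generates a 21-channel epoched recording on the standard occipital grid.
#' Channel c of a trial with stimulus frequency f carries
#' \deqn{g_c \sum_{k=1}^{K} k^{-\gamma}
#'   \sin(2\pi k f (t/f_s - \ell_c) + \phi) + \epsilon_c(t),}
#' where \eqn{g_c} is the spatial Gaussian gain ([spatialGain()]) centred
#' on the focus electrode, \eqn{\ell_c} is a response latency growing
#' linearly with distance from the focus (the scalp phase topography of the
#' SSVEP) and \eqn{\phi} is a per-trial uniform phase offset shared by all
#' channels and harmonics. The background \eqn{\epsilon_c} mixes three
#' 1/f^beta components: a small number of spatially coherent sources with
#' smooth random per-subject topographies, a uniform common-mode term, and
#' channel-independent sensor noise; the mixture is scaled so the focus
#' channel attains the configured SNR (signal power over total background
#' power). Labels are counterbalanced: within every consecutive block of
#' four trials each frequency occurs once, in randomized order.
#'
#' @param config a [simulationConfig()].
#' @param subject subject index in 1..nSubjects; each subject uses an
#'   independent seeded substream, so earlier subjects' data do not change
#'   when `nSubjects` grows.
#' @param grid an [ElectrodeGrid-class] (default the standard 3 x 7 grid).
#' @return An [EpochedRecording-class] with `4 * trialsPerFrequency` trials.
#' @export
simulateRecording <- function(config, subject = 1L, grid = electrodeGrid()) {
    stopifnot(inherits(config, "SimulationConfig"))
    if (subject < 1L || subject > config$nSubjects)
        stop("subject must lie in 1..nSubjects")
    seeds <- subjectSeeds(config)
    set.seed(seeds[subject])

    nf <- length(config$stimulusFrequencies)
    nTrials <- config$trialsPerFrequency * nf
    nCh <- grid@nRows * grid@nCols
    m <- as.integer(round(config$trialLength * config$fs))
    gain <- spatialGain(grid, config$focusPosition, config$gainSigma)
    pos <- channelPositionsCm(grid)
    focusXy <- c((config$focusPosition[2L] - 1) * grid@pitch,
                 (config$focusPosition[1L] - 1) * grid@pitch)
    distCm <- sqrt((pos[, "x"] - focusXy[1L])^2 +
                   (pos[, "y"] - focusXy[2L])^2)
    latency <- config$latencyGradient * distCm / 1000   # seconds

    # per-subject background-source topographies: Gaussian blobs at random
    # positions inside the grid's bounding box
    q <- config$nNoiseSources
    topo <- if (q > 0L) {
        vapply(seq_len(q), function(i) {
            cx <- stats::runif(1, 0, max(pos[, "x"]))
            cy <- stats::runif(1, 0, max(pos[, "y"]))
            exp(-((pos[, "x"] - cx)^2 + (pos[, "y"] - cy)^2) /
                (2 * config$noiseSourceSigma^2))
        }, numeric(nCh))
    } else matrix(0, nCh, 0L)

    labels <- counterbalancedLabels(config$trialsPerFrequency, nf)

    k <- seq_len(config$nHarmonicsSignal)
    amp <- k^(-config$harmonicDecay)
    sigPower <- sum(amp^2) / 2          # power of the unit-gain SSVEP
    noisePower <- if (is.infinite(config$snrDb)) 1
                  else sigPower / 10^(config$snrDb / 10)
    wCm <- config$commonModeWeight
    fStruct <- if (q > 0L || wCm > 0) config$structuredNoiseFraction else 0
    structVarFocus <- sum(topo[focusChannel(grid, config), ]^2) + wCm^2
    sdStruct <- if (fStruct > 0 && structVarFocus > 0)
        sqrt(fStruct * noisePower / structVarFocus) else 0
    sdLocal <- sqrt((1 - fStruct) * noisePower)
    signalOn <- !is.infinite(config$snrDb)

    tSec <- seq_len(m) / config$fs
    data <- array(0, dim = c(nTrials, nCh, m))
    for (tr in seq_len(nTrials)) {
        f <- config$stimulusFrequencies[labels[tr]]
        phi <- stats::runif(1, -config$phaseJitter / 2,
                            config$phaseJitter / 2)
        bg <- if (sdStruct > 0) {
            src <- vapply(seq_len(q), function(i)
                coloredNoise(m, config$noiseExponent), numeric(m))
            cm <- coloredNoise(m, config$noiseExponent)
            sdStruct * (src %*% t(topo) + outer(cm, rep(wCm, nCh)))
        } else matrix(0, m, nCh)
        alpha <- if (config$alphaWeight > 0) {
            config$alphaWeight *
                sin(2 * pi * 10 * tSec +
                    stats::runif(1, 0, 2 * pi))
        } else 0
        for (ch in seq_len(nCh)) {
            wave <- if (signalOn && gain[ch] > 0) {
                gain[ch] * colSums(
                    amp * sin(2 * pi * outer(k, f * (tSec - latency[ch])) +
                              phi))
            } else numeric(m)
            data[tr, ch, ] <- wave + bg[, ch] +
                sdLocal * coloredNoise(m, config$noiseExponent) + alpha
        }
    }
    epochedRecording(data, config$fs, seq_len(nCh), labels,
                     config$stimulusFrequencies,
                     sprintf("sim%02d", subject))
}

focusChannel <- function(grid, config) {
    channelOf(grid, config$focusPosition[1L], config$focusPosition[2L])
}

#' Simulate all subjects of a synthetic study
#'
#' @inheritParams simulateRecording
#' @return List of [EpochedRecording-class], one per subject.
#' @export
simulateStudy <- function(config, grid = electrodeGrid()) {
    lapply(seq_len(config$nSubjects), simulateRecording,
           config = config, grid = grid)
}
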