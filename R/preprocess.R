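# Zero-phase IIR filtering with odd-reflection edge padding.  filtfilt in
# the signal package applies no padding, which leaves visible transients on
# short (2 s) windows, so the forward-backward pass is done here around
# signal::filter.
zeroPhaseFilter <- function(b, a, x) {
    m <- length(x)
    p <- min(m - 1L, 3L * (max(length(a), length(b)) - 1L))
    if (p < 1L) stop("signal too short to filter")
    pre <- 2 * x[1L] - x[seq(p + 1L, 2L)]
    post <- 2 * x[m] - x[seq(m - 1L, m - p)]
    y <- c(pre, x, post)
    y <- as.numeric(signal::filter(b, a, y))
    y <- rev(as.numeric(signal::filter(b, a, rev(y))))
    y[(p + 1L):(p + m)]
}

# apply a zero-phase filter to every trial and channel of a 3-D array
filterArray <- function(data, b, a) {
    d <- dim(data)
    out <- array(0, d)
    for (tr in seq_len(d[1L]))
        for (ch in seq_len(d[2L]))
            out[tr, ch, ] <- zeroPhaseFilter(b, a, data[tr, ch, ])
    out
}

butterBand <- function(band, fs, order = 3L) {
    ny <- fs / 2
    if (band[1L] <= 0 || band[2L] <= band[1L] || band[2L] >= ny)
        stop("invalid band edges (", band[1L], ", ", band[2L],
             ") for fs ", fs)
    signal::butter(order, band / ny, type = "pass")
}

#' Decimate a recording to a lower sampling rate
#'
#' Anti-alias low-pass (4th-order zero-phase Butterworth at 80% of the
#' target Nyquist, effectively 8th-order magnitude) followed by keeping
#' every (fs/targetFs)-th sample. Trial count and labels are unchanged.
#'
#' @param rec an [EpochedRecording-class].
#' @param targetFs target sampling rate; `rec` fs must be an integer
#'   multiple. Equal rates return the recording unchanged.
#' @return The decimated [EpochedRecording-class].
#' @export
decimateRecording <- function(rec, targetFs = 256) {
    stopifnot(is(rec, "EpochedRecording"))
    r <- rec@fs / targetFs
    if (abs(r - round(r)) > 1e-9)
        stop("fs (", rec@fs, ") is not an integer multiple of targetFs (",
             targetFs, ")")
    r <- as.integer(round(r))
    if (r == 1L) return(rec)
    bf <- signal::butter(4L, 0.8 * targetFs / rec@fs, type = "low")
    data <- filterArray(rec@data, bf$b, bf$a)
    keep <- seq(1L, dim(data)[3L], by = r)
    epochedRecording(data[, , keep, drop = FALSE], targetFs,
                     rec@channelIds, rec@labels, rec@frequencies,
                     rec@subjectId)
}

#' Band-pass filter a recording
#'
#' Zero-phase (forward-backward) Butterworth band-pass applied per channel
#' per trial. The default mirrors the analysis band: 3rd-order design,
#' 4-52 Hz cutoffs, giving an effective 6th-order magnitude response with
#' no phase distortion.
#'
#' @param rec an [EpochedRecording-class].
#' @param band `c(low, high)` cutoff frequencies in Hz, inside Nyquist.
#' @param order Butterworth design order (applied twice).
#' @return The filtered [EpochedRecording-class]; dimensions unchanged.
#' @export
bandpassRecording <- function(rec, band = c(4, 52), order = 3L) {
    stopifnot(is(rec, "EpochedRecording"))
    bf <- butterBand(band, rec@fs, order)
    epochedRecording(filterArray(rec@data, bf$b, bf$a), rec@fs,
                     rec@channelIds, rec@labels, rec@frequencies,
                     rec@subjectId)
}

#' Extract an analysis window from every trial
#'
#' @param rec an [EpochedRecording-class].
#' @param lengthS window length in seconds.
#' @param offsetS start of the window after trial onset (default 0; no
#'   visual-latency correction is applied).
#' @return An [EpochedRecording-class] with `lengthS * fs` samples per
#'   trial.
#' @export
extractWindow <- function(rec, lengthS, offsetS = 0) {
    stopifnot(is(rec, "EpochedRecording"))
    m <- dim(rec@data)[3L]
    dur <- m / rec@fs
    if (offsetS < 0 || offsetS + lengthS > dur + 1e-9)
        stop("window [", offsetS, ", ", offsetS + lengthS,
             ") s exceeds the ", dur, " s trial")
    i0 <- as.integer(round(offsetS * rec@fs))
    n <- as.integer(round(lengthS * rec@fs))
    if (i0 == 0L && n == m) return(rec)
    epochedRecording(rec@data[, , (i0 + 1L):(i0 + n), drop = FALSE],
                     rec@fs, rec@channelIds, rec@labels, rec@frequencies,
                     rec@subjectId)
}
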