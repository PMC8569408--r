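#' @import methods
NULL

#' Epoched multichannel EEG recording
#'
#' Container for an epoched SSVEP recording: a trials x channels x samples
#' array in microvolts together with the sampling rate, the grid channel
#' numbers of the rows of the channel dimension, per-trial stimulus-frequency
#' labels and the stimulus frequency table.
#'
#' Labels are stored 1-based: `labels[i]` indexes into `frequencies`.
#'
#' @slot data numeric array, trials x channels x samples (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot channelIds integer vector of grid channel numbers (subset of 1..21).
#' @slot labels integer vector, one entry per trial, indexing `frequencies`.
#' @slot frequencies numeric vector of stimulus frequencies in Hz.
#' @slot subjectId character scalar identifying the subject.
#'
#' @seealso [epochedRecording()], [simulateRecording()], [readRecording()]
#' @export
setClass("EpochedRecording",
    representation(
        data = "array",
        fs = "numeric",
        channelIds = "integer",
        labels = "integer",
        frequencies = "numeric",
        subjectId = "character"
    )
)

setValidity("EpochedRecording", function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 3L)
        msg <- c(msg, "data must be a trials x channels x samples array")
    else {
        if (d[2L] != length(object@channelIds))
            msg <- c(msg, sprintf(
                "channel dimension (%d) does not match channelIds length (%d)",
                d[2L], length(object@channelIds)))
        if (d[1L] != length(object@labels))
            msg <- c(msg, sprintf(
                "trial dimension (%d) does not match labels length (%d)",
                d[1L], length(object@labels)))
    }
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
        msg <- c(msg, "fs must be a single positive number")
    if (length(object@labels) &&
        (any(object@labels < 1L) ||
         any(object@labels > length(object@frequencies))))
        msg <- c(msg, "labels must index into frequencies (1-based)")
    if (anyDuplicated(object@channelIds))
        msg <- c(msg, "channelIds must be unique")
    if (length(object@subjectId) != 1L)
        msg <- c(msg, "subjectId must be a single string")
    if (length(msg)) msg else TRUE
})

#' Occipital electrode grid geometry
#'
#' The dense occipital montage: `nRows` x `nCols` electrodes at `pitch` cm
#' spacing, numbered column-major (channel = (col - 1) * nRows + row, rows
#' top-to-bottom, columns left-to-right). For the standard 3 x 7 grid the
#' anchors are channel 5 = O1, 11 = Oz, 17 = O2 on the middle row, and the
#' three overlapping 9-channel shift groups are left = 1..9, middle = 7..15,
#' right = 13..21.
#'
#' @slot nRows,nCols grid dimensions.
#' @slot pitch inter-electrode distance in cm.
#' @slot anchors named integer vector of anchor channels (names "O1", "Oz",
#'   "O2").
#' @slot groups named list of integer vectors: `left`, `middle`, `right`.
#'
#' @seealso [electrodeGrid()], [channelsToPositions()], [spatialGain()]
#' @export
setClass("ElectrodeGrid",
    representation(
        nRows = "integer",
        nCols = "integer",
        pitch = "numeric",
        anchors = "integer",
        groups = "list"
    )
)

setValidity("ElectrodeGrid", function(object) {
    msg <- character()
    n <- object@nRows * object@nCols
    if (object@nRows < 1L || object@nCols < 1L)
        msg <- c(msg, "grid dimensions must be positive")
    if (length(object@pitch) != 1L || object@pitch <= 0)
        msg <- c(msg, "pitch must be a single positive number (cm)")
    allch <- unlist(object@groups, use.names = FALSE)
    if (length(allch) && (any(allch < 1L) || any(allch > n)))
        msg <- c(msg, "group channels must lie within 1..nRows*nCols")
    if (length(object@anchors) &&
        (any(object@anchors < 1L) || any(object@anchors > n)))
        msg <- c(msg, "anchor channels must lie within 1..nRows*nCols")
    if (length(msg)) msg else TRUE
})

#' Electrode-shift robustness result
#'
#' Per (subject, algorithm, number of channels, window length): the vector of
#' classification accuracies over all evaluated channel combinations, plus
#' the two summary measures ACA (mean accuracy across combinations) and
#' RES = 1 - CV (coefficient of variation of the accuracies).
#'
#' @slot subjectId character scalar.
#' @slot algorithm one of "CCA", "ECCA", "FBCCA", "MSI", "EMSI".
#' @slot nChannels integer, number of channels per combination (1, 2 or 3).
#' @slot windowLength analysis window in seconds.
#' @slot combos list of integer vectors, the channel combinations evaluated.
#' @slot accuracies numeric vector, fraction correct per combination.
#' @slot aca mean of `accuracies`.
#' @slot res 1 - sd/mean of `accuracies` (sample sd).
#'
#' @seealso [evaluateRobustness()], [computeAca()], [computeRes()]
#' @export
setClass("RobustnessResult",
    representation(
        subjectId = "character",
        algorithm = "character",
        nChannels = "integer",
        windowLength = "numeric",
        combos = "list",
        accuracies = "numeric",
        aca = "numeric",
        res = "numeric"
    )
)

setValidity("RobustnessResult", function(object) {
    msg <- character()
    if (length(object@accuracies) != length(object@combos))
        msg <- c(msg, "accuracies and combos must have equal length")
    if (length(object@accuracies) &&
        (any(object@accuracies < 0) || any(object@accuracies > 1)))
        msg <- c(msg, "accuracies must lie in [0, 1]")
    if (length(object@aca) == 1L && (object@aca < 0 || object@aca > 1))
        msg <- c(msg, "aca must lie in [0, 1]")
    if (length(object@res) == 1L && is.finite(object@res) && object@res > 1)
        msg <- c(msg, "res cannot exceed 1")
    if (length(msg)) msg else TRUE
})
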