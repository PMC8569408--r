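#' Construct an epoched recording
#'
#' @param data trials x channels x samples numeric array (microvolts).
#' @param fs sampling rate in Hz.
#' @param channelIds grid channel numbers for the channel dimension.
#' @param labels per-trial stimulus-frequency index (1-based into
#'   `frequencies`).
#' @param frequencies stimulus frequencies in Hz.
#' @param subjectId subject identifier.
#' @return A validated [EpochedRecording-class].
#' @export
epochedRecording <- function(data, fs, channelIds, labels, frequencies,
                             subjectId = "S01") {
    rec <- new("EpochedRecording",
        data = data, fs = as.numeric(fs),
        channelIds = as.integer(channelIds),
        labels = as.integer(labels),
        frequencies = as.numeric(frequencies),
        subjectId = as.character(subjectId))
    validObject(rec)
    rec
}

#' Accessors for EpochedRecording
#'
#' `recData` returns the trials x channels x samples array, `samplingRate`
#' the sampling rate in Hz, `channelIds` the grid channel numbers,
#' `trialLabels` the per-trial frequency indices, `stimulusFrequencies` the
#' frequency table, `subjectId` the subject identifier, `nTrials` /
#' `nChannels` / `nSamples` the array dimensions, and `trialMatrix` one
#' trial as a channels x samples matrix (optionally restricted to a channel
#' subset).
#'
#' @param rec an [EpochedRecording-class].
#' @name recording-accessors
NULL

#' @rdname recording-accessors
#' @export
recData <- function(rec) rec@data

#' @rdname recording-accessors
#' @export
samplingRate <- function(rec) rec@fs

#' @rdname recording-accessors
#' @export
channelIds <- function(rec) rec@channelIds

#' @rdname recording-accessors
#' @export
trialLabels <- function(rec) rec@labels

#' @rdname recording-accessors
#' @export
stimulusFrequencies <- function(rec) rec@frequencies

#' @rdname recording-accessors
#' @export
subjectId <- function(rec) rec@subjectId

#' @rdname recording-accessors
#' @export
nTrials <- function(rec) dim(rec@data)[1L]

#' @rdname recording-accessors
#' @export
nChannels <- function(rec) dim(rec@data)[2L]

#' @rdname recording-accessors
#' @export
nSamples <- function(rec) dim(rec@data)[3L]

#' @rdname recording-accessors
#' @param trial trial index.
#' @param channels grid channel numbers to keep (default all, in stored
#'   order).
#' @export
trialMatrix <- function(rec, trial, channels = NULL) {
    X <- rec@data[trial, , , drop = FALSE]
    dim(X) <- dim(rec@data)[2:3]
    if (!is.null(channels)) {
        idx <- match(channels, rec@channelIds)
        if (anyNA(idx))
            stop("channel(s) absent from recording: ",
                 paste(channels[is.na(idx)], collapse = ", "))
        X <- X[idx, , drop = FALSE]
    }
    X
}

setMethod("show", "EpochedRecording", function(object) {
    d <- dim(object@data)
    cat("EpochedRecording '", object@subjectId, "': ",
        d[1L], " trials x ", d[2L], " channels x ", d[3L], " samples @ ",
        object@fs, " Hz\n", sep = "")
    cat("  stimulus frequencies (Hz): ",
        paste(signif(object@frequencies, 4), collapse = ", "), "\n", sep = "")
    cat("  trials per frequency: ",
        paste(tabulate(object@labels, length(object@frequencies)),
              collapse = ", "), "\n", sep = "")
})

setMethod("show", "ElectrodeGrid", function(object) {
    cat("ElectrodeGrid: ", object@nRows, " x ", object@nCols,
        " channels, pitch ", object@pitch, " cm\n", sep = "")
    cat("  anchors: ",
        paste(names(object@anchors), object@anchors,
              sep = "=", collapse = ", "), "\n", sep = "")
})

setMethod("show", "RobustnessResult", function(object) {
    cat("RobustnessResult [", object@subjectId, ", ", object@algorithm,
        ", ", object@nChannels, " ch, ", object@windowLength, " s]\n",
        sep = "")
    cat("  combinations: ", length(object@combos),
        "  ACA: ", round(object@aca, 4),
        "  RES: ", round(object@res, 4), "\n", sep = "")
})

#' Accessors for RobustnessResult
#'
#' @param x a [RobustnessResult-class].
#' @return `aca`/`res` return the scalar summary measure;
#'   `comboAccuracies` the per-combination accuracy vector;
#'   `comboChannels` the list of channel combinations.
#' @name robustness-accessors
NULL

#' @rdname robustness-accessors
#' @export
aca <- function(x) x@aca

#' @rdname robustness-accessors
#' @export
res <- function(x) x@res

#' @rdname robustness-accessors
#' @export
comboAccuracies <- function(x) x@accuracies

#' @rdname robustness-accessors
#' @export
comboChannels <- function(x) x@combos
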