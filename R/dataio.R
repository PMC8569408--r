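#' Write an epoched recording to disk
#'
#' The container is a raw little-endian float64 payload (`<path>.bin`,
#' trials x channels x samples in column-major order) plus a human-readable
#' JSON sidecar (`<path>.json`) holding `dims`, `fs`, `channel_ids`,
#' `labels`, `frequencies` and `subject_id`. Metadata round-trips
#' losslessly; labels are stored 1-based as in the R object.
#'
#' @param rec an [EpochedRecording-class].
#' @param path base path without extension; `.bin` and `.json` are added.
#' @return Invisibly, the two file paths.
#' @seealso [readRecording()]
#' @export
writeRecording <- function(rec, path) {
    stopifnot(is(rec, "EpochedRecording"))
    validObject(rec)
    binPath <- paste0(path, ".bin")
    jsonPath <- paste0(path, ".json")
    if (file.exists(binPath) || file.exists(jsonPath))
        message("overwriting existing recording at ", path)
    meta <- list(
        dims = dim(rec@data),
        fs = rec@fs,
        channel_ids = rec@channelIds,
        labels = rec@labels,
        frequencies = rec@frequencies,
        subject_id = rec@subjectId
    )
    con <- file(binPath, "wb")
    on.exit(close(con))
    writeBin(as.vector(rec@data), con, size = 8L, endian = "little")
    # 17 significant digits: doubles survive the text round-trip exactly
    jsonlite::write_json(meta, jsonPath, digits = I(17), auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(c(bin = binPath, json = jsonPath))
}

#' Read an epoched recording from disk
#'
#' Reads a container written by [writeRecording()] and validates it:
#' missing metadata fields, payload/metadata dimension mismatches and
#' out-of-range labels each raise a distinct error.
#'
#' @param path base path without extension, as passed to [writeRecording()].
#' @return A validated [EpochedRecording-class].
#' @export
readRecording <- function(path) {
    binPath <- paste0(path, ".bin")
    jsonPath <- paste0(path, ".json")
    if (!file.exists(jsonPath))
        stop("missing metadata sidecar: ", jsonPath)
    if (!file.exists(binPath))
        stop("missing array payload: ", binPath)
    meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
    need <- c("dims", "fs", "channel_ids", "labels", "frequencies",
              "subject_id")
    missing <- setdiff(need, names(meta))
    if (length(missing))
        stop("metadata missing field(s): ", paste(missing, collapse = ", "))
    dims <- as.integer(meta$dims)
    if (length(dims) != 3L)
        stop("dims must have length 3 (trials, channels, samples)")
    n <- prod(dims)
    con <- file(binPath, "rb")
    on.exit(close(con))
    x <- readBin(con, "double", n = n + 1L, size = 8L, endian = "little")
    if (length(x) != n)
        stop("payload size (", length(x),
             " doubles) does not match dims (expected ", n, ")")
    # empty JSON arrays come back untyped; restore typed zero-length vectors
    asInt <- function(v) if (length(v) == 0L) integer() else as.integer(v)
    labels <- asInt(meta$labels)
    chan <- asInt(meta$channel_ids)
    if (length(chan) != dims[2L])
        stop("channel_ids length (", length(chan),
             ") does not match channel dimension (", dims[2L], ")")
    if (length(labels) != dims[1L])
        stop("labels length (", length(labels),
             ") does not match trial dimension (", dims[1L], ")")
    if (length(labels) && (any(labels < 1L) ||
                           any(labels > length(meta$frequencies))))
        stop("label value(s) outside 1..", length(meta$frequencies))
    epochedRecording(array(x, dim = dims), meta$fs, chan, labels,
                     meta$frequencies, meta$subject_id)
}
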