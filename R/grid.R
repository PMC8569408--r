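#' Construct the standard occipital electrode grid
#'
#' Builds the 3-row x 7-column occipital grid with 1.3 cm pitch used for
#' electrode-shift analysis. Channels are numbered column-major, so channel
#' \eqn{= (col - 1) \times 3 + row}; this is the unique 3 x 7 numbering for
#' which the left/middle/right 9-channel groups are columns 1-3, 3-5 and 5-7
#' (channels 1-9, 7-15, 13-21, overlapping in \{7, 8, 9\} and \{13, 14, 15\})
#' and the anchors O1/Oz/O2 sit at channels 5/11/17 on the middle row.
#'
#' @param nRows,nCols grid dimensions (defaults 3 and 7).
#' @param pitch inter-electrode distance in cm (default 1.3).
#' @return An [ElectrodeGrid-class] object.
#' @examples
#' grid <- electrodeGrid()
#' channelsToPositions(grid, c(5, 11, 17))
#' @export
electrodeGrid <- function(nRows = 3L, nCols = 7L, pitch = 1.3) {
    nRows <- as.integer(nRows)
    nCols <- as.integer(nCols)
    groupCols <- function(cols) {
        sort(as.integer(outer(seq_len(nRows), (cols - 1L) * nRows, "+")))
    }
    grid <- new("ElectrodeGrid",
        nRows = nRows, nCols = nCols, pitch = pitch,
        anchors = c(O1 = 5L, Oz = 11L, O2 = 17L),
        groups = list(
            left = groupCols(1:3),
            middle = groupCols(3:5),
            right = groupCols(5:7)
        )
    )
    validObject(grid)
    grid
}

#' Channel number of a grid cell
#'
#' @param grid an [ElectrodeGrid-class].
#' @param row,col grid coordinates, rows 1..3 top-to-bottom, columns 1..7
#'   left-to-right.
#' @return Integer channel number(s).
#' @export
channelOf <- function(grid, row, col) {
    stopifnot(is(grid, "ElectrodeGrid"))
    if (any(row < 1L | row > grid@nRows | col < 1L | col > grid@nCols))
        stop("grid cell (", row, ", ", col, ") outside the ",
             grid@nRows, " x ", grid@nCols, " grid")
    as.integer((col - 1L) * grid@nRows + row)
}

#' Grid cell of a channel number
#'
#' @inheritParams channelOf
#' @param channel integer channel number(s) in 1..nRows*nCols.
#' @return For a single channel, a named integer vector `c(row, col)`.
#' @export
positionOf <- function(grid, channel) {
    stopifnot(is(grid, "ElectrodeGrid"), length(channel) == 1L)
    checkChannels(grid, channel)
    c(row = as.integer((channel - 1L) %% grid@nRows + 1L),
      col = as.integer((channel - 1L) %/% grid@nRows + 1L))
}

#' Map channel numbers to grid (row, col) positions
#'
#' @inheritParams positionOf
#' @param ids integer vector of channel numbers.
#' @return Integer matrix with columns `row` and `col`, one row per id.
#' @examples
#' grid <- electrodeGrid()
#' channelsToPositions(grid, c(1, 5, 11, 17))
#' @export
channelsToPositions <- function(grid, ids) {
    stopifnot(is(grid, "ElectrodeGrid"))
    checkChannels(grid, ids)
    cbind(row = as.integer((ids - 1L) %% grid@nRows + 1L),
          col = as.integer((ids - 1L) %/% grid@nRows + 1L))
}

checkChannels <- function(grid, ids) {
    n <- grid@nRows * grid@nCols
    bad <- ids < 1L | ids > n | ids != floor(ids)
    if (any(bad))
        stop("channel id(s) outside 1..", n, ": ",
             paste(ids[bad], collapse = ", "))
    invisible(TRUE)
}

#' Physical positions of channels in cm
#'
#' x increases with column, y with row; units are `pitch` cm per grid step.
#' @inheritParams channelsToPositions
#' @return Numeric matrix with columns `x` and `y` (cm).
#' @export
channelPositionsCm <- function(grid, ids = seq_len(grid@nRows * grid@nCols)) {
    rc <- channelsToPositions(grid, ids)
    cbind(x = (rc[, "col"] - 1) * grid@pitch,
          y = (rc[, "row"] - 1) * grid@pitch)
}

#' Accessors for grid metadata
#'
#' `anchorChannels` returns the named anchor channels (O1/Oz/O2);
#' `channelGroups` the left/middle/right shift groups.
#' @inheritParams channelOf
#' @return A named integer vector, or a named list of integer vectors.
#' @export
anchorChannels <- function(grid) grid@anchors

#' @rdname anchorChannels
#' @export
channelGroups <- function(grid) grid@groups

#' Spatially smooth SSVEP gain field
#'
#' Models the attenuation a displaced electrode sees: an isotropic Gaussian
#' of the physical distance (in cm, at the grid pitch) from a focus cell,
#' with gain exactly 1 at the focus. Used by the synthetic generator so that
#' electrodes shifted away from the response focus record a lower-SNR SSVEP.
#'
#' @inheritParams channelOf
#' @param focus length-2 vector `(row, col)` of the gain maximum.
#' @param sigma spatial spread in cm; must be > 0 (`Inf` gives flat gain 1).
#' @return Numeric vector of gains in \[0, 1\], one per channel 1..21.
#' @examples
#' g <- spatialGain(electrodeGrid(), focus = c(2, 4), sigma = 1.3)
#' g[11]            # 1 at the focus (Oz)
#' g[14]            # one 1.3 cm step away: exp(-0.5)
#' @export
spatialGain <- function(grid, focus, sigma) {
    stopifnot(is(grid, "ElectrodeGrid"), length(focus) == 2L)
    if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
        stop("sigma must be a single positive number (cm)")
    if (focus[1L] < 1 || focus[1L] > grid@nRows ||
        focus[2L] < 1 || focus[2L] > grid@nCols)
        stop("focus (", focus[1L], ", ", focus[2L], ") outside the grid")
    pos <- channelPositionsCm(grid)
    fx <- (focus[2L] - 1) * grid@pitch
    fy <- (focus[1L] - 1) * grid@pitch
    d2 <- (pos[, "x"] - fx)^2 + (pos[, "y"] - fy)^2
    if (is.infinite(sigma)) rep(1, nrow(pos)) else exp(-d2 / (2 * sigma^2))
}
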