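#' Enumerate electrode-shift channel combinations
#'
#' All channel combinations modelling independent shifts of the O1/Oz/O2
#' electrodes within their 9-channel groups:
#' \itemize{
#'   \item 1 channel: the 9 middle-group channels (7..15);
#'   \item 2 channels: left group x right group, 81 combinations;
#'   \item 3 channels: left x middle x right, minus every tuple containing
#'     a repeated channel (possible because left/middle share \{7, 8, 9\}
#'     and middle/right share \{13, 14, 15\}): 729 - 27 - 27 = 675.
#' }
#' Tuples are ordered (left, middle, right) in deterministic lexicographic
#' order.
#'
#' @param grid an [ElectrodeGrid-class].
#' @param nChannels 1, 2 or 3.
#' @return List of integer vectors.
#' @examples
#' length(enumerateCombinations(electrodeGrid(), 3))  # 675
#' @export
enumerateCombinations <- function(grid, nChannels) {
    stopifnot(is(grid, "ElectrodeGrid"))
    g <- grid@groups
    if (nChannels == 1L) {
        lapply(g$middle, function(ch) ch)
    } else if (nChannels == 2L) {
        out <- vector("list", length(g$left) * length(g$right))
        i <- 0L
        for (l in g$left) for (r in g$right) {
            i <- i + 1L
            out[[i]] <- c(l, r)
        }
        out
    } else if (nChannels == 3L) {
        out <- vector("list", 0L)
        for (l in g$left) for (mch in g$middle) for (r in g$right) {
            tup <- c(l, mch, r)
            if (!anyDuplicated(tup)) out[[length(out) + 1L]] <- tup
        }
        out
    } else {
        stop("nChannels must be 1, 2 or 3")
    }
}

# Precompute, for one trial, every Gram matrix the configured algorithm
# needs over the full channel set; scoring a combination then reduces to
# subsetting rows/columns and a small eigendecomposition.
trialGrams <- function(X, frequencies, fs, config) {
    m <- ncol(X)
    Xc <- centerRows(X)
    refs <- lapply(frequencies, function(f)
        centerRows(makeReference(f, config$nHarmonics, fs, m)))
    Syy <- lapply(refs, function(Y) tcrossprod(Y) / m)
    Wy <- lapply(Syy, symInvSqrt, eigFloor = config$eigFloor)
    out <- list(refs = refs, Syy = Syy, Wy = Wy, m = m)
    alg <- config$algorithm
    if (alg %in% c("CCA", "MSI")) {
        out$Sxx <- tcrossprod(Xc) / m
        out$Sxy <- lapply(refs, function(Y) tcrossprod(Xc, Y) / m)
    } else if (alg %in% c("ECCA", "EMSI")) {
        Xe <- delayEmbed(Xc, config$tau)
        out$Sxx <- tcrossprod(Xe) / m
        out$Sxy <- lapply(refs, function(Y) tcrossprod(Xe, Y) / m)
    } else if (alg == "FBCCA") {
        out$sub <- lapply(config$fbBands, function(band) {
            bf <- butterBand(band, fs, 3L)
            Xn <- t(apply(X, 1L, function(x)
                zeroPhaseFilter(bf$b, bf$a, x)))
            if (nrow(X) == 1L) Xn <- matrix(Xn, nrow = 1L)
            Xn <- centerRows(Xn)
            list(Sxx = tcrossprod(Xn) / m,
                 Sxy = lapply(refs, function(Y) tcrossprod(Xn, Y) / m))
        })
    }
    out
}

# classify one combination from precomputed grams; idx indexes the rows of
# the full channel set
comboPredict <- function(gr, idx, nChannelsTotal, config) {
    alg <- config$algorithm
    ef <- config$eigFloor
    if (alg %in% c("ECCA", "EMSI"))
        idx <- c(idx, idx + nChannelsTotal)
    nf <- length(gr$Syy)
    scores <- numeric(nf)
    for (fi in seq_len(nf)) {
        scores[fi] <- if (alg %in% c("CCA", "ECCA")) {
            ccaFromGrams(gr$Sxx[idx, idx, drop = FALSE],
                         gr$Sxy[[fi]][idx, , drop = FALSE],
                         eigFloor = ef, Wy = gr$Wy[[fi]])
        } else if (alg %in% c("MSI", "EMSI")) {
            msiFromGrams(gr$Sxx[idx, idx, drop = FALSE],
                         gr$Sxy[[fi]][idx, , drop = FALSE],
                         eigFloor = ef, U22 = gr$Wy[[fi]])
        } else {
            w <- fbccaWeights(config)
            s <- 0
            for (n in seq_along(gr$sub)) {
                rho <- ccaFromGrams(
                    gr$sub[[n]]$Sxx[idx, idx, drop = FALSE],
                    gr$sub[[n]]$Sxy[[fi]][idx, , drop = FALSE],
                    eigFloor = ef, Wy = gr$Wy[[fi]])
                s <- s + w[n] * rho^2
            }
            s
        }
    }
    which.max(scores)
}

#' Classification accuracy for each channel combination
#'
#' Classifies every trial of the recording once per channel combination,
#' using only that combination's channels, and returns the fraction of
#' correct trials per combination. Cross-covariances with the harmonic
#' references are computed once per trial over the full channel set and
#' subset per combination, so the cost grows mildly with the number of
#' combinations.
#'
#' @param rec a preprocessed [EpochedRecording-class] containing every
#'   channel that any combination uses.
#' @param combos list of integer channel tuples
#'   (see [enumerateCombinations()]).
#' @param config a [classifierConfig()].
#' @param windowLength optional analysis window in seconds
#'   (see [extractWindow()]); default uses the full trial.
#' @return Numeric vector of accuracies in \[0, 1\], one per combination.
#' @export
accuracyPerCombination <- function(rec, combos,
                                   config = classifierConfig(),
                                   windowLength = NULL) {
    stopifnot(is(rec, "EpochedRecording"), length(combos) >= 1L)
    if (!is.null(windowLength)) rec <- extractWindow(rec, windowLength)
    idxList <- lapply(combos, function(ch) {
        idx <- match(ch, rec@channelIds)
        if (anyNA(idx))
            stop("combination channel(s) absent from recording: ",
                 paste(ch[is.na(idx)], collapse = ", "))
        idx
    })
    nTot <- nChannels(rec)
    correct <- numeric(length(combos))
    for (tr in seq_len(nTrials(rec))) {
        gr <- trialGrams(trialMatrix(rec, tr), rec@frequencies, rec@fs,
                         config)
        truth <- rec@labels[tr]
        for (ci in seq_along(idxList)) {
            if (comboPredict(gr, idxList[[ci]], nTot, config) == truth)
                correct[ci] <- correct[ci] + 1
        }
    }
    correct / nTrials(rec)
}

#' Average classification accuracy across electrode shifts (ACA)
#'
#' @param accuracies numeric vector of per-combination accuracies.
#' @return Their arithmetic mean.
#' @export
computeAca <- function(accuracies) {
    if (length(accuracies) == 0L) stop("empty accuracy vector")
    mean(accuracies)
}

#' Robustness to electrode shift (RES = 1 - CV)
#'
#' One minus the coefficient of variation of the per-combination
#' accuracies; 1 means the classifier is unaffected by electrode shift.
#'
#' @param accuracies numeric vector of per-combination accuracies with
#'   positive mean.
#' @param sd type of standard deviation: `"sample"` (n - 1 denominator,
#'   default) or `"population"`.
#' @return 1 - sd/mean.
#' @export
computeRes <- function(accuracies, sd = c("sample", "population")) {
    sd <- match.arg(sd)
    if (length(accuracies) == 0L) stop("empty accuracy vector")
    mu <- mean(accuracies)
    if (mu <= 0) stop("CV undefined: mean accuracy is zero")
    s <- stats::sd(accuracies)
    if (sd == "population")
        s <- s * sqrt((length(accuracies) - 1) / length(accuracies))
    if (is.na(s)) s <- 0      # single combination
    1 - s / mu
}

#' Evaluate electrode-shift robustness for one subject and condition
#'
#' Enumerates the shift combinations for `nChannels`, computes the
#' per-combination accuracies at the given window length, and summarizes
#' them as ACA and RES.
#'
#' @inheritParams accuracyPerCombination
#' @param grid an [ElectrodeGrid-class].
#' @param nChannels 1, 2 or 3.
#' @param windowLength analysis window in seconds.
#' @param maxCombos optional down-sampling for smoke runs: keep this many
#'   combinations at deterministic, evenly spaced positions of the
#'   lexicographic enumeration (default: all).
#' @return A [RobustnessResult-class].
#' @export
evaluateRobustness <- function(rec, grid = electrodeGrid(),
                               config = classifierConfig(),
                               nChannels = 3L, windowLength = NULL,
                               maxCombos = NULL) {
    combos <- enumerateCombinations(grid, nChannels)
    if (!is.null(maxCombos) && maxCombos < length(combos))
        combos <- combos[unique(round(seq(1L, length(combos),
                                          length.out = maxCombos)))]
    acc <- accuracyPerCombination(rec, combos, config, windowLength)
    wl <- if (is.null(windowLength)) nSamples(rec) / rec@fs
          else windowLength
    new("RobustnessResult",
        subjectId = rec@subjectId,
        algorithm = config$algorithm,
        nChannels = as.integer(nChannels),
        windowLength = wl,
        combos = combos,
        accuracies = acc,
        aca = computeAca(acc),
        res = computeRes(acc))
}

#' Same-direction electrode-shift accuracy map
#'
#' Models a rigid displacement of the whole three-electrode montage: for
#' every shift (dr, dc) in \{-1, 0, 1\}^2 the O1/Oz/O2 anchors move
#' together by one grid step, the per-subject accuracy of the shifted
#' triple is computed, averaged across subjects, and the nine means are
#' min-max normalized to \[0, 1\]. If all nine means are equal the map is
#' all zeros (with a warning).
#'
#' @param recs list of preprocessed [EpochedRecording-class], one per
#'   subject.
#' @param grid an [ElectrodeGrid-class].
#' @param config a [classifierConfig()].
#' @param windowLength optional analysis window in seconds.
#' @return A 3 x 3 matrix; rows are the row shift (-1, 0, 1), columns the
#'   column shift (-1, 0, 1). The (0, 0) cell is the unshifted montage
#'   (channels 5, 11, 17).
#' @export
shiftDirectionMap <- function(recs, grid = electrodeGrid(),
                              config = classifierConfig("EMSI"),
                              windowLength = NULL) {
    if (is(recs, "EpochedRecording")) recs <- list(recs)
    anchors <- channelsToPositions(grid, anchorChannels(grid))
    shifts <- expand.grid(dr = -1:1, dc = -1:1)
    combos <- lapply(seq_len(nrow(shifts)), function(i) {
        vapply(seq_len(nrow(anchors)), function(a)
            channelOf(grid, anchors[a, "row"] + shifts$dr[i],
                      anchors[a, "col"] + shifts$dc[i]), integer(1L))
    })
    accs <- vapply(recs, accuracyPerCombination, numeric(length(combos)),
                   combos = combos, config = config,
                   windowLength = windowLength)
    if (is.null(dim(accs))) accs <- matrix(accs, nrow = length(combos))
    meanAcc <- rowMeans(accs)
    rng <- range(meanAcc)
    norm <- if (rng[2L] > rng[1L]) {
        (meanAcc - rng[1L]) / (rng[2L] - rng[1L])
    } else {
        warning("all nine shift accuracies equal; map set to zeros")
        rep(0, length(meanAcc))
    }
    matrix(norm, 3L, 3L, dimnames = list(dr = -1:1, dc = -1:1))
}
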