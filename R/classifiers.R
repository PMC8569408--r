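#' Configure a training-free SSVEP classifier
#'
#' @param algorithm one of `"CCA"`, `"ECCA"`, `"FBCCA"`, `"MSI"`, `"EMSI"`.
#' @param nHarmonics number of reference harmonics Nh (default 4; with a
#'   10 Hz fundamental all four harmonics stay inside the 4-52 Hz analysis
#'   band).
#' @param tau delay in samples for the delay-embedded variants ECCA/EMSI
#'   (default 1). `tau = 0` makes them coincide with CCA/MSI decisions.
#' @param fbA,fbB filter-bank weight constants: sub-band n gets weight
#'   `n^-fbA + fbB` (defaults 1.25 and 0.25).
#' @param fbBands list of `c(low, high)` sub-band edges in Hz; the number
#'   of sub-bands is its length (default the five bands 4-52, 8-52, 12-52,
#'   16-52, 20-52 Hz).
#' @param eigFloor relative eigenvalue floor used when inverting
#'   covariance blocks (regularizes rank-deficient windows).
#' @return A validated list of class `ClassifierConfig`.
#' @export
classifierConfig <- function(algorithm = c("CCA", "ECCA", "FBCCA", "MSI",
                                           "EMSI"),
                             nHarmonics = 4L,
                             tau = 1L,
                             fbA = 1.25, fbB = 0.25,
                             fbBands = list(c(4, 52), c(8, 52), c(12, 52),
                                            c(16, 52), c(20, 52)),
                             eigFloor = 1e-12) {
    algorithm <- match.arg(algorithm)
    stopifnot(nHarmonics >= 1L, tau >= 0L, eigFloor > 0,
              is.finite(fbA), is.finite(fbB))
    structure(list(algorithm = algorithm,
                   nHarmonics = as.integer(nHarmonics),
                   tau = as.integer(tau),
                   fbA = fbA, fbB = fbB, fbBands = fbBands,
                   eigFloor = eigFloor),
              class = "ClassifierConfig")
}

refCache <- new.env(parent = emptyenv())

#' Harmonic sine/cosine reference matrix
#'
#' Builds the 2 Nh x M reference for stimulus frequency `f`: rows
#' \eqn{\sin(2\pi k f t / F_s)} and \eqn{\cos(2\pi k f t / F_s)} for
#' harmonics k = 1..Nh and t = 1..M. Matrices are cached per
#' (f, Nh, Fs, M).
#'
#' @param f stimulus frequency in Hz.
#' @param nh number of harmonics.
#' @param fs sampling rate in Hz; `nh * f` must be below `fs / 2`.
#' @param m number of samples.
#' @return A `2 * nh` x `m` numeric matrix.
#' @export
makeReference <- function(f, nh, fs, m) {
    if (nh * f >= fs / 2)
        stop("harmonic ", nh, " of ", f, " Hz is at or above Nyquist")
    if (m < 2L * nh)
        stop("window too short: ", m, " samples for ", 2L * nh,
             " reference rows")
    key <- paste(f, nh, fs, m, sep = "|")
    if (!is.null(refCache[[key]])) return(refCache[[key]])
    tIdx <- seq_len(m)
    Y <- matrix(0, 2L * nh, m)
    for (k in seq_len(nh)) {
        ph <- 2 * pi * k * f * tIdx / fs
        Y[2L * k - 1L, ] <- sin(ph)
        Y[2L * k, ] <- cos(ph)
    }
    refCache[[key]] <- Y
    Y
}

centerRows <- function(X) X - rowMeans(X)

# symmetric inverse square root with relative eigenvalue floor
symInvSqrt <- function(C, eigFloor) {
    e <- eigen((C + t(C)) / 2, symmetric = TRUE)
    v <- pmax(e$values, eigFloor * max(e$values, eigFloor))
    e$vectors %*% (t(e$vectors) / sqrt(v))
}

#' Maximal canonical correlation between a signal and a reference
#'
#' Computes the largest canonical correlation between the row spaces of
#' `X` (channels x M EEG) and `Y` (2 Nh x M reference), i.e. the maximum
#' over weight vectors of \eqn{corr(w_X' X, w_Y' Y)}. Rows are mean-centered
#' first. Implemented as the largest singular value of the whitened
#' cross-covariance \eqn{C_{XX}^{-1/2} C_{XY} C_{YY}^{-1/2}}, with a
#' relative eigenvalue floor guarding rank-deficient covariances.
#'
#' @param X channels x M numeric matrix.
#' @param Y reference matrix sharing M (see [makeReference()]).
#' @param eigFloor relative floor for covariance eigenvalues.
#' @return The canonical correlation, clamped to \[0, 1\].
#' @export
ccaCoefficient <- function(X, Y, eigFloor = 1e-12) {
    if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
    m <- ncol(X)
    if (ncol(Y) != m) stop("X and Y must share the sample dimension")
    if (m < nrow(X) + nrow(Y))
        stop("window too short (", m, " samples) for rank ",
             nrow(X) + nrow(Y))
    X <- centerRows(X); Y <- centerRows(Y)
    ccaFromGrams(tcrossprod(X) / m, tcrossprod(X, Y) / m,
                 tcrossprod(Y) / m, eigFloor)
}

ccaFromGrams <- function(Sxx, Sxy, Syy = NULL, eigFloor = 1e-12,
                         Wy = NULL) {
    if (is.null(Wy)) Wy <- symInvSqrt(Syy, eigFloor)
    K <- symInvSqrt(Sxx, eigFloor) %*% Sxy %*% Wy
    rho <- svd(K, nu = 0L, nv = 0L)$d[1L]
    min(max(rho, 0), 1)
}

#' Delay-embed a multichannel signal
#'
#' Stacks `X` on top of a circularly delayed copy: the final `tau` samples
#' move to the front while all other samples shift right. ECCA and EMSI
#' score `delayEmbed(X, tau)` against the unmodified reference.
#'
#' @param X channels x M numeric matrix.
#' @param tau delay in samples, `0 <= tau < M` (`tau = 0` duplicates `X`).
#' @return A `2 * channels` x M matrix.
#' @export
delayEmbed <- function(X, tau) {
    if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
    m <- ncol(X)
    if (tau < 0L || tau >= m) stop("tau must satisfy 0 <= tau < ", m)
    idx <- if (tau == 0L) seq_len(m)
           else c((m - tau + 1L):m, seq_len(m - tau))
    rbind(X, X[, idx, drop = FALSE])
}

#' Multivariate synchronization index (S-estimator)
#'
#' Measures synchronization between EEG `X` (N x M) and reference `Y`
#' (2 Nh x M) from the eigenvalue spectrum of the whitened joint
#' correlation matrix: with \eqn{C_{11} = XX'/M}, \eqn{C_{22} = YY'/M},
#' \eqn{C_{12} = XY'/M} (and \eqn{C_{21} = C_{12}'}), the blocks are
#' whitened by \eqn{C_{11}^{-1/2}} and \eqn{C_{22}^{-1/2}}, the P = N + 2Nh
#' eigenvalues of the result are normalized to sum to one, and
#' \deqn{S = 1 + \sum_i \lambda_i' \log \lambda_i' / \log P.}
#' S is 0 for independent signals (maximal eigenvalue entropy) and 1 for
#' complete synchronization. Rows are mean-centered; natural logs are used
#' (any common base gives the same S); `0 log 0` is taken as 0.
#'
#' @inheritParams ccaCoefficient
#' @return The synchronization index, clamped to \[0, 1\].
#' @export
msiIndex <- function(X, Y, eigFloor = 1e-12) {
    if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
    m <- ncol(X)
    if (ncol(Y) != m) stop("X and Y must share the sample dimension")
    if (!all(is.finite(X)) || !all(is.finite(Y)))
        stop("non-finite values in input")
    X <- centerRows(X); Y <- centerRows(Y)
    msiFromGrams(tcrossprod(X) / m, tcrossprod(X, Y) / m,
                 tcrossprod(Y) / m, eigFloor)
}

msiFromGrams <- function(C11, C12, C22 = NULL, eigFloor = 1e-12,
                         U22 = NULL) {
    if (is.null(U22)) U22 <- symInvSqrt(C22, eigFloor)
    U11 <- symInvSqrt(C11, eigFloor)
    B <- U11 %*% C12 %*% U22          # whitened off-diagonal block
    p <- nrow(C11) + nrow(U22)
    R <- rbind(cbind(diag(nrow(B)), B),
               cbind(t(B), diag(ncol(B))))
    lam <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
    lam <- pmax(lam, 0)
    lam <- lam / sum(lam)
    ent <- sum(ifelse(lam > 0, lam * log(lam), 0))
    min(max(1 + ent / log(p), 0), 1)
}

fbccaWeights <- function(config) {
    n <- seq_along(config$fbBands)
    n^(-config$fbA) + config$fbB
}

#' Filter-bank CCA score for one candidate frequency
#'
#' Decomposes the EEG into sub-band components (zero-phase 3rd-order
#' Butterworth band-passes at the configured edges), scores each sub-band
#' against the harmonic reference with [ccaCoefficient()], and combines
#' them as \eqn{\rho_f = \sum_n w(n) (\rho_f^n)^2} with
#' \eqn{w(n) = n^{-a} + b}. Sub-band edges are applied literally, so a
#' fundamental below a sub-band's low edge contributes only through its
#' harmonics there.
#'
#' @param X channels x M numeric matrix (analysis-band EEG).
#' @param f candidate stimulus frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param config a [classifierConfig()].
#' @return The weighted sum of squared sub-band canonical correlations.
#' @export
fbccaScore <- function(X, f, fs, config = classifierConfig("FBCCA")) {
    if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
    Y <- makeReference(f, config$nHarmonics, fs, ncol(X))
    w <- fbccaWeights(config)
    s <- 0
    for (n in seq_along(config$fbBands)) {
        bf <- butterBand(config$fbBands[[n]], fs, 3L)
        Xn <- t(apply(X, 1L, function(x) zeroPhaseFilter(bf$b, bf$a, x)))
        if (nrow(X) == 1L) Xn <- matrix(Xn, nrow = 1L)
        s <- s + w[n] * ccaCoefficient(Xn, Y, config$eigFloor)^2
    }
    s
}

scoreFrequency <- function(X, f, fs, config) {
    nh <- config$nHarmonics
    switch(config$algorithm,
        CCA = ccaCoefficient(X, makeReference(f, nh, fs, ncol(X)),
                             config$eigFloor),
        ECCA = {
            Xe <- delayEmbed(X, config$tau)
            ccaCoefficient(Xe, makeReference(f, nh, fs, ncol(X)),
                           config$eigFloor)
        },
        MSI = msiIndex(X, makeReference(f, nh, fs, ncol(X)),
                       config$eigFloor),
        EMSI = {
            Xe <- delayEmbed(X, config$tau)
            msiIndex(Xe, makeReference(f, nh, fs, ncol(X)),
                     config$eigFloor)
        },
        FBCCA = fbccaScore(X, f, fs, config))
}

#' Classify one trial's stimulus frequency
#'
#' Scores every candidate frequency with the configured algorithm and
#' returns the argmax index; exact ties go to the lowest frequency index
#' (deterministic contract for degenerate input).
#'
#' @param X channels x M numeric matrix, preprocessed to the analysis band
#'   and window.
#' @param frequencies candidate stimulus frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @param config a [classifierConfig()].
#' @return Integer index into `frequencies`.
#' @export
classifyTrial <- function(X, frequencies, fs, config = classifierConfig()) {
    scores <- vapply(frequencies, function(f)
        scoreFrequency(X, f, fs, config), numeric(1L))
    which.max(scores)       # first maximum = lowest frequency index on ties
}

#' Classify every trial of a recording
#'
#' @param rec an [EpochedRecording-class], preprocessed.
#' @param config a [classifierConfig()].
#' @param channels grid channel numbers to use (default: all channels in
#'   the recording).
#' @return Integer vector of predicted frequency indices, one per trial.
#' @export
classifyRecording <- function(rec, config = classifierConfig(),
                              channels = NULL) {
    vapply(seq_len(nTrials(rec)), function(tr) {
        classifyTrial(trialMatrix(rec, tr, channels),
                      rec@frequencies, rec@fs, config)
    }, integer(1L))
}

#' Classification accuracy of a recording
#'
#' @inheritParams classifyRecording
#' @return Fraction of trials whose predicted frequency matches the label.
#' @export
classificationAccuracy <- function(rec, config = classifierConfig(),
                                   channels = NULL) {
    mean(classifyRecording(rec, config, channels) == rec@labels)
}
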