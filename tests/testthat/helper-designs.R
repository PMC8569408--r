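# independent enumeration by brute force over the full product grid
bruteCombos <- function(n) {
    left <- 1:9; middle <- 7:15; right <- 13:21
    if (n == 1L) return(lapply(middle, identity))
    if (n == 2L) {
        g <- expand.grid(r = right, l = left)
        return(lapply(seq_len(nrow(g)), function(i) c(g$l[i], g$r[i])))
    }
    g <- expand.grid(r = right, m = middle, l = left)
    out <- lapply(seq_len(nrow(g)), function(i) c(g$l[i], g$m[i], g$r[i]))
    Filter(function(tup) !anyDuplicated(tup), out)
}

# balanced long-format measure table with optional injected effects
syntheticTable <- function(nSubjects = 21L, seed = 1L,
                           channelEffect = 0, algEffect = 0) {
    set.seed(seed)
    algs <- c("CCA", "ECCA", "FBCCA", "MSI", "EMSI")
    g <- expand.grid(subject = sprintf("S%02d", seq_len(nSubjects)),
                     algorithm = algs, nChannels = 1:3,
                     stringsAsFactors = FALSE)
    g$windowLength <- 2
    subjMean <- stats::rnorm(nSubjects, 0.6, 0.05)
    g$ACA <- subjMean[match(g$subject,
                            sprintf("S%02d", seq_len(nSubjects)))] +
        channelEffect * (g$nChannels - 2L) +
        algEffect * (g$algorithm == "EMSI") +
        stats::rnorm(nrow(g), 0, 0.03)
    g$RES <- g$ACA
    g
}
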