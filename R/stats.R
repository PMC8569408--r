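#' Assemble a long-format measure table
#'
#' Binds a list of [RobustnessResult-class] objects into the long-format
#' table the statistical layer consumes: one row per (subject, algorithm,
#' number of channels, window length) and measure.
#'
#' @param results list of [RobustnessResult-class].
#' @return `data.frame` with columns `subject`, `algorithm`, `nChannels`,
#'   `windowLength`, `ACA`, `RES`.
#' @export
measureTable <- function(results) {
    do.call(rbind, lapply(results, function(r) {
        data.frame(subject = r@subjectId, algorithm = r@algorithm,
                   nChannels = r@nChannels, windowLength = r@windowLength,
                   ACA = r@aca, RES = r@res, stringsAsFactors = FALSE)
    }))
}

checkCrossing <- function(table, measure) {
    need <- c("subject", "algorithm", "nChannels", measure)
    missing <- setdiff(need, names(table))
    if (length(missing))
        stop("table missing column(s): ", paste(missing, collapse = ", "))
    counts <- table(table$subject, table$algorithm, table$nChannels)
    if (any(counts != 1L))
        stop("incomplete or unbalanced design: every subject needs ",
             "exactly one value per (algorithm, nChannels) cell")
    invisible(TRUE)
}

#' Two-way repeated-measures ANOVA over channels and algorithm
#'
#' Fully within-subject two-way ANOVA with factors number of channels and
#' classification algorithm, fitted per window length on a complete
#' balanced crossing. Each main effect is tested against its
#' subject-by-factor interaction error stratum; no sphericity correction
#' is applied, so with 21 subjects, 3 channel counts and 5 algorithms the
#' degrees of freedom are (2, 40), (4, 80) and (8, 160) for the two main
#' effects and the interaction.
#'
#' @param table long-format `data.frame` (see [measureTable()]) for a
#'   single window length.
#' @param measure column to analyse, `"ACA"` or `"RES"`.
#' @return `data.frame` with columns `effect`, `F`, `df`, `dfError`, `p`.
#' @export
rmAnovaTwoWay <- function(table, measure = c("ACA", "RES")) {
    measure <- match.arg(measure)
    if (length(unique(table$windowLength)) > 1L)
        stop("fit one window length at a time")
    checkCrossing(table, measure)
    d <- data.frame(subject = factor(table$subject),
                    ch = factor(table$nChannels),
                    alg = factor(table$algorithm),
                    y = table[[measure]])
    fit <- stats::aov(y ~ ch * alg + Error(subject / (ch * alg)), data = d)
    s <- summary(fit)
    pull <- function(stratum, term) {
        tab <- s[[stratum]][[1L]]
        i <- match(term, trimws(rownames(tab)))
        data.frame(effect = term,
                   F = tab[i, "F value"],
                   df = tab[i, "Df"],
                   dfError = tab[trimws(rownames(tab)) == "Residuals",
                                 "Df"],
                   p = tab[i, "Pr(>F)"])
    }
    out <- rbind(pull("Error: subject:ch", "ch"),
                 pull("Error: subject:alg", "alg"),
                 pull("Error: subject:ch:alg", "ch:alg"))
    out$effect <- c("nChannels", "algorithm", "nChannels:algorithm")
    rownames(out) <- NULL
    out
}

#' Bonferroni-corrected paired t-tests
#'
#' Two-sided paired t-tests between levels of one factor, each computed on
#' per-subject values averaged over the other factor's levels present in
#' the table, with Bonferroni correction over the whole family of pairs
#' tested (raw p times the number of comparisons, capped at 1). Pairs with
#' zero difference variance are reported as non-significant with a
#' `degenerate` flag rather than an error, so pipelines never crash on
#' constant synthetic data.
#'
#' @param table long-format `data.frame` for a single window length.
#' @param factor `"nChannels"` or `"algorithm"`: the factor whose levels
#'   are compared (3 pairs for channels, 10 for algorithms).
#' @param measure `"ACA"` or `"RES"`.
#' @param comparisons optional list of length-2 level vectors; default all
#'   unordered pairs of observed levels.
#' @return `data.frame` with columns `levelA`, `levelB`, `t`, `df`,
#'   `pRaw`, `pBonferroni`, `meanDiff`, `signOfDiff`, `degenerate`.
#' @export
pairedTBonferroni <- function(table, factor = c("nChannels", "algorithm"),
                              measure = c("ACA", "RES"),
                              comparisons = NULL) {
    factor <- match.arg(factor)
    measure <- match.arg(measure)
    lev <- sort(unique(table[[factor]]))
    if (is.null(comparisons)) {
        comparisons <- utils::combn(lev, 2L, simplify = FALSE)
    }
    m <- length(comparisons)
    rows <- lapply(comparisons, function(pair) {
        sub <- table[table[[factor]] %in% pair, ]
        agg <- stats::aggregate(sub[[measure]],
                                by = list(subject = sub$subject,
                                          level = sub[[factor]]),
                                FUN = mean)
        a <- agg[agg$level == pair[1L], ]
        b <- agg[agg$level == pair[2L], ]
        a <- a[order(a$subject), ]
        b <- b[order(b$subject), ]
        if (!identical(a$subject, b$subject))
            stop("levels ", pair[1L], " and ", pair[2L],
                 " observed on different subjects")
        dif <- a$x - b$x
        degenerate <- stats::sd(dif) == 0 || length(dif) < 2L
        if (degenerate) {
            data.frame(levelA = pair[1L], levelB = pair[2L],
                       t = NA_real_, df = length(dif) - 1L,
                       pRaw = 1, pBonferroni = 1,
                       meanDiff = mean(dif),
                       signOfDiff = sign(mean(dif)),
                       degenerate = TRUE)
        } else {
            tt <- stats::t.test(a$x, b$x, paired = TRUE)
            data.frame(levelA = pair[1L], levelB = pair[2L],
                       t = unname(tt$statistic),
                       df = unname(tt$parameter),
                       pRaw = tt$p.value,
                       pBonferroni = min(1, tt$p.value * m),
                       meanDiff = mean(dif),
                       signOfDiff = sign(mean(dif)),
                       degenerate = FALSE)
        }
    })
    do.call(rbind, rows)
}
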