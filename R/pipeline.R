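#' Default experiment configuration
#'
#' Nested configuration for [runExperiment()]: seed, simulation settings
#' (see [simulationConfig()]), preprocessing band and order, the algorithms,
#' channel counts and window lengths to evaluate, and an optional
#' `maxCombos` down-sampling of the combination grids for smoke runs.
#'
#' @param ... overrides merged over the defaults (top-level names; nested
#'   lists replace whole blocks).
#' @return A list of class `RunConfig`.
#' @export
runConfig <- function(...) {
    cfg <- list(
        seed = 1L,
        simulation = list(nSubjects = 2L, trialsPerFrequency = 10L),
        preprocess = list(band = c(4, 52), order = 3L),
        algorithms = c("CCA", "ECCA", "FBCCA", "MSI", "EMSI"),
        nChannelsList = c(1L, 2L, 3L),
        windowLengths = c(2, 2.5, 3, 3.5, 4, 4.5, 5),
        maxCombos = NULL,
        outputDir = NULL
    )
    over <- list(...)
    cfg[names(over)] <- over
    class(cfg) <- "RunConfig"
    cfg
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file whose top-level keys match [runConfig()] fields.
#' @return A `RunConfig` list.
#' @export
readRunConfig <- function(path) {
    do.call(runConfig, yaml::read_yaml(path))
}

#' Run the full electrode-shift robustness experiment
#'
#' Orchestrates simulate, preprocess, evaluate and stats as one seeded,
#' reproducible run: simulates every subject, band-pass filters, evaluates
#' every (algorithm, number of channels, window length) cell's
#' per-combination accuracies with ACA/RES summaries, and fits the
#' repeated-measures ANOVA with Bonferroni post-hoc tests per window
#' length (when at least two subjects are available). If `outputDir` is
#' set, tidy CSVs (per-combination accuracies, ACA/RES table, ANOVA and
#' post-hoc tables) and a JSON manifest are written there.
#'
#' @param config a [runConfig()] (or path to a YAML file).
#' @return List with elements `measures` (long-format `data.frame`),
#'   `results` (list of [RobustnessResult-class]), `anova` and `posthoc`
#'   (`data.frame`s, possibly empty), and `config`.
#' @export
runExperiment <- function(config = runConfig()) {
    if (is.character(config)) config <- readRunConfig(config)
    stopifnot(inherits(config, "RunConfig"))
    grid <- electrodeGrid()
    simArgs <- config$simulation
    simArgs$seed <- config$seed
    simCfg <- do.call(simulationConfig, simArgs)

    stage <- "simulate"
    out <- tryCatch({
        message("[simulate] ", simCfg$nSubjects, " subject(s), ",
                simCfg$trialsPerFrequency * 4L, " trials each")
        recs <- simulateStudy(simCfg, grid)

        stage <- "preprocess"
        message("[preprocess] band ",
                paste(config$preprocess$band, collapse = "-"), " Hz")
        recs <- lapply(recs, function(r) {
            if (r@fs > 256) r <- decimateRecording(r, 256)
            bandpassRecording(r, config$preprocess$band,
                              config$preprocess$order)
        })

        stage <- "evaluate"
        results <- list()
        for (alg in config$algorithms) {
            clsCfg <- classifierConfig(alg)
            for (nc in config$nChannelsList) {
                for (wl in config$windowLengths) {
                    message("[evaluate] ", alg, " ", nc, " ch ", wl, " s")
                    for (r in recs) {
                        results[[length(results) + 1L]] <-
                            evaluateRobustness(r, grid, clsCfg, nc, wl,
                                               config$maxCombos)
                    }
                }
            }
        }
        measures <- measureTable(results)

        stage <- "stats"
        anova <- data.frame()
        posthoc <- data.frame()
        enoughForStats <- length(recs) >= 2L &&
            length(config$algorithms) >= 2L &&
            length(config$nChannelsList) >= 2L
        if (enoughForStats) {
            for (wl in config$windowLengths) {
                sub <- measures[measures$windowLength == wl, ]
                for (ms in c("ACA", "RES")) {
                    a <- rmAnovaTwoWay(sub, ms)
                    a$measure <- ms
                    a$windowLength <- wl
                    anova <- rbind(anova, a)
                    for (fac in c("nChannels", "algorithm")) {
                        if (fac == "nChannels" &&
                            length(config$nChannelsList) < 2L) next
                        p <- pairedTBonferroni(sub, fac, ms)
                        p$factor <- fac
                        p$measure <- ms
                        p$windowLength <- wl
                        posthoc <- rbind(posthoc, p)
                    }
                }
            }
        }
        list(measures = measures, results = results, anova = anova,
             posthoc = posthoc, config = config)
    }, error = function(e) {
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
    })

    if (!is.null(config$outputDir)) writeExperiment(out, config$outputDir)
    out
}

writeExperiment <- function(out, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$measures, file.path(dir, "measures.csv"),
                     row.names = FALSE)
    combos <- do.call(rbind, lapply(out$results, function(r) {
        data.frame(subject = r@subjectId, algorithm = r@algorithm,
                   nChannels = r@nChannels, windowLength = r@windowLength,
                   combo = vapply(r@combos, paste, character(1L),
                                  collapse = "-"),
                   accuracy = r@accuracies, stringsAsFactors = FALSE)
    }))
    utils::write.csv(combos, file.path(dir, "combination_accuracies.csv"),
                     row.names = FALSE)
    if (nrow(out$anova))
        utils::write.csv(out$anova, file.path(dir, "anova.csv"),
                         row.names = FALSE)
    if (nrow(out$posthoc))
        utils::write.csv(out$posthoc, file.path(dir, "posthoc.csv"),
                         row.names = FALSE)
    manifest <- list(
        seed = out$config$seed,
        nSubjects = length(unique(out$measures$subject)),
        algorithms = unique(out$measures$algorithm),
        nChannelsList = unique(out$measures$nChannels),
        windowLengths = unique(out$measures$windowLength),
        nResultCells = nrow(out$measures),
        files = list.files(dir)
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(dir)
}
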