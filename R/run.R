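## Reproducible end-to-end runs binding the modules together; the shell
## front end in inst/cli/secloc.R is a thin dispatcher over these.

.checkPaths <- function(paths) {
    paths <- paths[!vapply(paths, is.null, logical(1))]
    bad <- !vapply(paths, file.exists, logical(1))
    if (any(bad))
        stop("input file not found: ", paths[[which(bad)[1]]],
             call. = FALSE)
    invisible(paths)
}

.echoConfig <- function(outDir, what, config) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    cfg <- vapply(config, function(x) paste(format(x), collapse = " "),
                  character(1))
    writeLines(paste0(names(cfg), " = ", cfg),
               file.path(outDir, paste0(what, "_config.txt")))
}

#' Annotate a proteome from predictor output files
#'
#' Reads the sequence set and the seven predictor files, assembles
#' verdict bundles, scans the ER-retention motif, runs the cascade and
#' writes `assignments.tsv` (plus a config echo) into `outDir`.
#'
#' @param fasta FASTA path. Either this or `uniprot` is required;
#'   `uniprot` additionally supplies curated annotation and species.
#' @param uniprot Optional UniProt flat-text path.
#' @param signalp3,signalp4,targetp,phobius,wolfpsort,tmhmm,fraganchor
#'   Predictor output paths; in strict mode all seven are required.
#' @param outDir Output directory.
#' @param mode `"strict"` or `"lenient"` (see [classifyProteins()]).
#' @param maxIdMismatch Abort when more than this fraction of sequence
#'   ids lacks a verdict from a supplied tool file.
#' @param ... Passed on to [classifyProteins()].
#' @return The assignment data.frame, invisibly.
#' @export
runAnnotate <- function(fasta = NULL, uniprot = NULL,
                        signalp3 = NULL, signalp4 = NULL, targetp = NULL,
                        phobius = NULL, wolfpsort = NULL, tmhmm = NULL,
                        fraganchor = NULL, outDir,
                        mode = c("strict", "lenient"),
                        maxIdMismatch = 0.2, ...) {
    mode <- match.arg(mode)
    toolPaths <- list(SIGNALP3 = signalp3, SIGNALP4 = signalp4,
                      TARGETP = targetp, PHOBIUS = phobius,
                      WOLFPSORT = wolfpsort, TMHMM = tmhmm,
                      FRAGANCHOR = fraganchor)
    if (is.null(fasta) && is.null(uniprot))
        stop("need a FASTA or UniProt flat file", call. = FALSE)
    if (mode == "strict") {
        absent <- names(toolPaths)[vapply(toolPaths, is.null, logical(1))]
        if (length(absent))
            stop("strict mode requires all seven predictor files; ",
                 "missing: ", paste(absent, collapse = ", "),
                 call. = FALSE)
    }
    .checkPaths(c(list(fasta = fasta, uniprot = uniprot), toolPaths))

    proteins <- if (!is.null(uniprot)) parseUniprotFlat(uniprot)
                else readProteinFasta(fasta)
    parsers <- list(SIGNALP3 = function(p) parseSignalp(p, 3),
                    SIGNALP4 = function(p) parseSignalp(p, 4),
                    TARGETP = parseTargetp, PHOBIUS = parsePhobius,
                    WOLFPSORT = parseWolfpsort, TMHMM = parseTmhmm,
                    FRAGANCHOR = parseFraganchor)
    vl <- list()
    for (tool in names(toolPaths)) {
        if (is.null(toolPaths[[tool]])) next
        tab <- parsers[[tool]](toolPaths[[tool]])
        frac <- mean(!accessions(proteins) %in% tab$proteinId)
        if (frac > maxIdMismatch)
            stop(sprintf(
                "%.0f%% of sequence ids have no %s verdict (limit %.0f%%): id mismatch between inputs?",
                100 * frac, tool, 100 * maxIdMismatch), call. = FALSE)
        vl[[tool]] <- tab
    }
    bundles <- assembleBundles(unname(vl), ids = accessions(proteins))
    assignments <- classifyProteins(bundles, proteins = proteins,
                                    mode = mode, ...)
    .echoConfig(outDir, "annotate",
                list(fasta = fasta, uniprot = uniprot, mode = mode,
                     maxIdMismatch = maxIdMismatch,
                     tools = paste(names(vl), collapse = ",")))
    writeAssignments(assignments, file.path(outDir, "assignments.tsv"))
    message("annotated ", nrow(assignments), " proteins -> ",
            file.path(outDir, "assignments.tsv"))
    invisible(assignments)
}

#' Benchmark predictor-combination rules on curated annotation
#'
#' Builds the curated single-location benchmark from a UniProt flat file
#' and scores each rule, writing `metrics.tsv` and the exclusion tally.
#'
#' @param uniprot UniProt flat-text path (benchmark source).
#' @param rules data.frame with `rule` and `category` columns (see
#'   [evaluateRule()]), or path to such a TSV.
#' @param outDir Output directory.
#' @inheritParams runAnnotate
#' @return The metrics data.frame, invisibly.
#' @export
runEvaluate <- function(uniprot, rules,
                        signalp3 = NULL, signalp4 = NULL, targetp = NULL,
                        phobius = NULL, wolfpsort = NULL, tmhmm = NULL,
                        fraganchor = NULL, outDir) {
    if (is.character(rules)) {
        .checkPaths(list(rules = rules))
        rules <- utils::read.delim(rules, stringsAsFactors = FALSE)
    }
    if (!nrow(rules)) stop("empty rule list", call. = FALSE)
    proteins <- parseUniprotFlat(.checkPaths(list(uniprot))[[1]])
    benchmark <- buildBenchmark(proteins)
    toolPaths <- list(SIGNALP3 = signalp3, SIGNALP4 = signalp4,
                      TARGETP = targetp, PHOBIUS = phobius,
                      WOLFPSORT = wolfpsort, TMHMM = tmhmm,
                      FRAGANCHOR = fraganchor)
    parsers <- list(SIGNALP3 = function(p) parseSignalp(p, 3),
                    SIGNALP4 = function(p) parseSignalp(p, 4),
                    TARGETP = parseTargetp, PHOBIUS = parsePhobius,
                    WOLFPSORT = parseWolfpsort, TMHMM = parseTmhmm,
                    FRAGANCHOR = parseFraganchor)
    vl <- list()
    for (tool in names(toolPaths))
        if (!is.null(toolPaths[[tool]]))
            vl[[tool]] <- parsers[[tool]](.checkPaths(toolPaths[tool])[[1]])
    bundles <- assembleBundles(unname(vl), ids = accessions(proteins))
    hits <- scanProsite(proteins)
    metrics <- evaluateRule(rules, benchmark, bundles,
                            motifHits = stats::setNames(hits$hit,
                                                        hits$proteinId))
    .echoConfig(outDir, "evaluate", list(uniprot = uniprot,
                                         nRules = nrow(rules)))
    utils::write.table(metrics, file.path(outDir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    excl <- attr(benchmark, "exclusions")
    writeLines(paste0(names(excl), "\t", as.integer(excl)),
               file.path(outDir, "benchmark_exclusions.tsv"))
    invisible(metrics)
}

#' Per-species summary run
#'
#' @param assignments Assignment data.frame or `assignments.tsv` path.
#' @param uniprot UniProt flat-text path supplying species information.
#' @param outDir Output directory.
#' @param ... Passed on to [summarizeSpecies()].
#' @return The summary data.frame, invisibly.
#' @export
runSummarize <- function(assignments, uniprot, outDir, ...) {
    if (is.character(assignments)) {
        .checkPaths(list(assignments))
        assignments <- utils::read.delim(assignments,
                                         stringsAsFactors = FALSE)
    }
    if (!nrow(assignments)) stop("no assignments to summarize",
                                 call. = FALSE)
    proteins <- parseUniprotFlat(.checkPaths(list(uniprot))[[1]])
    summaries <- summarizeSpecies(assignments, proteins, ...)
    .echoConfig(outDir, "summarize", list(uniprot = uniprot))
    writeSpeciesSummary(summaries, file.path(outDir, "species_summary.tsv"))
    invisible(summaries)
}

#' Simulation run
#'
#' @param outDir Output directory for the generated files.
#' @param ... Passed to [simulationConfig()].
#' @return See [simulateProteome()].
#' @export
runSimulate <- function(outDir, ...) {
    config <- simulationConfig(...)
    .echoConfig(outDir, "simulate",
                config[setdiff(names(config), "categoryMix")])
    simulateProteome(config, outDir)
}
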