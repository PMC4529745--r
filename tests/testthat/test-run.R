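test_that("annotate run reproduces the simulated truth end to end", {
    d <- withr::local_tempdir()
    sim <- simulateProteome(simulationConfig(nProteins = 300, seed = 21), d)
    out <- withr::local_tempdir()
    p <- sim$paths
    a <- suppressMessages(runAnnotate(
        fasta = p["fasta"], uniprot = p["uniprot"],
        signalp3 = p["signalp3"], signalp4 = p["signalp4"],
        targetp = p["targetp"], phobius = p["phobius"],
        wolfpsort = p["wolfpsort"], tmhmm = p["tmhmm"],
        fraganchor = p["fraganchor"], outDir = out))
    expect_true(file.exists(file.path(out, "assignments.tsv")))
    expect_true(file.exists(file.path(out, "annotate_config.txt")))
    expect_identical(a$category,
                     sim$truth$category[match(a$proteinId,
                                              sim$truth$protein_id)])
    # the written table reloads to the same assignments
    back <- read.delim(file.path(out, "assignments.tsv"),
                       stringsAsFactors = FALSE)
    expect_equal(back$category, a$category)
})

test_that("strict mode aborts on a missing predictor file", {
    d <- withr::local_tempdir()
    sim <- simulateProteome(simulationConfig(nProteins = 50, seed = 4), d)
    p <- sim$paths
    expect_error(runAnnotate(fasta = p["fasta"], signalp3 = p["signalp3"],
                             signalp4 = p["signalp4"], targetp = p["targetp"],
                             phobius = p["phobius"], wolfpsort = p["wolfpsort"],
                             tmhmm = p["tmhmm"],
                             outDir = withr::local_tempdir()),
                 "missing: FRAGANCHOR")
    # lenient mode runs with a warning instead
    expect_warning(suppressMessages(runAnnotate(
        fasta = p["fasta"], signalp3 = p["signalp3"],
        signalp4 = p["signalp4"], targetp = p["targetp"],
        phobius = p["phobius"], wolfpsort = p["wolfpsort"],
        tmhmm = p["tmhmm"], outDir = withr::local_tempdir(),
        mode = "lenient")), "lenient")
})

test_that("id mismatch between sequences and tool files aborts", {
    d <- withr::local_tempdir()
    sim <- simulateProteome(simulationConfig(nProteins = 40, seed = 6), d)
    p <- sim$paths
    other <- file.path(d, "other.fasta")
    writeLines(c(">ZZ1", "MAAAG", ">ZZ2", "MKKKG"), other)
    expect_error(suppressMessages(runAnnotate(
        fasta = other, signalp3 = p["signalp3"], signalp4 = p["signalp4"],
        targetp = p["targetp"], phobius = p["phobius"],
        wolfpsort = p["wolfpsort"], tmhmm = p["tmhmm"],
        fraganchor = p["fraganchor"], outDir = withr::local_tempdir())),
        "id mismatch")
})

test_that("evaluate and summarize runs bind the modules together", {
    d <- withr::local_tempdir()
    sim <- simulateProteome(
        simulationConfig(nProteins = 600, seed = 31, curatedFraction = 0.5,
                         hedgedFraction = 0, multiFraction = 0), d)
    p <- sim$paths
    out <- withr::local_tempdir()
    res <- runEvaluate(
        uniprot = p["uniprot"],
        rules = data.frame(rule = "targetp=M AND wolf=mito",
                           category = "Mitochondria",
                           stringsAsFactors = FALSE),
        signalp3 = p["signalp3"], signalp4 = p["signalp4"],
        targetp = p["targetp"], phobius = p["phobius"],
        wolfpsort = p["wolfpsort"], tmhmm = p["tmhmm"],
        fraganchor = p["fraganchor"], outDir = out)
    expect_true(file.exists(file.path(out, "metrics.tsv")))
    # noiseless tools on curated mito entries: perfect recovery
    expect_equal(res$fn, 0); expect_equal(res$fp, 0)

    a <- suppressMessages(runAnnotate(
        fasta = p["fasta"], uniprot = p["uniprot"],
        signalp3 = p["signalp3"], signalp4 = p["signalp4"],
        targetp = p["targetp"], phobius = p["phobius"],
        wolfpsort = p["wolfpsort"], tmhmm = p["tmhmm"],
        fraganchor = p["fraganchor"], outDir = out))
    s <- runSummarize(file.path(out, "assignments.tsv"), p["uniprot"],
                      outDir = out)
    expect_equal(sum(s$totalProteins), 600L)
    expect_true(file.exists(file.path(out, "species_summary.tsv")))
    expect_error(runSummarize(a[0, ], p["uniprot"],
                              outDir = withr::local_tempdir()),
                 "no assignments")
})
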