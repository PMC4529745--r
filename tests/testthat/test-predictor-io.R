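sp3Line <- function(id, flag, ypos = 23)
    sprintf("%s  0.5  %d %s  0.5  %d %s  0.7  5 %s  0.6 %s  0.55 %s",
            id, ypos, flag, ypos, flag, flag, flag, flag)
sp4Line <- function(id, flag, cpos = 23)
    sprintf("%s  0.5  %d  0.48  %d  0.7  5  0.6  0.55 %s  0.45  SignalP-noTM",
            id, cpos, cpos, flag)

test_that("SignalP parsing reads the printed decision and cleavage site", {
    v3 <- parseSignalp(I(paste("# comment", sp3Line("P1", "Y"),
                               sp3Line("P2", "N"), sep = "\n")), 3)
    expect_equal(attr(v3, "tool"), "SIGNALP3")
    expect_equal(v3$signal, c(TRUE, FALSE))
    expect_equal(v3$cleavage, c(22L, NA_integer_))

    v4 <- parseSignalp(I(sp4Line("P1", "Y", 23)), 4)
    expect_equal(v4$cleavage, 22L)
    expect_true(v4$signal)

    # comment-only file -> empty verdict list
    expect_equal(nrow(parseSignalp(I("# only a comment\n# another"), 4)),
                 0L)
    expect_error(parseSignalp(I("P1 garbage"), 4), "malformed line")
    expect_warning(try(parseSignalp(I(sp3Line("P1", "Y")), 4),
                       silent = TRUE), "other SignalP version")
})

test_that("TargetP Loc symbols map to S/M/OTHER and reject junk", {
    txt <- paste("Name  Len  mTP  SP  other  Loc  RC",
                 "----------------------------------",
                 "P1  120  0.1  0.9  0.1  S  2",
                 "P2  120  0.9  0.1  0.1  M  1",
                 "P3  120  0.1  0.1  0.9  _  3", sep = "\n")
    v <- parseTargetp(I(txt))
    expect_equal(v$loc, c("S", "M", "OTHER"))
    expect_error(parseTargetp(I("P1  120  0.1  0.9  0.1  Q  2")),
                 "unknown Loc")
})

test_that("Phobius SP column becomes a boolean; header is skipped", {
    txt <- paste("SEQENCE ID  TM SP PREDICTION",
                 "P1  0  Y  n4-19c24/25o",
                 "P2  2  0  i10-30o100-122i", sep = "\n")
    v <- parsePhobius(I(txt))
    expect_equal(v$signal, c(TRUE, FALSE))
    expect_equal(v$tmCount, c(0L, 2L))
    expect_equal(nrow(parsePhobius(I("SEQENCE ID  TM SP PREDICTION"))), 0L)
})

test_that("WoLF PSORT keeps dual labels verbatim and enforces ordering", {
    v <- parseWolfpsort(I("P1 extr 26, plas 4\nP2 extr_plas 14, extr 9"))
    expect_equal(v$topLabel, c("extr", "extr_plas"))
    expect_equal(v$scores[1], "extr 26, plas 4")
    expect_error(parseWolfpsort(I("P1 plas 4, extr 26")), "decreasing")
    sorted <- parseWolfpsort(I("P1 plas 4, extr 26"), resort = TRUE)
    expect_equal(sorted$topLabel, "extr")
    expect_error(parseWolfpsort(I("P1   ")), "empty score list")
})

test_that("TMHMM topology parses to 1-based inclusive helices", {
    txt <- paste(
        "P1\tlen=210\tExpAA=0.0\tFirst60=0.0\tPredHel=0\tTopology=o",
        "P2\tlen=210\tExpAA=45.1\tFirst60=0.0\tPredHel=2\tTopology=o10-30i120-142o",
        sep = "\n")
    v <- parseTmhmm(I(txt))
    expect_equal(nrow(v$helices[[1]]), 0L)
    expect_equal(v$helices[[2]][, "start"], c(10L, 120L))
    expect_equal(v$helices[[2]][, "end"], c(30L, 142L))
    expect_error(parseTmhmm(I(
        "P3\tlen=100\tExpAA=20\tFirst60=0\tPredHel=2\tTopology=o120-142i")),
        "PredHel=2 but 1")
})

test_that("FragAnchor classes map to the internal enum", {
    v <- parseFraganchor(I("P1\tHighly probable\nP2\tPotential false positive"))
    expect_equal(v$gpiClass, c("HIGHLY_PROBABLE", "NONE"))
    expect_error(parseFraganchor(I("P1\tMaybe")), "unknown class")
})

test_that("bundle assembly tracks per-tool completeness", {
    full <- makeBundles(data.frame(id = "P1", sp4 = TRUE))
    expect_true(verdicts(full)$complete)

    six <- assembleBundles(list(
        structure(data.frame(proteinId = "P1", loc = "S"),
                  tool = "TARGETP")), ids = c("P1", "P2"))
    v <- verdicts(six)
    expect_false(any(v$complete))
    expect_true(v$hasTargetp[v$proteinId == "P1"])
    expect_false(v$hasTargetp[v$proteinId == "P2"])
    # absent verdicts stay NA, never a fabricated negative
    expect_true(is.na(v$sp4Signal[v$proteinId == "P1"]))
    expect_equal(nrow(verdicts(assembleBundles(list()))), 0L)
})

test_that("verdict tables round-trip losslessly through the long TSV", {
    spec <- data.frame(id = c("P1", "P2", "P3"),
                       sp3 = c(TRUE, FALSE, TRUE),
                       sp4 = c(TRUE, FALSE, FALSE),
                       phob = c(TRUE, TRUE, FALSE),
                       targetp = c("S", "M", "OTHER"),
                       wolf = c("extr", "mito", "extr_plas"),
                       tmStart = c(NA, 100, NA),
                       frag = c("HIGHLY_PROBABLE", "NONE", "PROBABLE"),
                       stringsAsFactors = FALSE)
    b <- makeBundles(spec)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeVerdictTable(b, f)
    b2 <- readVerdictTable(f)
    v1 <- verdicts(b); v2 <- verdicts(b2)
    v2 <- v2[match(v1$proteinId, v2$proteinId), ]
    for (col in setdiff(names(v1), "tmHelices"))
        expect_equal(unname(v2[[col]]), unname(v1[[col]]), label = col)
    for (i in seq_len(nrow(v1)))
        expect_equal(unname(v2$tmHelices[[i]]), unname(v1$tmHelices[[i]]))
})
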