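test_that("benchmark filters exclude hedged, short, multi-location records", {
    txt <- paste(
        upRecord("K1", strrep("MA", 50), locs = "Nucleus"),
        upRecord("X1", strrep("MA", 30), locs = "Nucleus"),  # 60 aa
        upRecord("X2", strrep("MA", 50), locs = c("Cytoplasm", "Nucleus")),
        upRecord("X3", strrep("MA", 50), locs = "Secreted (Probable)"),
        upRecord("X4", strrep("MA", 50), locs = "Secreted (By similarity)"),
        upRecord("X5", strrep("MA", 50), locs = "Nucleus", fragment = TRUE),
        upRecord("X6", paste0("A", strrep("MA", 50)), locs = "Nucleus"),
        upRecord("X7", strrep("MA", 50), locs = "Nucleus",
                 reviewed = FALSE),
        upRecord("K2", strrep("MA", 50),
                 locs = c("Cytoplasm", "Cytoskeleton")),
        upRecord("K3", strrep("MA", 50), locs = "Cell membrane"),
        sep = "\n")
    ps <- parseUniprotFlat(I(txt))
    bm <- buildBenchmark(ps)
    expect_setequal(attr(bm, "universe"), c("K1", "K2", "K3"))
    expect_equal(bm$Nucleus, "K1")
    # cytoplasm+cytoskeleton is cytoskeleton, never cytoplasm
    expect_equal(bm$Cytoskeleton, "K2")
    expect_length(bm$Cytoplasm, 0L)
    # cell membrane populates plasma membrane
    expect_equal(bm$`Plasma membrane`, "K3")
    excl <- attr(bm, "exclusions")
    expect_equal(unname(excl[["too_short"]]), 1L)
    expect_equal(unname(excl[["multiple_locations"]]), 1L)
    expect_equal(unname(excl[["qualifier"]]), 2L)
    expect_equal(unname(excl[["fragment"]]), 1L)
    expect_equal(unname(excl[["no_initial_met"]]), 1L)
    expect_equal(unname(excl[["unreviewed"]]), 1L)
})

test_that("confusion counts enumerate the 2x2 partition", {
    u <- paste0("p", 1:10)
    act <- u[1:4]
    pred <- c(u[1:3], u[5])
    cm <- confusion(pred, act, u)
    expect_equal(cm@tp, 3); expect_equal(cm@fn, 1)
    expect_equal(cm@fp, 1); expect_equal(cm@tn, 5)

    perfect <- confusion(u, u, u)
    expect_equal(perfect@fp + perfect@fn, 0)
    none <- confusion(character(0), act, u)
    expect_equal(none@tp + none@fp, 0)
    expect_error(confusion("zz", act, u), "subset")
})

test_that("metrics reproduce printed reference values and error on zeros", {
    expect_equal(sensitivity(confusionMatrix(930, 972, 16032, 940)), 49.7)
    expect_equal(specificity(confusionMatrix(930, 972, 16032, 940)), 94.3)
    expect_equal(sensitivity(confusionMatrix(5024, 276, 12874, 700)), 87.8)
    expect_equal(mcc(confusionMatrix(794, 262, 16742, 1076)), 0.53)
    expect_equal(mcc(confusionMatrix(5350, 522, 12628, 374)), 0.89)
    expect_equal(mcc(confusionMatrix(10, 0, 10, 0)), 1)
    expect_error(mcc(confusionMatrix(0, 0, 18855, 19)), "undefined")
    expect_error(sensitivity(confusionMatrix(0, 5, 10, 0)), "undefined")
})

test_that("MCC is invariant under the tp<->tn, fp<->fn swap", {
    set.seed(11)
    for (i in 1:25) {
        v <- sample.int(500, 4) # all marginals positive
        expect_equal(mcc(confusionMatrix(v[1], v[2], v[3], v[4]),
                         digits = NA),
                     mcc(confusionMatrix(v[3], v[4], v[1], v[2]),
                         digits = NA))
    }
})

test_that("rule evaluation: AND is at least as specific as OR", {
    set.seed(5)
    n <- 400
    truth <- sample(c("MITO_NONMEMBRANE", "CYTOPLASM", "NUCLEAR_NONMEMBRANE"),
                    n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
    isMito <- truth == "MITO_NONMEMBRANE"
    # noisy tools
    tgt <- ifelse(stats::runif(n) < ifelse(isMito, 0.7, 0.08), "M", "OTHER")
    wolfIsMito <- stats::runif(n) < ifelse(isMito, 0.65, 0.05)
    wolf <- ifelse(wolfIsMito, "mito",
                   ifelse(truth == "CYTOPLASM", "cyto", "nucl"))
    ids <- sprintf("q%03d", seq_len(n))
    b <- makeBundles(data.frame(id = ids, targetp = tgt, wolf = wolf,
                                stringsAsFactors = FALSE))
    locs <- c(MITO_NONMEMBRANE = "Mitochondrion", CYTOPLASM = "Cytoplasm",
              NUCLEAR_NONMEMBRANE = "Nucleus")
    txt <- paste(vapply(seq_len(n), function(i)
        upRecord(ids[i], strrep("MA", 60), locs = locs[[truth[i]]]),
        character(1)), collapse = "\n")
    bm <- buildBenchmark(parseUniprotFlat(I(txt)))
    res <- evaluateRule(data.frame(
        rule = c("targetp=M AND wolf=mito", "targetp=M OR wolf=mito"),
        category = "Mitochondria", stringsAsFactors = FALSE), bm, b)
    expect_gte(res$sp[1], res$sp[2])
    expect_lte(res$tp[1], res$tp[2])
    expect_error(evaluateRule(data.frame(rule = "targetp=M",
                                         category = "Mitochondira"),
                              bm, b), "unknown benchmark category")
    expect_error(applyRule("frobnicate", b), "unknown rule predicate")
})

test_that("an empty benchmark category is flagged undefined, not scored", {
    ids <- c("a1", "a2", "a3")
    txt <- paste(vapply(ids, function(i)
        upRecord(i, strrep("MA", 50), locs = "Nucleus"), character(1)),
        collapse = "\n")
    bm <- buildBenchmark(parseUniprotFlat(I(txt)))
    b <- makeBundles(data.frame(id = ids))
    res <- evaluateRule(data.frame(rule = "targetp=M",
                                   category = "Vacuole"), bm, b)
    expect_true(res$undefined)
    expect_true(is.na(res$mcc))
})
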