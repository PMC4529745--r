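test_that("secretion votes count the four voting tools", {
    b <- makeBundles(data.frame(
        id = c("P1", "P2", "P3"),
        sp4 = c(TRUE, TRUE, FALSE),
        phob = c(TRUE, TRUE, FALSE),
        targetp = c("S", "S", "OTHER"),
        wolf = c("extr", "nucl", "cyto"), stringsAsFactors = FALSE))
    expect_equal(unname(countSecretionVotes(b)), c(4L, 3L, 0L))
    # a dual label votes through its first component
    b2 <- makeBundles(data.frame(id = "P4", wolf = "extr_plas"))
    expect_equal(unname(countSecretionVotes(b2)), 1L)
})

test_that("membrane call ignores helices within the first 70 residues", {
    hl <- list(a = cbind(start = 10L, end = 30L),
               b = rbind(c(10L, 30L), c(100L, 122L)),
               c = matrix(integer(0), ncol = 2),
               d = cbind(start = 71L, end = 93L),
               e = cbind(start = 70L, end = 92L))
    got <- isMembraneByTmhmm(hl)
    expect_equal(unname(got), c(FALSE, TRUE, FALSE, TRUE, FALSE))
})

test_that("the cascade follows the documented rule order", {
    b <- makeBundles(data.frame(
        id = paste0("P", 1:6),
        sp4 = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
        phob = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
        targetp = c("S", "S", "M", "S", "OTHER", "OTHER"),
        wolf = c("extr", "extr", "mito", "extr", "E.R.", "golg"),
        tmStart = c(NA, 100, NA, NA, NA, 100),
        sp3 = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
        frag = c("NONE", "NONE", "NONE", "HIGHLY_PROBABLE", "NONE",
                 "NONE"), stringsAsFactors = FALSE))
    a <- classifyProteins(b)
    rownames(a) <- a$proteinId

    # votes with no exclusion -> secreted, highly likely
    expect_equal(a["P1", "category"], "SECRETED")
    expect_equal(a["P1", "tier"], "HIGHLY_LIKELY")
    # 4 votes but a late helix -> never secreted
    expect_false(a["P2", "category"] == "SECRETED")
    expect_true(a["P2", "isMembrane"])
    # mitochondrial agreement rule, no TM
    expect_equal(a["P3", "category"], "MITO_NONMEMBRANE")
    # GPI refinement: SignalP3 + FragAnchor on a secreted call
    expect_equal(a["P4", "category"], "GPI_ANCHORED")
    expect_true(a["P4", "gpiAnchored"])
    # WoLF E.R., no TM -> lumen
    expect_equal(a["P5", "category"], "ER_LUMEN")
    # golg + TM -> Golgi membrane
    expect_equal(a["P6", "category"], "GOLGI_MEMBRANE")
    expect_true(all(nzchar(a$ruleTrace)))
})

test_that("curated annotation outranks every prediction", {
    ps <- parseUniprotFlat(I(upRecord("P1", "MAAAG", locs = "Secreted")))
    b <- makeBundles(data.frame(id = "P1"))   # all predictors negative
    a <- classifyProteins(b, proteins = ps)
    expect_equal(a$category, "SECRETED")
    expect_equal(a$tier, "CURATED_SECRETED")
    expect_equal(a$evidence, "CURATED")
})

test_that("ER-retention motif blocks the secretion rule", {
    ps <- ProteinSet(c(P1 = "MAASKDEL"))
    b <- makeBundles(data.frame(id = "P1", sp4 = TRUE, phob = TRUE,
                                targetp = "S", wolf = "extr"))
    a <- classifyProteins(b, proteins = ps)
    expect_equal(a$category, "ER_LUMEN")     # SignalP4 + motif, no TM
    aNo <- classifyProteins(b, motifHits = c(P1 = FALSE))
    expect_equal(aNo$category, "SECRETED")
})

test_that("strict mode rejects incomplete bundles; lenient warns once", {
    partial <- assembleBundles(list(
        structure(data.frame(proteinId = "P1", loc = "S"),
                  tool = "TARGETP")), ids = "P1")
    expect_error(classifyProteins(partial), "missing tools")
    expect_warning(a <- classifyProteins(partial, mode = "lenient"),
                   "lenient")
    expect_equal(a$category, "SECRETED")   # the one vote still counts
    expect_equal(a$tier, "WEAKLY_LIKELY")
})

test_that("tier is monotone in the vote count and traces are reproducible", {
    mk <- function(v) makeBundles(data.frame(
        id = "P", sp4 = v >= 1, phob = v >= 2,
        targetp = ifelse(v >= 3, "S", "OTHER"),
        wolf = ifelse(v >= 4, "extr", "nucl"), stringsAsFactors = FALSE))
    tiers <- vapply(1:4, function(v)
        classifyProteins(mk(v))$tier, character(1))
    rank <- match(tiers, c("WEAKLY_LIKELY", "LIKELY", "HIGHLY_LIKELY"))
    expect_true(all(diff(rank) >= 0))
    a1 <- classifyProteins(mk(3)); a2 <- classifyProteins(mk(3))
    expect_identical(a1$ruleTrace, a2$ruleTrace)
})
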