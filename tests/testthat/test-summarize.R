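mkAssign <- function(id, category, tier = NA_character_,
                     evidence = "PREDICTED") {
    data.frame(proteinId = id, category = category, tier = tier,
               evidence = evidence, votes = 0L, gpiAnchored = FALSE,
               isMembrane = FALSE, ruleTrace = "t",
               stringsAsFactors = FALSE)
}

test_that("species summaries count tiers and size the secretome", {
    n <- 100
    ids <- sprintf("s%03d", 1:n)
    a <- do.call(rbind, c(
        list(mkAssign(ids[1:5], "SECRETED", "CURATED_SECRETED", "CURATED"),
             mkAssign(ids[6:8], "SECRETED", "HIGHLY_LIKELY"),
             mkAssign(ids[9:10], "SECRETED", "LIKELY"),
             mkAssign(ids[11], "SECRETED", "WEAKLY_LIKELY"),
             mkAssign(ids[12:100], "CYTOPLASM"))))
    ps <- ProteinSet(stats::setNames(rep("MAG", n), ids),
                     info = data.frame(accession = ids,
                                       speciesName = "Toy species",
                                       taxonId = 1L))
    s <- summarizeSpecies(a, ps)
    expect_equal(nrow(s), 1L)
    expect_equal(s$totalProteins, 100L)
    expect_equal(s$curatedSecreted, 5L)
    expect_equal(s$hls, 3L); expect_equal(s$ls, 2L); expect_equal(s$wls, 1L)
    expect_equal(s$secretomeSize, 8L)      # curated + highly likely only
    expect_equal(s$secretomePct, 8.0)
    # per-category counts add up to the total, unknowns included
    cats <- grep("^n_", names(s), value = TRUE)
    expect_equal(sum(unlist(s[cats])), s$totalProteins)
    # likely tier counted only on request
    s2 <- summarizeSpecies(a, ps, includeLikely = TRUE)
    expect_equal(s2$secretomeSize, 10L)
})

test_that("summaries are invariant under input permutation", {
    set.seed(9)
    ids <- sprintf("r%03d", 1:60)
    a <- mkAssign(ids, sample(c("SECRETED", "CYTOPLASM", "UNKNOWN"), 60,
                              replace = TRUE))
    a$tier[a$category == "SECRETED"] <- "HIGHLY_LIKELY"
    ps <- ProteinSet(stats::setNames(rep("MAG", 60), ids),
                     info = data.frame(accession = ids,
                                       speciesName = rep(c("A sp.", "B sp."),
                                                         30),
                                       taxonId = rep(c(1L, 2L), 30)))
    s1 <- summarizeSpecies(a, ps)
    perm <- sample.int(nrow(a))
    s2 <- summarizeSpecies(a[perm, ], ps)
    expect_equal(s2, s1)
})

test_that("proteins without a taxon fall into a sentinel group", {
    ids <- c("u1", "u2", "u3")
    ps <- ProteinSet(stats::setNames(rep("MAG", 3), ids),
                     info = data.frame(accession = ids,
                                       speciesName = c("A sp.", NA, NA),
                                       taxonId = c(1L, NA, NA)))
    a <- mkAssign(ids, "CYTOPLASM")
    expect_warning(s <- summarizeSpecies(a, ps), "without a taxon")
    expect_equal(s$totalProteins[s$taxonId == 0], 2L)
})

test_that("noiseless regression recovers the line exactly", {
    X <- seq(10000, 70000, length.out = 20)
    d <- data.frame(taxonId = seq_along(X), totalProteins = X,
                    secretomeSize = 289.9 + 0.066 * X)
    r <- secretomeRegression(d)
    expect_equal(r$slope, 0.066, tolerance = 1e-12)
    expect_equal(r$intercept, 289.9, tolerance = 1e-9)
    expect_equal(r$r, 1.0, tolerance = 1e-12)
    expect_equal(r$nSpecies, 20L)
})

test_that("noisy regression recovers coefficients within OLS standard errors", {
    set.seed(23)
    n <- 60
    X <- stats::runif(n, 8000, 60000)
    Y <- 289.9 + 0.066 * X + stats::rnorm(n, sd = 300)
    r <- secretomeRegression(data.frame(taxonId = 1:n, totalProteins = X,
                                        secretomeSize = Y))
    se <- summary(r$fit)$coefficients[, "Std. Error"]
    expect_lt(abs(r$intercept - 289.9), 4 * se[1])
    expect_lt(abs(r$slope - 0.066), 4 * se[2])
})

test_that("degenerate regressions error out", {
    d2 <- data.frame(taxonId = 1:2, totalProteins = c(1e4, 2e4),
                     secretomeSize = c(800, 1500))
    expect_error(secretomeRegression(d2), "at least 3 species")
    d3 <- data.frame(taxonId = 1:3, totalProteins = rep(1e4, 3),
                     secretomeSize = c(800, 900, 1000))
    expect_error(secretomeRegression(d3), "zero variance")
    # exclusion filter is honoured
    d4 <- rbind(d2, data.frame(taxonId = 3:5, totalProteins = c(3e4, 4e4, 5e4),
                               secretomeSize = c(2000, 2700, 3500)))
    r <- secretomeRegression(d4, exclude = c(1, 2))
    expect_equal(r$nSpecies, 3L)
})
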