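#' Per-species subcellular proteome summary
#'
#' Counts assignments per category for each species, the secreted
#' confidence tiers, and the secretome size. The secretome is defined as
#' curated secreted plus highly-likely secreted (at least 3 of 4
#' predictor votes); likely and weakly-likely tiers are reported but not
#' counted unless `includeLikely = TRUE` (sensitivity analysis only).
#'
#' @param assignments Output of [classifyProteins()].
#' @param proteins A [ProteinSet-class] carrying species names and taxon
#'   ids. Proteins without a taxon are collected under a sentinel group
#'   with a warning.
#' @param includeLikely Count the likely tier into the secretome size.
#' @return data.frame with one row per species: `taxonId`,
#'   `speciesName`, `totalProteins`, one `n_<CATEGORY>` column per
#'   category, `curatedSecreted`, `hls`, `ls`, `wls`, `secretomeSize`,
#'   `secretomePct` (percent of total entries, to 0.1).
#' @export
summarizeSpecies <- function(assignments, proteins, includeLikely = FALSE) {
    stopifnot(methods::is(proteins, "ProteinSet"))
    info <- proteinInfo(proteins)
    idx <- match(assignments$proteinId, info$accession)
    if (anyNA(idx))
        stop("assignments contain proteins absent from the ProteinSet: ",
             assignments$proteinId[which(is.na(idx))[1]], call. = FALSE)
    taxon <- info$taxonId[idx]
    sp <- info$speciesName[idx]
    if (anyNA(taxon)) {
        warning(sum(is.na(taxon)), " proteins without a taxon collected ",
                "under taxon 0", call. = FALSE)
        sp[is.na(taxon)] <- "unassigned"
        taxon[is.na(taxon)] <- 0L
    }

    a <- assignments
    a$taxonId <- taxon
    a$speciesName <- sp
    cats <- locationCategories()
    groups <- split(a, a$taxonId)
    rows <- lapply(groups, function(g) {
        counts <- table(factor(g$category, levels = cats))
        curSec <- sum(g$category == "SECRETED" & g$evidence == "CURATED")
        tiers <- function(t) sum(!is.na(g$tier) & g$tier == t &
                                 g$category == "SECRETED" &
                                 g$evidence == "PREDICTED")
        hls <- tiers("HIGHLY_LIKELY"); ls <- tiers("LIKELY")
        wls <- tiers("WEAKLY_LIKELY")
        size <- curSec + hls + if (includeLikely) ls else 0L
        out <- data.frame(taxonId = g$taxonId[1],
                          speciesName = g$speciesName[1],
                          totalProteins = nrow(g),
                          stringsAsFactors = FALSE)
        for (ct in cats) out[[paste0("n_", ct)]] <- as.integer(counts[[ct]])
        out$curatedSecreted <- curSec
        out$hls <- hls; out$ls <- ls; out$wls <- wls
        out$secretomeSize <- size
        out$secretomePct <- roundHalfUp(100 * size / nrow(g), 1)
        out
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    out[order(out$taxonId), , drop = FALSE]
}

#' Secretome-size vs proteome-size regression
#'
#' Ordinary least squares of secretome size (Y) on proteome size (X)
#' across species, with the Pearson correlation coefficient.
#'
#' @param summaries Output of [summarizeSpecies()] (or any data.frame
#'   with the two columns named by `x` and `y`).
#' @param exclude Optional vector of `taxonId`s (or logical vector) of
#'   species to drop, e.g. those whose entry count strays far from the
#'   reference proteome.
#' @param x,y Column names for proteome and secretome size.
#' @return Object of class `"secretomeRegression"`: list with `slope`,
#'   `intercept`, `r`, `nSpecies` and the underlying `fit`.
#' @export
secretomeRegression <- function(summaries, exclude = NULL,
                                x = "totalProteins", y = "secretomeSize") {
    d <- summaries
    if (!is.null(exclude)) {
        drop <- if (is.logical(exclude)) exclude else d$taxonId %in% exclude
        d <- d[!drop, , drop = FALSE]
    }
    if (nrow(d) < 3)
        stop("regression needs at least 3 species (got ", nrow(d), ")",
             call. = FALSE)
    X <- d[[x]]; Y <- d[[y]]
    if (stats::var(X) == 0)
        stop("degenerate regression: proteome sizes have zero variance",
             call. = FALSE)
    fit <- stats::lm(Y ~ X)
    structure(list(slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   r = stats::cor(X, Y), nSpecies = nrow(d), fit = fit),
              class = "secretomeRegression")
}

#' @export
print.secretomeRegression <- function(x, ...) {
    cat(sprintf(
        "Secretome ~ proteome OLS over %d species:\n  Y = %.4g + %.4g X   (r = %.3f)\n",
        x$nSpecies, x$intercept, x$slope, x$r))
    invisible(x)
}

#' Write a species summary table as TSV
#'
#' @param summaries Output of [summarizeSpecies()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeSpeciesSummary <- function(summaries, path) {
    utils::write.table(summaries, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
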