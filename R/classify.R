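## The consensus cascade: curated annotation first, then the fixed rule
## order (secretion votes with transmembrane/ER-retention exclusions,
## mitochondrial agreement rule, ER rule, WoLF PSORT locations, residual
## membrane, unknown). All steps are vectorised over the bundle set; the
## fired rule is logged per protein so every assignment is auditable.

# first '_'-component of a WoLF PSORT label: dual labels such as
# "extr_plas" list the dominant compartment first
.wolfComponent <- function(label) {
    out <- sub("_.*$", "", label)
    out[is.na(label)] <- NA_character_
    out
}

.checkComplete <- function(v, toolsNeeded, mode) {
    has <- as.matrix(v[, .TOOL_HAS[toolsNeeded], drop = FALSE])
    if (all(has)) return(invisible())
    missing <- toolsNeeded[colSums(!has) > 0]
    if (mode == "strict")
        stop("incomplete bundles in strict mode; missing tools: ",
             paste(missing, collapse = ", "),
             " (first affected protein: ",
             v$proteinId[which(rowSums(!has) > 0)[1]], ")", call. = FALSE)
    warning("lenient mode: missing verdicts from ",
            paste(missing, collapse = ", "),
            " treated as negative", call. = FALSE)
}

#' Count secretion votes per protein
#'
#' One vote each from SignalP 4 (signal peptide), Phobius (signal
#' peptide), TargetP (Loc `S`) and WoLF PSORT (top label component
#' `extr`).
#'
#' @param bundles A [PredictionBundleSet-class].
#' @param mode `"strict"` errors when a voting tool is missing;
#'   `"lenient"` counts a missing tool as a negative vote and warns once.
#' @return Integer vector 0--4 named by protein id.
#' @export
countSecretionVotes <- function(bundles, mode = c("strict", "lenient")) {
    mode <- match.arg(mode)
    stopifnot(methods::is(bundles, "PredictionBundleSet"))
    v <- bundles@verdicts
    .checkComplete(v, c("SIGNALP4", "PHOBIUS", "TARGETP", "WOLFPSORT"), mode)
    asv <- function(x) as.integer(!is.na(x) & x)
    votes <- asv(v$sp4Signal) + asv(v$phobiusSignal) +
        asv(v$targetpLoc == "S") + asv(.wolfComponent(v$wolfTop) == "extr")
    stats::setNames(votes, v$proteinId)
}

#' Membrane call from TMHMM topology
#'
#' A protein is called membrane-bound when at least one predicted
#' transmembrane helix starts beyond residue 70; helices confined to the
#' first 70 residues are disregarded because they are routinely
#' confounded with signal peptides.
#'
#' @param bundles A [PredictionBundleSet-class], or a list of helix
#'   matrices as stored in its `tmHelices` column.
#' @param nTerminalCutoff Helix starts at or below this residue are
#'   ignored (default 70).
#' @return Logical vector named by protein id (for a bundle set).
#' @export
isMembraneByTmhmm <- function(bundles, nTerminalCutoff = 70L) {
    if (methods::is(bundles, "PredictionBundleSet")) {
        v <- bundles@verdicts
        hl <- v$tmHelices
        nm <- v$proteinId
    } else {
        hl <- bundles
        nm <- names(bundles)
    }
    out <- vapply(hl, function(h)
        !is.null(h) && nrow(h) > 0 && any(h[, 1] > nTerminalCutoff),
        logical(1))
    if (!is.null(nm)) names(out) <- nm
    out
}

#' Assign subcellular locations by the consensus cascade
#'
#' Applies, in order and terminally: (1) curated annotation; (2)
#' secretion votes with transmembrane and ER-retention exclusions,
#' including the GPI-anchor refinement (SignalP 3 signal peptide plus a
#' FragAnchor class at or above `gpiThreshold`); (3) the
#' TargetP-AND-WoLF-PSORT mitochondrial rule; (4) the ER rule (WoLF
#' PSORT `E.R.` or SignalP 4 signal plus an ER-retention motif); (5)
#' direct WoLF PSORT locations with membrane splits for Golgi, nucleus
#' and vacuole; (6) residual transmembrane proteins; (7) unknown.
#'
#' @param bundles A [PredictionBundleSet-class].
#' @param proteins Optional [ProteinSet-class] supplying curated
#'   annotation and sequences (used to scan the ER-retention motif when
#'   `motifHits` is not given).
#' @param motifHits Optional logical vector named by protein id: does the
#'   sequence carry the C-terminal ER-retention motif? Computed from
#'   `proteins` when omitted; proteins absent from the vector count as
#'   non-hits.
#' @param mode `"strict"` (default) requires all seven tools per protein;
#'   `"lenient"` treats missing verdicts as negative with one warning.
#' @param gpiThreshold Least FragAnchor class counted as a GPI anchor
#'   (`"HIGHLY_PROBABLE"`, the default, or `"PROBABLE"`,
#'   `"WEAKLY_PROBABLE"`).
#' @param reviewedOnly Honour curated annotation from reviewed entries
#'   only.
#' @param nTerminalCutoff Passed to [isMembraneByTmhmm()].
#' @return data.frame with one row per protein: `proteinId`, `category`,
#'   `tier` (`CURATED_SECRETED`/`HIGHLY_LIKELY`/`LIKELY`/`WEAKLY_LIKELY`
#'   or `NA`), `evidence` (`CURATED`/`PREDICTED`), `votes`,
#'   `gpiAnchored`, `isMembrane`, `ruleTrace`.
#' @export
classifyProteins <- function(bundles, proteins = NULL, motifHits = NULL,
                             mode = c("strict", "lenient"),
                             gpiThreshold = "HIGHLY_PROBABLE",
                             reviewedOnly = TRUE, nTerminalCutoff = 70L) {
    mode <- match.arg(mode)
    stopifnot(methods::is(bundles, "PredictionBundleSet"))
    gpiThreshold <- match.arg(gpiThreshold, .GPI_CLASSES[1:3])
    v <- bundles@verdicts
    ids <- v$proteinId
    n <- length(ids)
    .checkComplete(v, predictorTools(), mode)

    if (is.null(motifHits)) {
        motifHits <- if (!is.null(proteins)) {
            h <- scanProsite(proteins)
            stats::setNames(h$hit, h$proteinId)
        } else stats::setNames(logical(0), character(0))
    }
    kdel <- !is.na(motifHits[ids]) & motifHits[ids]

    curatedCat <- rep(NA_character_, n)
    curatedAll <- rep("", n)
    if (!is.null(proteins)) {
        eff <- effectiveCuratedCategory(proteins, reviewedOnly = reviewedOnly)
        hit <- intersect(ids, names(eff)[!is.na(eff)])
        curatedCat[match(hit, ids)] <- eff[hit]
        cur <- proteins@curated
        cur <- cur[cur$category %in% locationCategories() &
                   cur$accession %in% hit, , drop = FALSE]
        if (nrow(cur)) {
            all <- tapply(cur$category, cur$accession,
                          function(z) paste(unique(z), collapse = "+"))
            curatedAll[match(names(all), ids)] <- unname(all)
        }
    }

    # completeness was already reported above; don't warn a second time
    votes <- unname(suppressWarnings(
        countSecretionVotes(bundles, mode = "lenient")))
    tm <- unname(isMembraneByTmhmm(bundles, nTerminalCutoff))
    okGpi <- .GPI_CLASSES[seq_len(match(gpiThreshold, .GPI_CLASSES))]
    gpi <- !is.na(v$sp3Signal) & v$sp3Signal &
        !is.na(v$gpiClass) & v$gpiClass %in% okGpi
    wolf <- .wolfComponent(v$wolfTop)
    targetpM <- !is.na(v$targetpLoc) & v$targetpLoc == "M"
    sp4 <- !is.na(v$sp4Signal) & v$sp4Signal

    category <- rep("UNKNOWN", n)
    tier <- rep(NA_character_, n)
    evidence <- rep("PREDICTED", n)
    gpiOut <- rep(FALSE, n)
    trace <- rep("7:unassigned", n)

    # step 1 — curated annotation decides
    s1 <- !is.na(curatedCat)
    category[s1] <- curatedCat[s1]
    evidence[s1] <- "CURATED"
    tier[s1 & curatedCat == "SECRETED"] <- "CURATED_SECRETED"
    trace[s1] <- paste0("1:curated=", curatedCat[s1],
                        ifelse(grepl("\\+", curatedAll[s1]),
                               paste0("[", curatedAll[s1], "]"), ""))
    done <- s1

    # step 2 — secretion votes minus TM / ER-retention exclusions
    s2 <- !done & votes >= 1 & !tm & !kdel
    tierOf <- c("WEAKLY_LIKELY", "LIKELY", "HIGHLY_LIKELY", "HIGHLY_LIKELY")
    category[s2] <- ifelse(gpi[s2], "GPI_ANCHORED", "SECRETED")
    tier[s2] <- tierOf[votes[s2]]
    gpiOut[s2] <- gpi[s2]
    trace[s2] <- paste0("2:votes=", votes[s2],
                        ifelse(gpi[s2], ",gpi", ""))
    done <- done | s2

    # step 3 — mitochondrial agreement rule
    s3 <- !done & targetpM & !is.na(wolf) & wolf == "mito"
    category[s3] <- ifelse(tm[s3], "MITO_MEMBRANE", "MITO_NONMEMBRANE")
    trace[s3] <- paste0("3:targetp=M+wolf=mito,tm=", as.integer(tm[s3]))
    done <- done | s3

    # step 4 — ER rule (WoLF PSORT or signal peptide + retention motif)
    erWolf <- !is.na(wolf) & wolf == "E.R."
    s4 <- !done & (erWolf | (sp4 & kdel))
    category[s4] <- ifelse(tm[s4], "ER_MEMBRANE", "ER_LUMEN")
    trace[s4] <- paste0("4:", ifelse(erWolf[s4], "wolf=E.R.", "sp4+kdel"),
                        ",tm=", as.integer(tm[s4]))
    done <- done | s4

    # step 5 — remaining WoLF PSORT locations, with membrane splits
    s5 <- !done & !is.na(wolf) & wolf %in% names(.WOLF_LOCATION_MAP)
    base <- .WOLF_LOCATION_MAP[wolf[s5]]
    splitUp <- c(GOLGI_LUMEN = "GOLGI_MEMBRANE",
                 NUCLEAR_NONMEMBRANE = "NUCLEAR_MEMBRANE",
                 VACUOLE_NONMEMBRANE = "VACUOLE_MEMBRANE")
    memv <- tm[s5] & base %in% names(splitUp)
    base[memv] <- splitUp[base[memv]]
    category[s5] <- unname(base)
    trace[s5] <- paste0("5:wolf=", wolf[s5], ",tm=", as.integer(tm[s5]))
    done <- done | s5

    # step 6 — residual transmembrane proteins
    s6 <- !done & tm
    category[s6] <- "OTHER_MEMBRANE"
    trace[s6] <- "6:tm"
    done <- done | s6

    data.frame(proteinId = ids, category = category, tier = tier,
               evidence = evidence, votes = votes, gpiAnchored = gpiOut,
               isMembrane = category %in% .MEMBRANE_CATEGORIES,
               ruleTrace = trace, stringsAsFactors = FALSE)
}

#' Write an assignment table as TSV
#'
#' @param assignments Output of [classifyProteins()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeAssignments <- function(assignments, path) {
    utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(path)
}
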