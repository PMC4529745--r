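# In-code fixture builders shared across the suite.

# Build a PredictionBundleSet from a compact spec: one row per protein,
# any column may be omitted (defaults = all-negative verdicts).
#   id, sp3 (lgl), sp4 (lgl), phob (lgl), targetp ("S"/"M"/"OTHER"),
#   wolf (label), tmStart (NA = no helix, numeric = one helix of 23 aa),
#   frag (FragAnchor class string)
makeBundles <- function(spec) {
    n <- nrow(spec)
    def <- list(sp3 = FALSE, sp4 = FALSE, phob = FALSE,
                targetp = "OTHER", wolf = "cyto", tmStart = NA_real_,
                frag = "NONE")
    for (nm in names(def))
        if (is.null(spec[[nm]])) spec[[nm]] <- rep(def[[nm]], n)
    mk <- function(tool, df) structure(df, tool = tool)
    helices <- lapply(spec$tmStart, function(s) {
        if (is.na(s)) {
            h <- matrix(integer(0), ncol = 2)
        } else h <- cbind(as.integer(s), as.integer(s) + 22L)
        colnames(h) <- c("start", "end")
        h
    })
    tm <- data.frame(proteinId = spec$id,
                     predHel = vapply(helices, nrow, integer(1)),
                     stringsAsFactors = FALSE)
    tm$helices <- helices
    assembleBundles(list(
        mk("SIGNALP3", data.frame(proteinId = spec$id, signal = spec$sp3,
                                  cleavage = ifelse(spec$sp3, 22L,
                                                    NA_integer_))),
        mk("SIGNALP4", data.frame(proteinId = spec$id, signal = spec$sp4,
                                  cleavage = ifelse(spec$sp4, 22L,
                                                    NA_integer_))),
        mk("TARGETP", data.frame(proteinId = spec$id, loc = spec$targetp)),
        mk("PHOBIUS", data.frame(proteinId = spec$id, signal = spec$phob,
                                 tmCount = 0L)),
        mk("WOLFPSORT", data.frame(proteinId = spec$id,
                                   topLabel = spec$wolf,
                                   scores = paste(spec$wolf, 25))),
        mk("TMHMM", tm),
        mk("FRAGANCHOR", data.frame(proteinId = spec$id,
                                    gpiClass = spec$frag))),
        ids = spec$id)
}

# one UniProt flat-text record as a string
upRecord <- function(acc, seq, locs = character(0), reviewed = TRUE,
                     fragment = FALSE, species = "Homo sapiens",
                     taxid = 9606, entry = paste0(acc, "_TST")) {
    cc <- if (length(locs))
        paste0("CC   -!- SUBCELLULAR LOCATION: ",
               paste0(locs, collapse = ". "), ".")
    else NULL
    de <- if (fragment) "DE   Flags: Fragment;" else NULL
    paste(c(
        sprintf("ID   %s   %s;   %d AA.", entry,
                if (reviewed) "Reviewed" else "Unreviewed", nchar(seq)),
        sprintf("AC   %s;", acc),
        de,
        sprintf("OS   %s.", species),
        sprintf("OX   NCBI_TaxID=%d;", taxid),
        cc,
        sprintf("SQ   SEQUENCE   %d AA;", nchar(seq)),
        paste0("     ", seq),
        "//"), collapse = "\n")
}

# full seven-file parse of a simulateProteome() output directory
parseSimulated <- function(paths) {
    list(parseSignalp(paths["signalp3"], 3),
         parseSignalp(paths["signalp4"], 4),
         parseTargetp(paths["targetp"]),
         parsePhobius(paths["phobius"]),
         parseWolfpsort(paths["wolfpsort"]),
         parseTmhmm(paths["tmhmm"]),
         parseFraganchor(paths["fraganchor"]))
}
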