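## Parsers for the native short/batch output formats of the seven
## external predictors. Each parser returns a data.frame with a "tool"
## attribute; assembleBundles() merges any set of them into a
## PredictionBundleSet. Parsers never invent defaults: a protein absent
## from a tool's file simply has no verdict for that tool.

.dataLines <- function(x, what) {
    lines <- .readLinesFlexible(x)
    if (!length(lines)) stop("empty ", what, " input", call. = FALSE)
    keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
    structure(lines[keep], lineno = which(keep))
}

.lineError <- function(what, lines, i, msg) {
    stop(what, ": malformed line ", attr(lines, "lineno")[i], " (", msg, ")",
         call. = FALSE)
}

#' Parse SignalP short-format output (versions 3 and 4)
#'
#' Version 3 corresponds to the SignalP-NN one-line summary (14
#' whitespace-separated fields; decision is the final `?` flag, cleavage
#' from the Ymax position). Version 4 is the standard 12-field summary
#' (decision in the `?` column, cleavage from the Cmax position). The
#' stored cleavage site is the last residue of the signal peptide, so a
#' site printed as "between 22 and 23" is stored as 22.
#'
#' @param x Path, connection or literal text.
#' @param version 3 or 4.
#' @return data.frame (`proteinId`, `signal`, `cleavage`) with attribute
#'   `tool` set to `"SIGNALP3"` or `"SIGNALP4"`.
#' @export
parseSignalp <- function(x, version) {
    version <- as.integer(version)
    stopifnot(version %in% c(3L, 4L))
    what <- paste0("SignalP", version)
    lines <- .dataLines(x, what)
    nfield <- if (version == 3L) 14L else 12L
    other <- if (version == 3L) 12L else 14L
    toks <- strsplit(trimws(lines), "\\s+")
    nf <- lengths(toks)
    if (any(nf == other))
        warning(what, ": line ", attr(lines, "lineno")[which(nf == other)[1]],
                " has ", other, " fields; does the file come from the ",
                "other SignalP version?", call. = FALSE)
    if (any(nf != nfield)) {
        i <- which(nf != nfield)[1]
        .lineError(what, lines, i,
                   paste0("expected ", nfield, " fields, got ", nf[i]))
    }
    if (!length(toks))
        return(structure(data.frame(proteinId = character(),
                                    signal = logical(),
                                    cleavage = integer(),
                                    stringsAsFactors = FALSE),
                         tool = paste0("SIGNALP", version)))
    m <- matrix(unlist(toks), ncol = nfield, byrow = TRUE)
    flag <- if (version == 3L) m[, 14] else m[, 10]
    ypos <- suppressWarnings(
        as.integer(if (version == 3L) m[, 6] else m[, 3]))
    if (any(!flag %in% c("Y", "N")))
        .lineError(what, lines, which(!flag %in% c("Y", "N"))[1],
                   paste0("decision flag '",
                          flag[!flag %in% c("Y", "N")][1], "'"))
    if (anyNA(ypos))
        .lineError(what, lines, which(is.na(ypos))[1],
                   "non-integer position")
    out <- data.frame(proteinId = m[, 1], signal = flag == "Y",
                      cleavage = ypos - 1L, stringsAsFactors = FALSE)
    out$cleavage[!out$signal] <- NA_integer_
    structure(out, tool = paste0("SIGNALP", version))
}

#' Parse TargetP short-format output
#'
#' Non-plant networks: columns Name, Len, mTP, SP, other, Loc, RC. The
#' Loc symbol `S` marks the secretory pathway, `M` mitochondrion and `_`
#' any other location.
#'
#' @inheritParams parseSignalp
#' @return data.frame (`proteinId`, `loc` in `S`/`M`/`OTHER`), attribute
#'   `tool = "TARGETP"`.
#' @export
parseTargetp <- function(x) {
    lines <- .dataLines(x, "TargetP")
    keep <- !grepl("^-+$|^Name\\s|^cutoff", trimws(lines))
    lineno <- attr(lines, "lineno")[keep]
    lines <- structure(lines[keep], lineno = lineno)
    toks <- strsplit(trimws(lines), "\\s+")
    nf <- lengths(toks)
    if (any(nf < 7))
        .lineError("TargetP", lines, which(nf < 7)[1], "expected 7 fields")
    if (!length(toks))
        return(structure(data.frame(proteinId = character(),
                                    loc = character(),
                                    stringsAsFactors = FALSE),
                         tool = "TARGETP"))
    ids <- vapply(toks, `[`, character(1), 1)
    sym <- vapply(toks, `[`, character(1), 6)
    loc <- c(S = "S", M = "M", "_" = "OTHER")[sym]
    if (anyNA(loc))
        stop("TargetP: unknown Loc symbol '", sym[is.na(loc)][1],
             "' at line ", attr(lines, "lineno")[which(is.na(loc))[1]],
             call. = FALSE)
    structure(data.frame(proteinId = ids, loc = unname(loc),
                         stringsAsFactors = FALSE), tool = "TARGETP")
}

#' Parse Phobius short-format output
#'
#' Columns: sequence id, TM segment count, SP flag (`Y`/`0`), topology
#' string. Only the signal-peptide flag feeds the secretion vote; the
#' membrane call of the cascade comes from TMHMM.
#'
#' @inheritParams parseSignalp
#' @return data.frame (`proteinId`, `signal`, `tmCount`), attribute
#'   `tool = "PHOBIUS"`.
#' @export
parsePhobius <- function(x) {
    lines <- .dataLines(x, "Phobius")
    keep <- !grepl("^SEQ[UE]*NCE", trimws(lines))   # header (typo'd in v1.01)
    lineno <- attr(lines, "lineno")[keep]
    lines <- structure(lines[keep], lineno = lineno)
    toks <- strsplit(trimws(lines), "\\s+")
    nf <- lengths(toks)
    if (any(nf < 3))
        .lineError("Phobius", lines, which(nf < 3)[1],
                   "expected >= 3 fields")
    if (!length(toks))
        return(structure(data.frame(proteinId = character(),
                                    signal = logical(),
                                    tmCount = integer(),
                                    stringsAsFactors = FALSE),
                         tool = "PHOBIUS"))
    sp <- vapply(toks, `[`, character(1), 3)
    if (any(!sp %in% c("Y", "0")))
        .lineError("Phobius", lines, which(!sp %in% c("Y", "0"))[1],
                   paste0("SP flag '", sp[!sp %in% c("Y", "0")][1], "'"))
    tm <- suppressWarnings(as.integer(vapply(toks, `[`, character(1), 2)))
    if (anyNA(tm))
        .lineError("Phobius", lines, which(is.na(tm))[1],
                   "non-integer TM count")
    structure(data.frame(proteinId = vapply(toks, `[`, character(1), 1),
                         signal = sp == "Y", tmCount = tm,
                         stringsAsFactors = FALSE), tool = "PHOBIUS")
}

#' Parse WoLF PSORT output
#'
#' One line per protein: the id followed by comma-separated
#' `label score` pairs, best first. Dual labels (`extr_plas`) are kept
#' verbatim; the cascade later uses the first `_`-component.
#'
#' @inheritParams parseSignalp
#' @param resort Re-sort score pairs by decreasing score instead of
#'   erroring when they are out of order.
#' @return data.frame (`proteinId`, `topLabel`, `scores` as the verbatim
#'   pair string), attribute `tool = "WOLFPSORT"`.
#' @export
parseWolfpsort <- function(x, resort = FALSE) {
    lines <- .dataLines(x, "WoLF PSORT")
    ln <- trimws(lines)
    ids <- .idToken(ln)
    rest <- trimws(sub("^\\S+\\s*", "", ln))
    pairsList <- strsplit(rest, ",")
    rows <- lapply(seq_along(ln), function(i) {
        pairs <- trimws(pairsList[[i]])
        pairs <- pairs[nzchar(pairs)]
        if (!length(pairs))
            stop("WoLF PSORT: empty score list for '", ids[i],
                 "' at line ", attr(lines, "lineno")[i], call. = FALSE)
        lab <- sub("[:[:space:]].*$", "", pairs)
        val <- suppressWarnings(as.numeric(sub("^\\S+[:[:space:]]+", "",
                                               pairs)))
        if (anyNA(val))
            .lineError("WoLF PSORT", lines, i, "non-numeric score")
        if (is.unsorted(rev(val), strictly = FALSE)) {
            if (!resort)
                stop("WoLF PSORT: scores not in decreasing order for '",
                     ids[i], "' at line ", attr(lines, "lineno")[i],
                     "; pass resort = TRUE to re-sort", call. = FALSE)
            o <- order(val, decreasing = TRUE)
            lab <- lab[o]; val <- val[o]
        }
        c(lab[1], paste(lab, val, sep = " ", collapse = ", "))
    })
    if (!length(rows))
        return(structure(data.frame(proteinId = character(),
                                    topLabel = character(),
                                    scores = character(),
                                    stringsAsFactors = FALSE),
                         tool = "WOLFPSORT"))
    m <- matrix(unlist(rows), ncol = 2, byrow = TRUE)
    structure(data.frame(proteinId = ids, topLabel = m[, 1],
                         scores = m[, 2], stringsAsFactors = FALSE),
              tool = "WOLFPSORT")
}

#' Parse TMHMM 2 short-format output
#'
#' One line per protein with `key=value` fields; transmembrane helices
#' are taken from the `Topology=` string as 1-based inclusive residue
#' intervals and cross-checked against `PredHel=`.
#'
#' @inheritParams parseSignalp
#' @return data.frame (`proteinId`, `predHel`, list column `helices` of
#'   two-column start/end matrices), attribute `tool = "TMHMM"`.
#' @export
parseTmhmm <- function(x) {
    lines <- .dataLines(x, "TMHMM")
    ln <- trimws(lines)
    ids <- .idToken(ln)
    hasPh <- grepl("PredHel=", ln, fixed = TRUE)
    hasTo <- grepl("Topology=", ln, fixed = TRUE)
    if (any(!hasPh | !hasTo))
        .lineError("TMHMM", lines, which(!hasPh | !hasTo)[1],
                   "missing PredHel= or Topology=")
    nh <- as.integer(sub(".*PredHel=([0-9]+).*", "\\1", ln))
    ts <- sub(".*Topology=(\\S+).*", "\\1", ln)
    segMatches <- gregexpr("([0-9]+)-([0-9]+)", ts)
    allSegs <- regmatches(ts, segMatches)
    helices <- lapply(seq_along(ln), function(i) {
        segs <- allSegs[[i]]
        h <- if (length(segs) && segMatches[[i]][1] != -1) {
            t(vapply(strsplit(segs, "-"),
                     function(p) as.integer(p), integer(2)))
        } else matrix(integer(0), ncol = 2)
        colnames(h) <- c("start", "end")
        if (nrow(h) != nh[i])
            stop("TMHMM: PredHel=", nh[i], " but ", nrow(h),
                 " helices parsed for '", ids[i], "' at line ",
                 attr(lines, "lineno")[i], call. = FALSE)
        if (nrow(h) && any(h[, 1] > h[, 2]))
            .lineError("TMHMM", lines, i, "helix start > end")
        h
    })
    out <- data.frame(proteinId = ids, predHel = nh,
                      stringsAsFactors = FALSE)
    out$helices <- helices
    structure(out, tool = "TMHMM")
}

.FRAG_CLASS_MAP <- c("highly probable" = "HIGHLY_PROBABLE",
                     "probable" = "PROBABLE",
                     "weakly probable" = "WEAKLY_PROBABLE",
                     "potential false positive" = "NONE",
                     "not gpi-anchored" = "NONE")

#' Parse FragAnchor output
#'
#' Two-column (id, qualitative class) table; the class strings are the
#' web server's "Highly probable" ... "Potential false positive".
#'
#' @inheritParams parseSignalp
#' @return data.frame (`proteinId`, `gpiClass`), attribute
#'   `tool = "FRAGANCHOR"`.
#' @export
parseFraganchor <- function(x) {
    lines <- .dataLines(x, "FragAnchor")
    toks <- strsplit(trimws(lines), "\t")
    nf <- lengths(toks)
    if (any(nf < 2))
        .lineError("FragAnchor", lines, which(nf < 2)[1],
                   "expected 2 tab fields")
    if (!length(toks))
        return(structure(data.frame(proteinId = character(),
                                    gpiClass = character(),
                                    stringsAsFactors = FALSE),
                         tool = "FRAGANCHOR"))
    raw <- vapply(toks, `[`, character(1), 2)
    cls <- .FRAG_CLASS_MAP[tolower(trimws(raw))]
    if (anyNA(cls))
        stop("FragAnchor: unknown class '", raw[is.na(cls)][1],
             "' at line ", attr(lines, "lineno")[which(is.na(cls))[1]],
             call. = FALSE)
    structure(data.frame(proteinId = vapply(toks, `[`, character(1), 1),
                         gpiClass = unname(cls),
                         stringsAsFactors = FALSE), tool = "FRAGANCHOR")
}

.TOOL_HAS <- c(SIGNALP3 = "hasSignalp3", SIGNALP4 = "hasSignalp4",
               TARGETP = "hasTargetp", PHOBIUS = "hasPhobius",
               WOLFPSORT = "hasWolfpsort", TMHMM = "hasTmhmm",
               FRAGANCHOR = "hasFraganchor")

#' Assemble per-tool verdicts into a PredictionBundleSet
#'
#' @param verdictList List of parser outputs (each carrying a `tool`
#'   attribute), in any order; at most one table per tool.
#' @param ids Optional character vector fixing the protein universe (e.g.
#'   the FASTA accessions); defaults to the union of ids seen.
#' @return A [PredictionBundleSet-class]. Ids covered by some tools but
#'   not others are available through `attr(verdicts(x), "missing")`.
#' @export
assembleBundles <- function(verdictList, ids = NULL) {
    tools <- vapply(verdictList, function(v) attr(v, "tool"), character(1))
    if (anyDuplicated(tools))
        stop("more than one verdict table for: ",
             paste(unique(tools[duplicated(tools)]), collapse = ", "))
    if (!all(tools %in% predictorTools()))
        stop("unknown tool tag: ",
             paste(setdiff(tools, predictorTools()), collapse = ", "))
    names(verdictList) <- tools
    seen <- unique(unlist(lapply(verdictList, `[[`, "proteinId")))
    if (is.null(ids)) ids <- seen else ids <- as.character(ids)
    n <- length(ids)

    v <- data.frame(proteinId = ids, stringsAsFactors = FALSE)
    if (!n) {
        # zero-protein edge: build the typed empty frame explicitly
        v <- data.frame(proteinId = character(0), sp3Signal = logical(0),
                        sp3Cleavage = integer(0), sp4Signal = logical(0),
                        sp4Cleavage = integer(0),
                        phobiusSignal = logical(0), phobiusTm = integer(0),
                        targetpLoc = character(0), wolfTop = character(0),
                        wolfScores = character(0), tmPredHel = integer(0),
                        gpiClass = character(0), stringsAsFactors = FALSE)
        v$tmHelices <- list()
        for (h in .TOOL_HAS) v[[h]] <- logical(0)
        v$complete <- logical(0)
        v <- v[, .BUNDLE_COLS]
        attr(v, "missing") <- lapply(stats::setNames(nm = names(.TOOL_HAS)),
                                     function(tool) character(0))
        return(methods::new("PredictionBundleSet", verdicts = v))
    }
    v$sp3Signal <- v$sp4Signal <- v$phobiusSignal <- rep(NA, n)
    v$sp3Cleavage <- v$sp4Cleavage <- v$phobiusTm <- rep(NA_integer_, n)
    v$targetpLoc <- v$wolfTop <- v$wolfScores <- v$gpiClass <-
        rep(NA_character_, n)
    v$tmHelices <- rep(list(NULL), n)
    v$tmPredHel <- rep(NA_integer_, n)
    for (h in .TOOL_HAS) v[[h]] <- rep(FALSE, n)

    put <- function(tool, assign) {
        tab <- verdictList[[tool]]
        if (is.null(tab)) return()
        idx <- match(tab$proteinId, ids)
        ok <- !is.na(idx)
        v[[.TOOL_HAS[tool]]][idx[ok]] <<- TRUE
        assign(tab[ok, , drop = FALSE], idx[ok])
    }
    put("SIGNALP3", function(tab, i) {
        v$sp3Signal[i] <<- tab$signal; v$sp3Cleavage[i] <<- tab$cleavage })
    put("SIGNALP4", function(tab, i) {
        v$sp4Signal[i] <<- tab$signal; v$sp4Cleavage[i] <<- tab$cleavage })
    put("TARGETP", function(tab, i) v$targetpLoc[i] <<- tab$loc)
    put("PHOBIUS", function(tab, i) {
        v$phobiusSignal[i] <<- tab$signal; v$phobiusTm[i] <<- tab$tmCount })
    put("WOLFPSORT", function(tab, i) {
        v$wolfTop[i] <<- tab$topLabel; v$wolfScores[i] <<- tab$scores })
    put("TMHMM", function(tab, i) {
        v$tmHelices[i] <<- tab$helices; v$tmPredHel[i] <<- tab$predHel })
    put("FRAGANCHOR", function(tab, i) v$gpiClass[i] <<- tab$gpiClass)

    has <- as.matrix(v[, .TOOL_HAS])
    v$complete <- rowSums(has) == 7L
    missing <- lapply(stats::setNames(nm = names(.TOOL_HAS)), function(tool)
        if (tool %in% tools) ids[!v[[.TOOL_HAS[tool]]]] else ids)
    attr(v, "missing") <- missing
    methods::new("PredictionBundleSet", verdicts = v)
}

.serializeHelices <- function(h) {
    if (is.null(h) || !nrow(h)) return("")
    paste(h[, 1], h[, 2], sep = "-", collapse = ",")
}

.deserializeHelices <- function(s) {
    if (!nzchar(s)) {
        h <- matrix(integer(0), ncol = 2)
    } else {
        parts <- strsplit(strsplit(s, ",")[[1]], "-")
        h <- t(vapply(parts, function(p) as.integer(p), integer(2)))
    }
    colnames(h) <- c("start", "end")
    h
}

#' Write / read the canonical long verdict table
#'
#' Lossless TSV serialisation of a [PredictionBundleSet-class] as
#' `protein_id`, `tool`, `field`, `value` rows: re-reading reproduces the
#' bundle set exactly.
#'
#' @param x A [PredictionBundleSet-class].
#' @param path Output TSV path (for [readVerdictTable()]: input path,
#'   connection or literal text).
#' @return `path` invisibly; [readVerdictTable()] returns the
#'   reconstructed [PredictionBundleSet-class].
#' @export
writeVerdictTable <- function(x, path) {
    stopifnot(methods::is(x, "PredictionBundleSet"))
    v <- x@verdicts
    rows <- list()
    add <- function(keep, tool, field, value)
        rows[[length(rows) + 1L]] <<- data.frame(
            protein_id = v$proteinId[keep], tool = tool, field = field,
            value = as.character(value[keep]), stringsAsFactors = FALSE)
    add(v$hasSignalp3, "SIGNALP3", "signal", v$sp3Signal)
    add(v$hasSignalp3 & !is.na(v$sp3Cleavage), "SIGNALP3", "cleavage",
        v$sp3Cleavage)
    add(v$hasSignalp4, "SIGNALP4", "signal", v$sp4Signal)
    add(v$hasSignalp4 & !is.na(v$sp4Cleavage), "SIGNALP4", "cleavage",
        v$sp4Cleavage)
    add(v$hasTargetp, "TARGETP", "loc", v$targetpLoc)
    add(v$hasPhobius, "PHOBIUS", "signal", v$phobiusSignal)
    add(v$hasPhobius, "PHOBIUS", "tm_count", v$phobiusTm)
    add(v$hasWolfpsort, "WOLFPSORT", "top_label", v$wolfTop)
    add(v$hasWolfpsort, "WOLFPSORT", "scores", v$wolfScores)
    add(v$hasTmhmm, "TMHMM", "pred_hel", v$tmPredHel)
    add(v$hasTmhmm, "TMHMM", "helices",
        vapply(v$tmHelices, .serializeHelices, character(1)))
    add(v$hasFraganchor, "FRAGANCHOR", "gpi_class", v$gpiClass)
    long <- do.call(rbind, rows)
    long <- long[order(match(long$protein_id, v$proteinId),
                       match(long$tool, predictorTools()), long$field), ]
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeVerdictTable
#' @export
readVerdictTable <- function(path) {
    long <- utils::read.delim(text = paste(.readLinesFlexible(path),
                                           collapse = "\n"),
                              stringsAsFactors = FALSE,
                              colClasses = "character")
    stopifnot(all(c("protein_id", "tool", "field", "value") %in% names(long)))
    ids <- unique(long$protein_id)
    get <- function(tool, field) {
        sel <- long$tool == tool & long$field == field
        stats::setNames(long$value[sel], long$protein_id[sel])
    }
    mk <- function(tool, build) {
        sel <- long$tool == tool
        if (!any(sel)) return(NULL)
        tids <- unique(long$protein_id[sel])
        structure(build(tids), tool = tool)
    }
    vl <- list(
        mk("SIGNALP3", function(tids) {
            cl <- get("SIGNALP3", "cleavage")
            data.frame(proteinId = tids,
                       signal = get("SIGNALP3", "signal")[tids] == "TRUE",
                       cleavage = as.integer(cl[tids]),
                       stringsAsFactors = FALSE)
        }),
        mk("SIGNALP4", function(tids) {
            cl <- get("SIGNALP4", "cleavage")
            data.frame(proteinId = tids,
                       signal = get("SIGNALP4", "signal")[tids] == "TRUE",
                       cleavage = as.integer(cl[tids]),
                       stringsAsFactors = FALSE)
        }),
        mk("TARGETP", function(tids)
            data.frame(proteinId = tids,
                       loc = unname(get("TARGETP", "loc")[tids]),
                       stringsAsFactors = FALSE)),
        mk("PHOBIUS", function(tids)
            data.frame(proteinId = tids,
                       signal = get("PHOBIUS", "signal")[tids] == "TRUE",
                       tmCount = as.integer(get("PHOBIUS", "tm_count")[tids]),
                       stringsAsFactors = FALSE)),
        mk("WOLFPSORT", function(tids) {
            sc <- get("WOLFPSORT", "scores")
            data.frame(proteinId = tids,
                       topLabel = unname(get("WOLFPSORT", "top_label")[tids]),
                       scores = unname(sc[tids]), stringsAsFactors = FALSE)
        }),
        mk("TMHMM", function(tids) {
            hx <- get("TMHMM", "helices")
            out <- data.frame(proteinId = tids,
                              predHel = as.integer(get("TMHMM",
                                                       "pred_hel")[tids]),
                              stringsAsFactors = FALSE)
            out$helices <- lapply(unname(hx[tids]), .deserializeHelices)
            out
        }),
        mk("FRAGANCHOR", function(tids)
            data.frame(proteinId = tids,
                       gpiClass = unname(get("FRAGANCHOR",
                                             "gpi_class")[tids]),
                       stringsAsFactors = FALSE)))
    assembleBundles(Filter(Negate(is.null), vl), ids = ids)
}
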