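#' Parse UniProtKB flat text records
#'
#' Reads the Swiss-Prot/TrEMBL flat-file dialect (ID/AC/DE/OS/OX/CC/SQ
#' lines, `//` terminators). Curated subcellular locations are taken from
#' the `CC   -!- SUBCELLULAR LOCATION:` comment block only; FT feature
#' lines and isoform-specific locations are ignored. The review status
#' comes from the ID-line status token and the fragment flag from the DE
#' `Flags: Fragment` line.
#'
#' @param x Path to a flat file, a connection, or literal text.
#' @param vocabulary Term-to-category table ([locationVocabulary()]).
#' @return A [ProteinSet-class] with curated locations attached.
#' @examples
#' txt <- paste(
#'   "ID   TST1_HUMAN  Reviewed;  5 AA.",
#'   "AC   P00001;",
#'   "OS   Homo sapiens.",
#'   "OX   NCBI_TaxID=9606;",
#'   "CC   -!- SUBCELLULAR LOCATION: Secreted.",
#'   "SQ   SEQUENCE  5 AA;",
#'   "     MKDEL", "//", sep = "\n")
#' curatedLocations(parseUniprotFlat(I(txt)))
#' @export
parseUniprotFlat <- function(x, vocabulary = locationVocabulary()) {
    lines <- .stopIfEmpty(.readLinesFlexible(x), "UniProt flat")
    ends <- grep("^//\\s*$", lines)
    if (!length(ends))
        stop("no record terminator '//' found (line ", length(lines), ")",
             call. = FALSE)
    if (max(ends) != length(lines) &&
        any(nzchar(trimws(lines[(max(ends) + 1L):length(lines)]))))
        stop("record missing terminator '//' at line ", length(lines),
             call. = FALSE)
    starts <- c(1L, ends[-length(ends)] + 1L)

    recs <- lapply(seq_along(ends), function(i) {
        .parseUniprotRecord(lines[starts[i]:(ends[i] - 1L)], starts[i])
    })
    seqs <- vapply(recs, `[[`, character(1), "sequence")
    names(seqs) <- vapply(recs, `[[`, character(1), "accession")
    info <- data.frame(
        accession = names(seqs),
        entryName = vapply(recs, `[[`, character(1), "entryName"),
        reviewed = vapply(recs, `[[`, logical(1), "reviewed"),
        isFragment = vapply(recs, `[[`, logical(1), "isFragment"),
        speciesName = vapply(recs, `[[`, character(1), "speciesName"),
        taxonId = vapply(recs, `[[`, integer(1), "taxonId"),
        stringsAsFactors = FALSE)
    curated <- do.call(rbind, c(lapply(recs, `[[`, "curated"),
                                list(make.row.names = FALSE)))
    if (is.null(curated))
        curated <- data.frame(accession = character(),
                              rawTerm = character(),
                              category = character(),
                              qualifier = character(),
                              stringsAsFactors = FALSE)
    curated$category <- mapCuratedTerm(curated$rawTerm, vocabulary)
    ProteinSet(seqs, info = info, curated = curated)
}

# one ID..SQ record (terminator already stripped); offset = 1-based line
# number of the record's first line, for error messages
.parseUniprotRecord <- function(lines, offset) {
    sqAt <- grep("^SQ   ", lines)
    # tag scanning stops at SQ: wrapped sequence lines may start with
    # letters that look like a line tag (e.g. "CC")
    header <- if (length(sqAt)) lines[seq_len(sqAt[1])] else lines
    tag <- substr(header, 1L, 2L)
    body <- trimws(substr(header, 6L, nchar(header)))

    idl <- which(tag == "ID")
    if (!length(idl))
        stop("record at line ", offset, " lacks an ID line", call. = FALSE)
    idtok <- strsplit(body[idl[1]], "\\s+")[[1]]
    entryName <- idtok[1]
    reviewed <- grepl("^Reviewed", idtok[2])

    acl <- which(tag == "AC")
    if (!length(acl))
        stop("record at line ", offset, " lacks an AC line", call. = FALSE)
    accession <- sub(";.*$", "", body[acl[1]])

    isFragment <- any(tag == "DE" & grepl("Flags:.*Fragment", body))

    osl <- which(tag == "OS")
    speciesName <- if (length(osl))
        sub("\\s*\\(.*$", "", sub("\\.\\s*$", "", paste(body[osl], collapse = " ")))
    else NA_character_
    oxl <- which(tag == "OX")
    taxonId <- if (length(oxl)) {
        m <- regmatches(body[oxl[1]],
                        regexpr("NCBI_TaxID=\\s*([0-9]+)", body[oxl[1]]))
        as.integer(sub("NCBI_TaxID=\\s*", "", m))
    } else NA_integer_
    if (!length(taxonId)) taxonId <- NA_integer_

    if (!length(sqAt) || sqAt[1] == length(lines))
        stop("record '", accession, "' at line ", offset,
             " lacks an SQ block", call. = FALSE)
    seqLines <- lines[(sqAt[1] + 1L):length(lines)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
    if (!nzchar(sequence))
        stop("record '", accession, "' at line ", offset,
             " has an empty sequence", call. = FALSE)

    curated <- .extractSubcellularTerms(tag, body)
    curated$accession <- rep(accession, nrow(curated))
    curated <- curated[, c("accession", "rawTerm", "qualifier")]
    curated$category <- rep(NA_character_, nrow(curated)) # mapped by caller

    list(accession = accession, entryName = entryName, reviewed = reviewed,
         isFragment = isFragment, speciesName = speciesName,
         taxonId = taxonId, sequence = sequence, curated = curated)
}

# pull location tokens out of the CC SUBCELLULAR LOCATION comment; a
# qualifier phrase attached to a token ("Probable", "By similarity",
# "Potential", in parentheses or evidence braces) is recorded with it
.extractSubcellularTerms <- function(tag, body) {
    empty <- data.frame(rawTerm = character(), qualifier = character(),
                        stringsAsFactors = FALSE)
    cc <- which(tag == "CC")
    if (!length(cc)) return(empty)
    txt <- body[cc]
    starts <- grep("^-!- SUBCELLULAR LOCATION:", txt)
    if (!length(starts)) return(empty)
    blockEnds <- c(grep("^-!-", txt), length(txt) + 1L)
    out <- lapply(starts, function(s) {
        e <- min(blockEnds[blockEnds > s], length(txt) + 1L) - 1L
        paste(txt[s:e], collapse = " ")
    })
    comment <- paste(unlist(out), collapse = " ")
    comment <- sub("^-!- SUBCELLULAR LOCATION:\\s*", "", comment)
    comment <- sub("Note=.*$", "", comment)          # free-text note
    tokens <- strsplit(comment, "[.;]")[[1]]
    tokens <- trimws(tokens)
    tokens <- tokens[nzchar(tokens)]
    if (!length(tokens)) return(empty)
    qual <- vapply(tokens, function(tk) {
        if (grepl("by similarity", tk, ignore.case = TRUE)) "BY_SIMILARITY"
        else if (grepl("probable", tk, ignore.case = TRUE)) "PROBABLE"
        else if (grepl("potential", tk, ignore.case = TRUE)) "POTENTIAL"
        else "NONE"
    }, character(1), USE.NAMES = FALSE)
    raw <- gsub("\\{[^}]*\\}|\\([^)]*\\)", "", tokens)   # strip evidence
    raw <- trimws(gsub("\\s+", " ", raw))
    keep <- nzchar(raw)
    data.frame(rawTerm = raw[keep], qualifier = qual[keep],
               stringsAsFactors = FALSE)
}
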