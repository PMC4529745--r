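#' Read protein sequences from FASTA
#'
#' Sequences are uppercased and a single trailing stop (`*`) is stripped.
#' The accession is the first whitespace-delimited token of the header.
#'
#' @param x Path to a FASTA file, a connection, or literal FASTA text
#'   (a string containing newlines, or a character vector of lines).
#' @return A [ProteinSet-class] (sequence fields only).
#' @examples
#' readProteinFasta(I(">P1 test\nMKDEL"))
#' @export
readProteinFasta <- function(x) {
    lines <- .stopIfEmpty(.readLinesFlexible(x), "FASTA")
    hdr <- grep("^>", lines)
    if (!length(hdr)) stop("no FASTA headers found", call. = FALSE)
    acc <- .idToken(sub("^>", "", lines[hdr]))
    if (anyDuplicated(acc))
        stop("duplicate accession in FASTA: ",
             paste(unique(acc[duplicated(acc)]), collapse = ", "),
             call. = FALSE)
    to <- c(hdr[-1] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(i) {
        if (hdr[i] + 1L > to[i]) return("")
        paste(lines[(hdr[i] + 1L):to[i]], collapse = "")
    }, character(1))
    seqs <- toupper(gsub("[ \t]", "", seqs))
    seqs <- sub("\\*$", "", seqs)
    if (any(!nzchar(seqs)))
        stop("zero-length sequence for: ",
             paste(acc[!nzchar(seqs)], collapse = ", "), call. = FALSE)
    names(seqs) <- acc
    ProteinSet(seqs)
}

#' Write a ProteinSet to FASTA
#'
#' @param x A [ProteinSet-class].
#' @param path Output file path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(x, path, width = 60L) {
    stopifnot(methods::is(x, "ProteinSet"))
    Biostrings::writeXStringSet(x@sequences, filepath = path, width = width)
    invisible(path)
}

#' Map a curated location term to a category
#'
#' Case-insensitive, total and deterministic lookup in the vocabulary
#' table; unrecognised terms map to `"UNMAPPED"` rather than being
#' dropped.
#'
#' @param term Character vector of raw annotation terms.
#' @param vocabulary Mapping table as returned by [locationVocabulary()].
#' @return Character vector of categories (or `"UNMAPPED"`).
#' @examples
#' mapCuratedTerm(c("Extracellular", "Cytosol", "Flagellum"))
#' @export
mapCuratedTerm <- function(term, vocabulary = locationVocabulary()) {
    key <- tolower(trimws(term))
    out <- vocabulary$category[match(key, vocabulary$term)]
    out[is.na(out)] <- "UNMAPPED"
    out
}

#' Effective curated category of each protein
#'
#' Collapses a protein's mapped curated terms to a single category by the
#' fixed precedence list (secreted first; cytoskeleton outranks cytoplasm,
#' because curated cytoskeleton entries are routinely also annotated
#' cytoplasm). Proteins with no mapped term get `NA`.
#'
#' @param x A [ProteinSet-class].
#' @param reviewedOnly Honour curated annotation of reviewed entries only
#'   (default `TRUE`); unreviewed entries then fall through to prediction.
#' @return Named character vector (accession -> category or `NA`).
#' @export
effectiveCuratedCategory <- function(x, reviewedOnly = TRUE) {
    stopifnot(methods::is(x, "ProteinSet"))
    cur <- x@curated
    acc <- accessions(x)
    out <- stats::setNames(rep(NA_character_, length(acc)), acc)
    if (!nrow(cur)) return(out)
    keep <- cur$category %in% locationCategories()
    if (reviewedOnly) {
        rev <- stats::setNames(x@info$reviewed, acc)
        keep <- keep & rev[cur$accession]
    }
    cur <- cur[keep, , drop = FALSE]
    if (!nrow(cur)) return(out)
    rank <- match(cur$category, .CURATED_PRECEDENCE)
    best <- tapply(rank, cur$accession, min)
    out[names(best)] <- .CURATED_PRECEDENCE[best]
    out
}

#' Read a UniProt identifier-mapping table
#'
#' Three-or-more-column TSV: accession, entry name, then one column per
#' external identifier namespace (RefSeq, gi, ...).
#'
#' @param x Path, connection or literal text.
#' @return data.frame; first two columns renamed `accession`, `entryName`.
#' @export
readIdMapping <- function(x) {
    lines <- .stopIfEmpty(.readLinesFlexible(x), "ID-mapping")
    tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                             header = TRUE, stringsAsFactors = FALSE)
    if (ncol(tab) < 3)
        stop("ID-mapping table needs at least 3 columns", call. = FALSE)
    names(tab)[1:2] <- c("accession", "entryName")
    tab
}

#' Write the per-protein records table as TSV
#'
#' One row per protein with metadata plus the collapsed curated category.
#'
#' @param x A [ProteinSet-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeRecordsTable <- function(x, path) {
    stopifnot(methods::is(x, "ProteinSet"))
    info <- x@info
    info$length <- unname(seqLengths(x))
    info$startsWithMet <- unname(startsWithMet(x))
    info$curatedCategory <- unname(effectiveCuratedCategory(x))
    utils::write.table(info, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
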