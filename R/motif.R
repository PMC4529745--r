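.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Compile a PROSITE pattern
#'
#' Implements the PROSITE syntax subset sufficient for KDEL-class
#' patterns: literal residues, `[...]` allowed classes, `{...}`
#' exclusions, the wildcard `x`, `-` separators and the `>` C-terminal
#' anchor. Repetition ranges and the `<` N-terminal anchor are out of
#' scope and raise an "unsupported construct" error.
#'
#' @param patternText Pattern string, e.g. `"[KRHQSA]-[DENQ]-E-L>"`.
#' @param patternId Identifier stored on the compiled object.
#' @return A [PrositePattern-class].
#' @examples
#' compileProsite("[KRHQSA]-[DENQ]-E-L>")
#' @export
compileProsite <- function(patternText, patternId = "pattern") {
    txt <- gsub("\\s+", "", patternText)
    txt <- sub("\\.$", "", txt)              # PROSITE entries end in '.'
    if (grepl("\\(|\\)|<|\\*", txt))
        stop("unsupported construct in PROSITE pattern '", patternText,
             "' (repetition ranges and N-terminal anchors are not ",
             "implemented)", call. = FALSE)
    anchored <- grepl(">$", txt)
    if (anchored) txt <- sub(">$", "", txt)
    parts <- strsplit(txt, "-", fixed = TRUE)[[1]]
    if (!length(parts) || any(!nzchar(parts)))
        stop("empty PROSITE pattern element in '", patternText, "'",
             call. = FALSE)
    elements <- lapply(parts, function(p) {
        if (p == "x") return(.AA20)
        if (grepl("^\\[[A-Z]+\\]$", p))
            return(strsplit(substr(p, 2, nchar(p) - 1), "")[[1]])
        if (grepl("^\\{[A-Z]+\\}$", p))
            return(setdiff(.AA20,
                           strsplit(substr(p, 2, nchar(p) - 1), "")[[1]]))
        if (grepl("^[A-Z]$", p)) return(p)
        stop("unsupported construct '", p, "' in PROSITE pattern '",
             patternText, "'", call. = FALSE)
    })
    methods::new("PrositePattern", patternId = patternId,
                 elements = elements, anchoredCterm = anchored)
}

#' Load the shipped ER-retention pattern (PS00014)
#'
#' The pattern string lives in a config file under `extdata`, so a
#' PROSITE revision is a data update rather than a code change.
#'
#' @param path Optional alternative config file (`id<TAB>pattern` lines).
#' @return A compiled [PrositePattern-class].
#' @export
erRetentionPattern <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "ps00014.txt", package = "secloc",
                            mustWork = TRUE)
    lines <- .dataLines(path, "pattern config")
    f <- strsplit(trimws(lines[1]), "\t")[[1]]
    if (length(f) != 2) stop("pattern config must be 'id<TAB>pattern'")
    compileProsite(f[2], patternId = f[1])
}

.regexOfPattern <- function(pattern) {
    paste0(vapply(pattern@elements, function(el)
        if (length(el) == 1) el
        else paste0("[", paste(el, collapse = ""), "]"), character(1)),
        collapse = "")
}

#' Scan sequences for a compiled PROSITE pattern
#'
#' For C-terminally anchored patterns only the final *k* residues are
#' tested (*k* = number of pattern elements); otherwise the first
#' matching window is reported. A sequence shorter than the pattern is a
#' non-hit, not an error.
#'
#' @param sequences Character vector (uppercase amino acids),
#'   [Biostrings::AAStringSet] or [ProteinSet-class].
#' @param pattern A [PrositePattern-class]; default the shipped
#'   ER-retention pattern PS00014.
#' @return data.frame: `proteinId`, `hit` (logical), `position` (1-based
#'   start of the match, `NA` when no hit).
#' @examples
#' scanProsite(c(A = "MAASKDEL", B = "MAASKDELG"))
#' @export
scanProsite <- function(sequences, pattern = erRetentionPattern()) {
    stopifnot(methods::is(pattern, "PrositePattern"))
    if (methods::is(sequences, "ProteinSet"))
        sequences <- sequences@sequences
    if (methods::is(sequences, "AAStringSet")) {
        nm <- names(sequences)
        sequences <- as.character(sequences)
        names(sequences) <- nm
    }
    ids <- names(sequences)
    if (is.null(ids)) ids <- as.character(seq_along(sequences))
    rx <- .regexOfPattern(pattern)
    k <- length(pattern@elements)
    n <- nchar(sequences)
    if (pattern@anchoredCterm) {
        hit <- n >= k & grepl(paste0(rx, "$"), sequences)
        pos <- ifelse(hit, n - k + 1L, NA_integer_)
    } else {
        m <- regexpr(rx, sequences)
        hit <- m != -1L
        pos <- ifelse(hit, as.integer(m), NA_integer_)
    }
    data.frame(proteinId = ids, hit = unname(hit), position = unname(pos),
               stringsAsFactors = FALSE)
}

#' Write a motif hit table as TSV
#'
#' @param hits Output of [scanProsite()].
#' @param pattern The pattern scanned (for the `pattern_id` column).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeHitTable <- function(hits, pattern, path) {
    out <- data.frame(protein_id = hits$proteinId,
                      pattern_id = pattern@patternId,
                      position = hits$position)[hits$hit, ]
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
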