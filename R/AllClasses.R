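#' @import methods
#' @importFrom Biostrings AAStringSet writeXStringSet width subseq
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom stats setNames runif
#' @importFrom utils read.delim write.table
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' ProteinSet: sequences plus curated annotation
#'
#' Container for a set of protein records: the amino-acid sequences (a
#' [Biostrings::AAStringSet]), per-protein metadata (review status,
#' fragment flag, species) and curated subcellular-location terms parsed
#' from UniProt flat text.
#'
#' @slot sequences [Biostrings::AAStringSet] named by accession.
#' @slot info data.frame with one row per protein: `accession`,
#'   `entryName`, `reviewed`, `isFragment`, `speciesName`, `taxonId`.
#' @slot curated data.frame of curated location terms: `accession`,
#'   `rawTerm`, `category`, `qualifier` (zero or more rows per protein).
#'
#' @aliases ProteinSet
#' @exportClass ProteinSet
setClass("ProteinSet",
    slots = c(sequences = "AAStringSet", info = "data.frame",
              curated = "data.frame"))

setValidity("ProteinSet", function(object) {
    info <- object@info
    need <- c("accession", "entryName", "reviewed", "isFragment",
              "speciesName", "taxonId")
    if (!all(need %in% names(info)))
        return(paste("info lacks columns:",
                     paste(setdiff(need, names(info)), collapse = ", ")))
    if (length(object@sequences) != nrow(info))
        return("sequences and info disagree on the number of proteins")
    acc <- info$accession
    if (any(!nzchar(acc)) || anyNA(acc)) return("empty accession")
    if (anyDuplicated(acc))
        return(paste("duplicate accession:", acc[duplicated(acc)][1]))
    if (!identical(names(object@sequences), acc))
        return("sequence names do not match info$accession")
    needc <- c("accession", "rawTerm", "category", "qualifier")
    if (!all(needc %in% names(object@curated)))
        return("curated lacks required columns")
    if (!all(object@curated$qualifier %in% .QUALIFIERS))
        return("invalid curated qualifier")
    okcat <- c(locationCategories(), "UNMAPPED")
    if (!all(object@curated$category %in% okcat))
        return("invalid curated category")
    TRUE
})

#' Construct a ProteinSet
#'
#' @param sequences Named character vector or [Biostrings::AAStringSet] of
#'   amino-acid sequences; names are accessions.
#' @param info Optional metadata data.frame (defaults filled in).
#' @param curated Optional curated-location data.frame.
#' @return A [ProteinSet-class] object.
#' @examples
#' ps <- ProteinSet(c(P1 = "MKDEL"))
#' accessions(ps)
#' @export
ProteinSet <- function(sequences, info = NULL, curated = NULL) {
    if (!methods::is(sequences, "AAStringSet"))
        sequences <- Biostrings::AAStringSet(sequences)
    acc <- names(sequences)
    if (is.null(acc)) stop("sequences must be named by accession")
    if (is.null(info))
        info <- data.frame(accession = acc, stringsAsFactors = FALSE)
    defaults <- list(entryName = info$accession, reviewed = FALSE,
                     isFragment = FALSE, speciesName = NA_character_,
                     taxonId = NA_integer_)
    for (nm in names(defaults))
        if (is.null(info[[nm]])) info[[nm]] <- defaults[[nm]]
    if (is.null(curated))
        curated <- data.frame(accession = character(), rawTerm = character(),
                              category = character(), qualifier = character(),
                              stringsAsFactors = FALSE)
    methods::new("ProteinSet", sequences = sequences, info = info,
                 curated = curated)
}

#' PredictionBundleSet: unified per-protein predictor verdicts
#'
#' One row per protein, typed columns carrying exactly the fields the
#' cascade consumes. A tool that produced no verdict for a protein leaves
#' its fields `NA` and its `has*` presence flag `FALSE` — parsers never
#' invent defaults.
#'
#' @slot verdicts data.frame; see [assembleBundles()] for the columns.
#'
#' @aliases PredictionBundleSet
#' @exportClass PredictionBundleSet
setClass("PredictionBundleSet", slots = c(verdicts = "data.frame"))

.BUNDLE_COLS <- c("proteinId",
                  "sp3Signal", "sp3Cleavage", "sp4Signal", "sp4Cleavage",
                  "phobiusSignal", "phobiusTm", "targetpLoc",
                  "wolfTop", "wolfScores", "tmHelices", "tmPredHel",
                  "gpiClass",
                  paste0("has", c("Signalp3", "Signalp4", "Targetp",
                                  "Phobius", "Wolfpsort", "Tmhmm",
                                  "Fraganchor")),
                  "complete")

setValidity("PredictionBundleSet", function(object) {
    v <- object@verdicts
    if (!all(.BUNDLE_COLS %in% names(v)))
        return(paste("verdicts lack columns:",
                     paste(setdiff(.BUNDLE_COLS, names(v)), collapse = ", ")))
    if (anyDuplicated(v$proteinId)) return("duplicate protein id in bundles")
    if (!is.list(v$tmHelices)) return("tmHelices must be a list column")
    has <- as.matrix(v[, grep("^has", names(v))])
    if (!identical(as.logical(v$complete),
                   as.logical(rowSums(has) == 7L)))
        return("complete flag inconsistent with tool presence")
    TRUE
})

#' PrositePattern: a compiled PROSITE pattern
#'
#' Supports the PROSITE syntax subset needed for KDEL-class patterns:
#' literal residues, `[...]` classes, `{...}` exclusions, `x`, `-`
#' separators and the `>` C-terminal anchor.
#'
#' @slot patternId character identifier (e.g. `"PS00014"`).
#' @slot elements list of character vectors, one allowed-residue set per
#'   pattern position.
#' @slot anchoredCterm logical; `TRUE` when the pattern ends in `>`.
#'
#' @aliases PrositePattern
#' @exportClass PrositePattern
setClass("PrositePattern",
    slots = c(patternId = "character", elements = "list",
              anchoredCterm = "logical"))

setValidity("PrositePattern", function(object) {
    if (!length(object@elements)) return("pattern has no elements")
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (el in object@elements) {
        if (!length(el)) return("empty element set")
        if (!all(el %in% aa)) return("element contains a non-amino-acid")
    }
    TRUE
})

#' ConfusionMatrix: 2x2 classification counts
#'
#' @slot tp,fp,tn,fn non-negative integer counts.
#' @aliases ConfusionMatrix
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
    slots = c(tp = "numeric", fp = "numeric", tn = "numeric",
              fn = "numeric"))

setValidity("ConfusionMatrix", function(object) {
    v <- c(object@tp, object@fp, object@tn, object@fn)
    if (length(v) != 4 || anyNA(v)) return("tp/fp/tn/fn must be scalars")
    if (any(v < 0)) return("negative count")
    if (any(v != floor(v))) return("non-integer count")
    TRUE
})

#' Construct a ConfusionMatrix from counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A [ConfusionMatrix-class] object.
#' @examples
#' confusionMatrix(tp = 794, fp = 262, tn = 16742, fn = 1076)
#' @export
confusionMatrix <- function(tp, fp, tn, fn)
    methods::new("ConfusionMatrix", tp = as.numeric(tp), fp = as.numeric(fp),
                 tn = as.numeric(tn), fn = as.numeric(fn))

setMethod("show", "ProteinSet", function(object) {
    cat("ProteinSet with", length(object@sequences), "proteins\n")
    cat("  reviewed:", sum(object@info$reviewed),
        " fragments:", sum(object@info$isFragment), "\n")
    cat("  curated location terms:", nrow(object@curated), "\n")
})

setMethod("show", "PredictionBundleSet", function(object) {
    v <- object@verdicts
    cat("PredictionBundleSet for", nrow(v), "proteins (",
        sum(v$complete), "with all seven tools )\n")
})

setMethod("show", "PrositePattern", function(object) {
    cat("PrositePattern", object@patternId, "—", length(object@elements),
        "elements,", if (object@anchoredCterm) "C-terminal anchored"
        else "unanchored", "\n")
})

setMethod("show", "ConfusionMatrix", function(object) {
    cat(sprintf("ConfusionMatrix  tp=%d fp=%d tn=%d fn=%d\n",
                object@tp, object@fp, object@tn, object@fn))
})

#' @rdname ProteinSet-class
#' @param x,object A `ProteinSet`.
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' @rdname ProteinSet-class
#' @export
setMethod("accessions", "ProteinSet", function(x) x@info$accession)

#' @rdname ProteinSet-class
#' @export
setGeneric("proteinInfo", function(x) standardGeneric("proteinInfo"))

#' @rdname ProteinSet-class
#' @export
setMethod("proteinInfo", "ProteinSet", function(x) x@info)

#' @rdname ProteinSet-class
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname ProteinSet-class
#' @export
setMethod("sequences", "ProteinSet", function(x) x@sequences)

#' @rdname ProteinSet-class
#' @export
setGeneric("curatedLocations", function(x) standardGeneric("curatedLocations"))

#' @rdname ProteinSet-class
#' @export
setMethod("curatedLocations", "ProteinSet", function(x) x@curated)

#' @rdname PredictionBundleSet-class
#' @param x A `PredictionBundleSet`.
#' @export
setGeneric("verdicts", function(x) standardGeneric("verdicts"))

#' @rdname PredictionBundleSet-class
#' @export
setMethod("verdicts", "PredictionBundleSet", function(x) x@verdicts)

#' @rdname ProteinSet-class
#' @export
setMethod("length", "ProteinSet", function(x) length(x@sequences))

#' Does a record start with methionine / sequence lengths
#'
#' Convenience accessors used by the benchmark filters.
#' @param x A [ProteinSet-class].
#' @return Logical / integer vector named by accession.
#' @export
startsWithMet <- function(x) {
    stopifnot(methods::is(x, "ProteinSet"))
    s <- as.character(Biostrings::subseq(x@sequences, 1L, 1L)) == "M"
    names(s) <- accessions(x)
    s
}

#' @rdname startsWithMet
#' @export
seqLengths <- function(x) {
    stopifnot(methods::is(x, "ProteinSet"))
    w <- Biostrings::width(x@sequences)
    names(w) <- accessions(x)
    w
}
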