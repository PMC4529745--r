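#' @details
#' `secloc` implements a consensus protocol for assigning protein
#' subcellular locations in metazoa: curated UniProtKB annotation takes
#' precedence; otherwise a fixed rule cascade combines the verdicts of
#' seven sequence-based predictors (SignalP 3/4, Phobius, TargetP, WoLF
#' PSORT, TMHMM 2, FragAnchor) plus a C-terminal ER-retention motif scan.
#' See `vignette("secloc-methods")` for the model and its assumptions.
#'
#' @keywords internal
"_PACKAGE"

#' Subcellular location categories
#'
#' The closed category vocabulary used throughout the package: sixteen
#' locations (with membrane / non-membrane splits), a GPI-anchored class,
#' and `UNKNOWN` for proteins no rule claims.
#'
#' @return Character vector of category names.
#' @examples
#' locationCategories()
#' @export
locationCategories <- function() {
    c("SECRETED",
      "MITO_MEMBRANE", "MITO_NONMEMBRANE",
      "ER_MEMBRANE", "ER_LUMEN",
      "CYTOPLASM", "CYTOSKELETON",
      "GOLGI_MEMBRANE", "GOLGI_LUMEN",
      "NUCLEAR_MEMBRANE", "NUCLEAR_NONMEMBRANE",
      "VACUOLE_MEMBRANE", "VACUOLE_NONMEMBRANE",
      "LYSOSOME", "PEROXISOME",
      "PLASMA_MEMBRANE", "OTHER_MEMBRANE",
      "GPI_ANCHORED", "UNKNOWN")
}

#' Predictor tools recognised by the package
#'
#' @return Character vector of tool identifiers.
#' @export
predictorTools <- function() {
    c("SIGNALP3", "SIGNALP4", "TARGETP", "PHOBIUS",
      "WOLFPSORT", "TMHMM", "FRAGANCHOR")
}

# membrane-bearing categories: drives the is_membrane flag on assignments
.MEMBRANE_CATEGORIES <- c(
    "MITO_MEMBRANE", "ER_MEMBRANE", "GOLGI_MEMBRANE", "NUCLEAR_MEMBRANE",
    "VACUOLE_MEMBRANE", "PLASMA_MEMBRANE", "OTHER_MEMBRANE")

# WoLF PSORT labels the cascade maps directly to a category (step 5);
# golg/nucl/vacu are split by TMHMM afterwards
.WOLF_LOCATION_MAP <- c(
    cyto = "CYTOPLASM", cysk = "CYTOSKELETON",
    golg = "GOLGI_LUMEN", lyso = "LYSOSOME",
    nucl = "NUCLEAR_NONMEMBRANE", pero = "PEROXISOME",
    plas = "PLASMA_MEMBRANE", vacu = "VACUOLE_NONMEMBRANE")

.GPI_CLASSES <- c("HIGHLY_PROBABLE", "PROBABLE", "WEAKLY_PROBABLE", "NONE")

.QUALIFIERS <- c("NONE", "BY_SIMILARITY", "PROBABLE", "POTENTIAL")

# precedence when a curated record carries several mapped categories:
# the first matching entry decides (secreted first, cytoskeleton before
# cytoplasm because curated cytoskeleton entries are routinely also
# annotated cytoplasm)
.CURATED_PRECEDENCE <- c(
    "SECRETED", "GPI_ANCHORED", "CYTOSKELETON",
    "MITO_MEMBRANE", "MITO_NONMEMBRANE",
    "ER_MEMBRANE", "ER_LUMEN",
    "GOLGI_MEMBRANE", "GOLGI_LUMEN",
    "NUCLEAR_MEMBRANE", "NUCLEAR_NONMEMBRANE",
    "VACUOLE_MEMBRANE", "VACUOLE_NONMEMBRANE",
    "LYSOSOME", "PEROXISOME", "PLASMA_MEMBRANE",
    "CYTOPLASM", "OTHER_MEMBRANE")

#' Load the curated-vocabulary mapping table
#'
#' The mapping from UniProt subcellular-location terms to package
#' categories ships as a plain TSV so that a vocabulary revision is a data
#' update, not a code change.
#'
#' @param path Optional path to an alternative two-column (`term`,
#'   `category`) TSV; defaults to the table shipped with the package.
#' @return data.frame with columns `term` (lower case) and `category`.
#' @export
locationVocabulary <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "location_vocabulary.tsv",
                            package = "secloc", mustWork = TRUE)
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    stopifnot(all(c("term", "category") %in% names(tab)))
    bad <- setdiff(tab$category, locationCategories())
    if (length(bad))
        stop("vocabulary maps to unknown categories: ",
             paste(bad, collapse = ", "))
    tab$term <- tolower(tab$term)
    tab
}
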