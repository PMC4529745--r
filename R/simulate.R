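## Synthetic fixture generator: a proteome with known ground-truth
## locations plus the seven predictor output files in their native
## dialects, so the cascade and the metrics machinery can be exercised
## end-to-end without the licensed predictors. Errors are injected at
## the verdict level (the unit under test is the cascade, not the
## predictors' biology); sequences only carry the features the package
## itself reads from them: the initial Met, the C-terminal ER-retention
## motif for ER-truth proteins, and enough length for the planted
## transmembrane helices.

# categories a curated comment can express (have a vocabulary term)
.SIM_CURATABLE <- c(
    SECRETED = "Secreted", GPI_ANCHORED = "GPI-anchor",
    MITO_MEMBRANE = "Mitochondrion inner membrane",
    MITO_NONMEMBRANE = "Mitochondrion",
    ER_MEMBRANE = "Endoplasmic reticulum membrane",
    ER_LUMEN = "Endoplasmic reticulum lumen",
    CYTOPLASM = "Cytoplasm", CYTOSKELETON = "Cytoskeleton",
    GOLGI_MEMBRANE = "Golgi apparatus membrane",
    GOLGI_LUMEN = "Golgi apparatus",
    NUCLEAR_MEMBRANE = "Nucleus membrane",
    NUCLEAR_NONMEMBRANE = "Nucleus",
    VACUOLE_MEMBRANE = "Vacuole membrane",
    VACUOLE_NONMEMBRANE = "Vacuole",
    LYSOSOME = "Lysosome", PEROXISOME = "Peroxisome",
    PLASMA_MEMBRANE = "Cell membrane")

.SIM_MEMBRANE_TRUTH <- c("MITO_MEMBRANE", "ER_MEMBRANE", "GOLGI_MEMBRANE",
                         "NUCLEAR_MEMBRANE", "VACUOLE_MEMBRANE",
                         "OTHER_MEMBRANE")

.SIM_ERROR_CHANNELS <- c("signalp4", "phobius", "targetp_s", "wolf_extr",
                         "targetp_m", "wolf_mito", "tmhmm", "signalp3",
                         "fraganchor")

#' Default category mix for simulated proteomes
#'
#' Proportions chosen to resemble a typical metazoan subcellular proteome
#' distribution: cytoplasm and nucleus dominate (about 30% each),
#' plasma membrane about 12%, secreted 8%, mitochondria 6%, the
#' remaining organelles small.
#'
#' @return Named probability vector over truth categories (sums to 1).
#' @export
defaultCategoryMix <- function() {
    c(SECRETED = 0.08, GPI_ANCHORED = 0.01,
      MITO_MEMBRANE = 0.02, MITO_NONMEMBRANE = 0.04,
      ER_MEMBRANE = 0.015, ER_LUMEN = 0.015,
      CYTOPLASM = 0.30, CYTOSKELETON = 0.02,
      GOLGI_MEMBRANE = 0.01, GOLGI_LUMEN = 0.01,
      NUCLEAR_MEMBRANE = 0.02, NUCLEAR_NONMEMBRANE = 0.28,
      VACUOLE_MEMBRANE = 0.005, VACUOLE_NONMEMBRANE = 0.005,
      LYSOSOME = 0.01, PEROXISOME = 0.01,
      PLASMA_MEMBRANE = 0.12, OTHER_MEMBRANE = 0.02,
      UNKNOWN = 0.01)
}

#' Simulation configuration
#'
#' @param nProteins Number of proteins to generate.
#' @param categoryMix Named probability vector over truth categories
#'   (must sum to 1); see [defaultCategoryMix()].
#' @param perToolError Named numeric vector of verdict error rates,
#'   names `<channel>_fp` / `<channel>_fn` with channels `signalp4`,
#'   `phobius`, `targetp_s`, `wolf_extr` (the four secretion votes),
#'   `targetp_m`, `wolf_mito` (the mitochondrial rule), `tmhmm`,
#'   `signalp3`, `fraganchor`. Unspecified rates are 0 (noiseless).
#' @param seed Integer seed; the same configuration always produces
#'   byte-identical files.
#' @param lengthRange Residue-length bounds for generated sequences.
#' @param nSpecies Number of species the proteins are spread over.
#' @param curatedFraction Fraction of proteins carrying a curated
#'   (reviewed) location comment; the cascade then ignores their
#'   predictions.
#' @param hedgedFraction Of the curated records, the fraction whose
#'   comment carries a `By similarity`/`Probable`/`Potential` qualifier
#'   (exercises the benchmark filter; the cascade still honours them).
#' @param multiFraction Of the curated records, the fraction given a
#'   second, lower-precedence location term.
#' @return List of class `"simulationConfig"`.
#' @export
simulationConfig <- function(nProteins = 1000,
                             categoryMix = defaultCategoryMix(),
                             perToolError = numeric(0),
                             seed = 1L,
                             lengthRange = c(80L, 400L),
                             nSpecies = 3L,
                             curatedFraction = 0.1,
                             hedgedFraction = 0.1,
                             multiFraction = 0.05) {
    if (abs(sum(categoryMix) - 1) > 1e-8)
        stop("categoryMix must sum to 1", call. = FALSE)
    if (any(categoryMix < 0)) stop("negative mix probability", call. = FALSE)
    bad <- setdiff(names(categoryMix), locationCategories())
    if (length(bad))
        stop("unknown truth category: ", paste(bad, collapse = ", "),
             call. = FALSE)
    err <- stats::setNames(
        rep(0, 2 * length(.SIM_ERROR_CHANNELS)),
        paste0(rep(.SIM_ERROR_CHANNELS, each = 2), c("_fp", "_fn")))
    if (length(perToolError)) {
        bad <- setdiff(names(perToolError), names(err))
        if (length(bad))
            stop("unknown error channel: ", paste(bad, collapse = ", "),
                 call. = FALSE)
        if (any(perToolError < 0 | perToolError > 1))
            stop("error rates must be in [0, 1]", call. = FALSE)
        err[names(perToolError)] <- perToolError
    }
    if (lengthRange[1] < 10)
        stop("lengthRange minimum too small to carry the planted motifs",
             call. = FALSE)
    structure(list(nProteins = as.integer(nProteins),
                   categoryMix = categoryMix, perToolError = err,
                   seed = as.integer(seed),
                   lengthRange = as.integer(lengthRange),
                   nSpecies = as.integer(nSpecies),
                   curatedFraction = curatedFraction,
                   hedgedFraction = hedgedFraction,
                   multiFraction = multiFraction),
              class = "simulationConfig")
}

# flip boolean verdicts through an asymmetric error channel
.channel <- function(truth, fp, fn) {
    n <- length(truth)
    u <- stats::runif(n)
    ifelse(truth, u >= fn, u < fp)
}

#' Generate a synthetic proteome with predictor outputs
#'
#' Writes, under `dir`: `proteome.fasta`, `uniprot.txt` (flat-text
#' records for every protein; only curated ones carry a location
#' comment), the seven tool files (`signalp3.txt`, `signalp4.txt`,
#' `targetp.txt`, `phobius.txt`, `wolfpsort.txt`, `tmhmm.txt`,
#' `fraganchor.txt`) and `truth.tsv` (protein_id, category, tier,
#' species_name, taxon_id).
#'
#' @param config A [simulationConfig()].
#' @param dir Output directory (created if needed).
#' @return Invisible list: `paths` (named file paths) and `truth`
#'   (the truth table as a data.frame).
#' @export
simulateProteome <- function(config, dir) {
    stopifnot(inherits(config, "simulationConfig"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    set.seed(config$seed)
    n <- config$nProteins
    err <- config$perToolError

    truthCat <- sample(names(config$categoryMix), n, replace = TRUE,
                       prob = config$categoryMix)
    ids <- sprintf("SP%05d", seq_len(n))
    species <- sample.int(config$nSpecies, n, replace = TRUE)
    speciesName <- paste("Synthetica species", species)
    taxonId <- 900000L + species

    ## --- sequences -----------------------------------------------------
    isMemTruth <- truthCat %in% .SIM_MEMBRANE_TRUTH
    isER <- truthCat %in% c("ER_LUMEN", "ER_MEMBRANE")
    len <- sample(seq(config$lengthRange[1], config$lengthRange[2]), n,
                  replace = TRUE)
    len[isMemTruth] <- pmax(len[isMemTruth], 130L)
    seqs <- vapply(len, function(L)
        paste(sample(.AA20, L, replace = TRUE), collapse = ""),
        character(1))
    substr(seqs, 1L, 1L) <- "M"
    # ER truth carries the C-terminal retention motif; everyone else is
    # guaranteed motif-free (final residue G breaks the ...E-L> pattern)
    seqs[isER] <- paste0(substr(seqs[isER], 1L, len[isER] - 4L), "KDEL")
    seqs[!isER] <- paste0(substr(seqs[!isER], 1L, len[!isER] - 1L), "G")

    ## --- true verdicts, then the error channels ------------------------
    secretedLike <- truthCat %in% c("SECRETED", "GPI_ANCHORED")
    isMito <- truthCat %in% c("MITO_MEMBRANE", "MITO_NONMEMBRANE")
    isGPI <- truthCat == "GPI_ANCHORED"

    sp4 <- .channel(secretedLike, err["signalp4_fp"], err["signalp4_fn"])
    phob <- .channel(secretedLike, err["phobius_fp"], err["phobius_fn"])
    tgtS <- .channel(secretedLike, err["targetp_s_fp"], err["targetp_s_fn"])
    wExtr <- .channel(secretedLike, err["wolf_extr_fp"], err["wolf_extr_fn"])
    tgtM <- .channel(isMito, err["targetp_m_fp"], err["targetp_m_fn"])
    wMito <- .channel(isMito, err["wolf_mito_fp"], err["wolf_mito_fn"])
    tm <- .channel(isMemTruth, err["tmhmm_fp"], err["tmhmm_fn"])
    sp3 <- .channel(secretedLike, err["signalp3_fp"], err["signalp3_fn"])
    frag <- .channel(isGPI, err["fraganchor_fp"], err["fraganchor_fn"])

    targetpLoc <- ifelse(tgtM, "M", ifelse(tgtS, "S", "_"))
    # WoLF PSORT top label: votes and the mito rule outrank the plain
    # location labels; a location-truth protein keeps its own label
    wolfBase <- c(CYTOPLASM = "cyto", CYTOSKELETON = "cysk",
                  GOLGI_MEMBRANE = "golg", GOLGI_LUMEN = "golg",
                  NUCLEAR_MEMBRANE = "nucl", NUCLEAR_NONMEMBRANE = "nucl",
                  VACUOLE_MEMBRANE = "vacu", VACUOLE_NONMEMBRANE = "vacu",
                  LYSOSOME = "lyso", PEROXISOME = "pero",
                  PLASMA_MEMBRANE = "plas",
                  ER_LUMEN = "E.R.", ER_MEMBRANE = "E.R.",
                  MITO_MEMBRANE = "mito", MITO_NONMEMBRANE = "mito",
                  SECRETED = "extr", GPI_ANCHORED = "extr",
                  OTHER_MEMBRANE = "mito", UNKNOWN = "mito")
    wolfTop <- unname(wolfBase[truthCat])
    wolfTop[secretedLike & !wExtr] <- "cyto"   # lost the extr call
    wolfTop[!secretedLike & wExtr] <- "extr"
    wolfTop[isMito & !wMito] <- "cyto"
    wolfTop[!isMito & !secretedLike & wMito] <- "mito"

    helices <- vector("list", n)
    for (i in which(tm)) helices[[i]] <- cbind(start = 100L, end = 122L)
    for (i in which(!tm)) helices[[i]] <- matrix(integer(0), ncol = 2,
                                                 dimnames = list(NULL,
                                                     c("start", "end")))

    ## --- curated annotation --------------------------------------------
    curatable <- truthCat %in% names(.SIM_CURATABLE)
    curated <- stats::runif(n) < config$curatedFraction & curatable
    tier <- ifelse(curated & truthCat == "SECRETED", "CURATED_SECRETED",
                   NA_character_)
    votes <- as.integer(sp4) + as.integer(phob) + as.integer(tgtS) +
        as.integer(wolfTop == "extr")
    predSec <- !curated & votes >= 1 & !tm
    tier[predSec & truthCat %in% c("SECRETED", "GPI_ANCHORED")] <-
        c("WEAKLY_LIKELY", "LIKELY", "HIGHLY_LIKELY",
          "HIGHLY_LIKELY")[votes[predSec & truthCat %in%
                                 c("SECRETED", "GPI_ANCHORED")]]

    hedged <- curated & stats::runif(n) < config$hedgedFraction
    rankCyt <- match("CYTOPLASM", .CURATED_PRECEDENCE)
    multi <- curated & stats::runif(n) < config$multiFraction &
        match(truthCat, .CURATED_PRECEDENCE) < rankCyt

    ## --- write the files -----------------------------------------------
    paths <- c(fasta = "proteome.fasta", uniprot = "uniprot.txt",
               signalp3 = "signalp3.txt", signalp4 = "signalp4.txt",
               targetp = "targetp.txt", phobius = "phobius.txt",
               wolfpsort = "wolfpsort.txt", tmhmm = "tmhmm.txt",
               fraganchor = "fraganchor.txt", truth = "truth.tsv")
    paths <- stats::setNames(file.path(dir, paths), names(paths))

    wrap <- function(s) gsub("(.{60})", "\\1\n", s)
    writeLines(paste0(">", ids, "\n", wrap(seqs)), paths["fasta"])

    qualTxt <- ifelse(hedged, " (By similarity)", "")
    ccLine <- ifelse(curated,
        paste0("CC   -!- SUBCELLULAR LOCATION: ",
               .SIM_CURATABLE[truthCat], qualTxt, ".",
               ifelse(multi, " Cytoplasm.", ""), "\n"),
        "")
    up <- paste0(
        "ID   ", ids, "_SYN   ",
        ifelse(curated, "Reviewed;", "Unreviewed;"), "   ", len, " AA.\n",
        "AC   ", ids, ";\n",
        "OS   ", speciesName, ".\n",
        "OX   NCBI_TaxID=", taxonId, ";\n",
        ccLine,
        "SQ   SEQUENCE   ", len, " AA;\n",
        "     ", wrap(seqs), "\n//")
    writeLines(up, paths["uniprot"])

    ysn <- function(b) ifelse(b, "Y", "N")
    writeLines(c("# SignalP-NN euk predictions",
        sprintf("%s  0.500  23 %s  0.500  23 %s  0.700   5 %s  0.600 %s  0.550 %s",
                ids, ysn(sp3), ysn(sp3), ysn(sp3), ysn(sp3), ysn(sp3))),
        paths["signalp3"])
    writeLines(c("# SignalP-4.1 euk predictions",
        "# name   Cmax  pos  Ymax  pos  Smax  pos  Smean   D     ?  Dmaxcut  Networks-used",
        sprintf("%s  0.500  23  0.480  23  0.700   5  0.600  0.550 %s  0.450  SignalP-noTM",
                ids, ysn(sp4))),
        paths["signalp4"])
    writeLines(c("# TargetP v1.1 prediction results",
        "Name  Len  mTP  SP  other  Loc  RC", paste(rep("-", 60), collapse = ""),
        sprintf("%s  %d  %.3f  %.3f  %.3f  %s  2", ids, len,
                ifelse(targetpLoc == "M", 0.9, 0.1),
                ifelse(targetpLoc == "S", 0.9, 0.1),
                ifelse(targetpLoc == "_", 0.9, 0.1), targetpLoc)),
        paths["targetp"])
    writeLines(c("SEQENCE ID                     TM SP PREDICTION",
        sprintf("%s  %d  %s  %s", ids, vapply(helices, nrow, integer(1)),
                ifelse(phob, "Y", "0"),
                ifelse(tm, "i100-122o", "o"))),
        paths["phobius"])
    writeLines(c("# k used for kNN is: 27",
        sprintf("%s %s 25, %s 5", ids, wolfTop,
                ifelse(wolfTop == "cyto", "nucl", "cyto"))),
        paths["wolfpsort"])
    topo <- vapply(seq_len(n), function(i) {
        h <- helices[[i]]
        if (!nrow(h)) "o"
        else paste0("o", paste(h[, 1], h[, 2], sep = "-", collapse = "i"),
                    "i")
    }, character(1))
    writeLines(sprintf(
        "%s\tlen=%d\tExpAA=%.2f\tFirst60=0.00\tPredHel=%d\tTopology=%s",
        ids, len, 23 * vapply(helices, nrow, integer(1)),
        vapply(helices, nrow, integer(1)), topo),
        paths["tmhmm"])
    fragTxt <- ifelse(frag, "Highly probable", "Potential false positive")
    writeLines(sprintf("%s\t%s", ids, fragTxt), paths["fraganchor"])

    truth <- data.frame(protein_id = ids, category = truthCat,
                        tier = ifelse(is.na(tier), "", tier),
                        curated = curated,
                        species_name = speciesName, taxon_id = taxonId,
                        stringsAsFactors = FALSE)
    utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(list(paths = paths, truth = truth))
}
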