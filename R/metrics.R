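## Benchmark construction and Sn/Sp/MCC evaluation. The benchmark is the
## curated single-location set: reviewed entries with exactly one mapped
## location, no hedged qualifier, full length (not a fragment, starts
## with Met, >= 70 residues). Metrics follow the standard definitions:
## Sn = TP/(TP+FN)x100, Sp = TN/(TN+FP)x100, MCC on the -1..1 scale.

# benchmark groups: membrane/non-membrane splits are pooled per organelle
.BENCHMARK_GROUPS <- list(
    Secreted = "SECRETED",
    Mitochondria = c("MITO_MEMBRANE", "MITO_NONMEMBRANE"),
    Cytoplasm = "CYTOPLASM",
    Cytoskeleton = "CYTOSKELETON",
    ER = c("ER_MEMBRANE", "ER_LUMEN"),
    Golgi = c("GOLGI_MEMBRANE", "GOLGI_LUMEN"),
    Lysosome = "LYSOSOME",
    Nucleus = c("NUCLEAR_MEMBRANE", "NUCLEAR_NONMEMBRANE"),
    Peroxisome = "PEROXISOME",
    `Plasma membrane` = "PLASMA_MEMBRANE",
    Vacuole = c("VACUOLE_MEMBRANE", "VACUOLE_NONMEMBRANE"),
    `GPI-anchored` = "GPI_ANCHORED")

#' Build the curated single-location benchmark
#'
#' Keeps reviewed proteins with exactly one mapped curated location
#' category, no `By similarity`/`Probable`/`Potential` qualifier on any
#' location term, not flagged as fragment, starting with methionine and
#' at least 70 residues long. Proteins annotated both cytoplasm and
#' cytoskeleton count as cytoskeleton (not as multi-location, and never
#' inside cytoplasm); cell-membrane annotation populates the plasma
#' membrane set.
#'
#' @param x A [ProteinSet-class] with curated locations.
#' @param minLength Minimum sequence length retained (default 70).
#' @return Named list of accession vectors, one per benchmark group, with
#'   attributes `universe` (all retained accessions) and `exclusions`
#'   (named tally of exclusion reasons).
#' @export
buildBenchmark <- function(x, minLength = 70L) {
    stopifnot(methods::is(x, "ProteinSet"))
    info <- x@info
    cur <- x@curated
    acc <- info$accession

    mappedCats <- lapply(stats::setNames(nm = acc), function(a) character(0))
    hedged <- stats::setNames(rep(FALSE, length(acc)), acc)
    if (nrow(cur)) {
        mapped <- cur[cur$category %in% locationCategories(), , drop = FALSE]
        sp <- split(mapped$category, mapped$accession)
        mappedCats[names(sp)] <- lapply(sp, unique)
        hq <- tapply(cur$qualifier != "NONE", cur$accession, any)
        hedged[names(hq)] <- hq
    }
    # cytoskeleton precedence: cytoplasm+cytoskeleton is one location
    mappedCats <- lapply(mappedCats, function(cats) {
        if (setequal(cats, c("CYTOPLASM", "CYTOSKELETON"))) "CYTOSKELETON"
        else cats
    })
    nCats <- lengths(mappedCats)

    reasons <- character(length(acc))
    reasons[!info$reviewed] <- "unreviewed"
    reasons[reasons == "" & nCats == 0] <- "no_mapped_location"
    reasons[reasons == "" & nCats > 1] <- "multiple_locations"
    reasons[reasons == "" & hedged] <- "qualifier"
    reasons[reasons == "" & info$isFragment] <- "fragment"
    met <- unname(startsWithMet(x))
    reasons[reasons == "" & !met] <- "no_initial_met"
    len <- unname(seqLengths(x))
    reasons[reasons == "" & len < minLength] <- "too_short"

    keep <- reasons == ""
    universe <- acc[keep]
    cat1 <- vapply(mappedCats[keep], `[`, character(1), 1)
    out <- lapply(.BENCHMARK_GROUPS, function(cats)
        universe[cat1 %in% cats])
    attr(out, "universe") <- universe
    attr(out, "exclusions") <- table(factor(reasons[!keep]))
    out
}

#' 2x2 confusion counts over a universe
#'
#' @param predictedPos,actualPos Character vectors of protein ids.
#' @param universe All ids under evaluation; `actualPos` and
#'   `predictedPos` must be subsets.
#' @return A [ConfusionMatrix-class].
#' @export
confusion <- function(predictedPos, actualPos, universe) {
    universe <- unique(universe)
    if (!all(actualPos %in% universe))
        stop("actualPos is not a subset of the universe", call. = FALSE)
    if (!all(predictedPos %in% universe))
        stop("predictedPos is not a subset of the universe", call. = FALSE)
    pred <- universe %in% predictedPos
    act <- universe %in% actualPos
    confusionMatrix(tp = sum(pred & act), fp = sum(pred & !act),
                    tn = sum(!pred & !act), fn = sum(!pred & act))
}

.asCM <- function(cm) {
    if (methods::is(cm, "ConfusionMatrix"))
        return(c(tp = cm@tp, fp = cm@fp, tn = cm@tn, fn = cm@fn))
    stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(cm)))
    c(tp = cm[["tp"]], fp = cm[["fp"]], tn = cm[["tn"]], fn = cm[["fn"]])
}

#' Sensitivity, specificity and Matthews correlation coefficient
#'
#' `sensitivity()` is TP/(TP+FN) x 100 and `specificity()` TN/(TN+FP) x
#' 100, both reported in percent; `mcc()` is the Matthews correlation
#' coefficient on the -1..1 scale, with an exact integer numerator and a
#' full-precision square-root denominator. A zero denominator (any zero
#' marginal for MCC) is an undefined-metric error, as for a benchmark
#' category with no predicted positives.
#'
#' @param cm A [ConfusionMatrix-class] (or a named vector/list with
#'   `tp`, `fp`, `tn`, `fn`).
#' @param digits Display rounding (half-up): 1 decimal for Sn/Sp, 2 for
#'   MCC; `NA` for no rounding.
#' @return Numeric scalar.
#' @examples
#' cm <- confusionMatrix(tp = 5350, fp = 522, tn = 12628, fn = 374)
#' sensitivity(cm); specificity(cm); mcc(cm)
#' @export
sensitivity <- function(cm, digits = 1) {
    x <- .asCM(cm)
    if (x["tp"] + x["fn"] == 0)
        stop("undefined metric: no actual positives", call. = FALSE)
    out <- 100 * x[["tp"]] / (x[["tp"]] + x[["fn"]])
    if (is.na(digits)) out else roundHalfUp(out, digits)
}

#' @rdname sensitivity
#' @export
specificity <- function(cm, digits = 1) {
    x <- .asCM(cm)
    if (x["tn"] + x["fp"] == 0)
        stop("undefined metric: no actual negatives", call. = FALSE)
    out <- 100 * x[["tn"]] / (x[["tn"]] + x[["fp"]])
    if (is.na(digits)) out else roundHalfUp(out, digits)
}

#' @rdname sensitivity
#' @export
mcc <- function(cm, digits = 2) {
    x <- .asCM(cm)
    marg <- c(x["tp"] + x["fp"], x["tp"] + x["fn"],
              x["tn"] + x["fp"], x["tn"] + x["fn"])
    if (any(marg == 0))
        stop("undefined metric: zero marginal in the confusion matrix",
             call. = FALSE)
    num <- x[["tp"]] * x[["tn"]] - x[["fp"]] * x[["fn"]]
    out <- num / sqrt(prod(marg))
    if (is.na(digits)) out else roundHalfUp(out, digits)
}

#' All three metrics for a confusion matrix
#'
#' @inheritParams sensitivity
#' @param snSpDigits,mccDigits Display rounding, as in [sensitivity()].
#' @return Named list `sn`, `sp`, `mcc` (`mcc` is `NA` when undefined).
#' @export
metricSet <- function(cm, snSpDigits = 1, mccDigits = 2) {
    m <- tryCatch(mcc(cm, mccDigits), error = function(e) NA_real_)
    list(sn = sensitivity(cm, snSpDigits),
         sp = specificity(cm, snSpDigits), mcc = m)
}

## ---- rule mini-language -----------------------------------------------
## A rule is a boolean expression over tool verdicts, e.g.
##   "targetp=M AND wolf=mito"
##   "votes>=3 AND NOT tmhmm AND NOT ps00014"
##   "signalp4 OR phobius"
## Predicates: signalp3, signalp4, phobius, tmhmm, ps00014,
## targetp=<S|M|OTHER>, wolf=<label-component>, fraganchor>=<class>,
## votes=<k>, votes>=<k>. AND binds tighter than OR; NOT prefixes a
## single predicate. No parentheses.

.rulePredicate <- function(token, v, votes, tm, kdel) {
    neg <- grepl("^NOT\\s+", token)
    tk <- sub("^NOT\\s+", "", token)
    val <- if (grepl("^votes>=", tk)) {
        votes >= as.integer(sub("votes>=", "", tk))
    } else if (grepl("^votes=", tk)) {
        votes == as.integer(sub("votes=", "", tk))
    } else if (grepl("^targetp=", tk, ignore.case = TRUE)) {
        !is.na(v$targetpLoc) &
            v$targetpLoc == toupper(sub("targetp=", "", tk,
                                        ignore.case = TRUE))
    } else if (grepl("^wolf=", tk, ignore.case = TRUE)) {
        w <- .wolfComponent(v$wolfTop)
        !is.na(w) & w == sub("wolf=", "", tk, ignore.case = TRUE)
    } else if (grepl("^fraganchor>=", tk, ignore.case = TRUE)) {
        cls <- toupper(sub("fraganchor>=", "", tk, ignore.case = TRUE))
        if (!cls %in% .GPI_CLASSES)
            stop("unknown FragAnchor class '", cls, "'", call. = FALSE)
        ok <- .GPI_CLASSES[seq_len(match(cls, .GPI_CLASSES))]
        !is.na(v$gpiClass) & v$gpiClass %in% ok
    } else switch(tolower(tk),
        signalp3 = !is.na(v$sp3Signal) & v$sp3Signal,
        signalp4 = !is.na(v$sp4Signal) & v$sp4Signal,
        phobius = !is.na(v$phobiusSignal) & v$phobiusSignal,
        tmhmm = tm,
        ps00014 = kdel,
        stop("unknown rule predicate '", tk, "'", call. = FALSE))
    if (neg) !val else val
}

#' Evaluate a predictor-combination rule over a bundle set
#'
#' @param rule Rule string (see Details in [evaluateRule()]).
#' @param bundles A [PredictionBundleSet-class].
#' @param motifHits Optional logical vector named by protein id
#'   (ER-retention motif hits) backing the `ps00014` predicate.
#' @return Logical vector named by protein id: does the rule call the
#'   protein positive?
#' @export
applyRule <- function(rule, bundles, motifHits = NULL) {
    stopifnot(methods::is(bundles, "PredictionBundleSet"))
    v <- bundles@verdicts
    votes <- unname(suppressWarnings(
        countSecretionVotes(bundles, mode = "lenient")))
    tm <- unname(isMembraneByTmhmm(bundles))
    kdel <- if (is.null(motifHits)) rep(FALSE, nrow(v)) else {
        k <- motifHits[v$proteinId]
        !is.na(k) & k
    }
    orParts <- strsplit(rule, "\\s+OR\\s+")[[1]]
    res <- Reduce(`|`, lapply(orParts, function(part) {
        andParts <- trimws(strsplit(part, "\\s+AND\\s+")[[1]])
        Reduce(`&`, lapply(andParts, .rulePredicate, v = v, votes = votes,
                           tm = tm, kdel = kdel))
    }))
    stats::setNames(res, v$proteinId)
}

#' Benchmark a set of rules, one row per rule
#'
#' Each rule is scored one-vs-rest on a benchmark category: positives are
#' the benchmark proteins of `category`, negatives all other retained
#' benchmark proteins.
#'
#' @param rules data.frame with columns `rule` (rule strings, see
#'   [applyRule()]) and `category` (benchmark group name); an optional
#'   `label` column names the rows.
#' @param benchmark Output of [buildBenchmark()].
#' @param bundles A [PredictionBundleSet-class] covering the benchmark
#'   universe.
#' @param motifHits As in [applyRule()].
#' @return data.frame: label, rule, category, tp, fp, tn, fn, sn, sp,
#'   mcc (`NA` with `undefined = TRUE` when a marginal is zero).
#' @export
evaluateRule <- function(rules, benchmark, bundles, motifHits = NULL) {
    stopifnot(is.data.frame(rules),
              all(c("rule", "category") %in% names(rules)))
    universe <- attr(benchmark, "universe")
    bad <- setdiff(rules$category, names(benchmark))
    if (length(bad))
        stop("unknown benchmark category: ", paste(bad, collapse = ", "),
             call. = FALSE)
    label <- if (!is.null(rules$label)) rules$label else rules$rule
    out <- lapply(seq_len(nrow(rules)), function(i) {
        pos <- applyRule(rules$rule[i], bundles, motifHits)
        predicted <- intersect(names(pos)[pos], universe)
        actual <- benchmark[[rules$category[i]]]
        cm <- confusion(predicted, actual, universe)
        ms <- tryCatch(metricSet(cm), error = function(e)
            list(sn = NA_real_, sp = NA_real_, mcc = NA_real_))
        data.frame(label = label[i], rule = rules$rule[i],
                   category = rules$category[i],
                   tp = cm@tp, fp = cm@fp, tn = cm@tn, fn = cm@fn,
                   sn = ms$sn, sp = ms$sp, mcc = ms$mcc,
                   undefined = is.na(ms$mcc) || is.na(ms$sn) ||
                       is.na(ms$sp),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Reference benchmark counts of the consensus protocol
#'
#' The published confusion counts (with printed Sn/Sp/MCC) of the
#' protocol's evaluation on 18,874 single-location reviewed metazoan
#' proteins: four mitochondrial rules (1870 positives / 17,004
#' negatives), four cumulative secretion-vote tiers (5724 / 13,150) and
#' nine WoLF-PSORT location categories. Shipped as a plain TSV and used
#' as the regression fixture for the metrics implementation.
#'
#' @return data.frame with columns `panel`, `rule`, `tp`, `fp`, `tn`,
#'   `fn`, `sn`, `sp`, `mcc`.
#' @export
referenceAccuracyCounts <- function() {
    path <- system.file("extdata", "reference_accuracy_counts.tsv",
                        package = "secloc", mustWork = TRUE)
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
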