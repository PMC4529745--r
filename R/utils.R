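# round half away from zero (base round() is banker's); display rounding
# for reported metrics
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

# read a text source: path, connection, or literal text via I()/newline
.readLinesFlexible <- function(x) {
    if (inherits(x, "connection")) return(readLines(x, warn = FALSE))
    if (inherits(x, "AsIs") || (is.character(x) && length(x) == 1 &&
                                grepl("\n", x, fixed = TRUE)))
        return(strsplit(paste(unclass(x), collapse = "\n"), "\n",
                        fixed = TRUE)[[1]])
    if (is.character(x) && length(x) > 1) return(x)
    readLines(x, warn = FALSE)
}

.stopIfEmpty <- function(lines, what) {
    if (!length(lines) || all(!nzchar(trimws(lines))))
        stop("empty ", what, " input", call. = FALSE)
    lines
}

# first whitespace-delimited token: how the predictors truncate headers
.idToken <- function(x) sub("\\s.*$", "", trimws(x))
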