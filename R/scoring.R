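# Scoring model: alphabet handling, pairwise sigma and three-way gamma.

.ALPHABET <- c("A", "C", "G", "T", "N")
.GAP <- "-"

.inputError <- function(...) {
    stop(errorCondition(paste0(...), class = c("plalign_input_error",
                                               "error", "condition")))
}

# Encode letters/gaps as integers: 0 gap, 1..4 ACGT, 5 N.
.encode <- function(x) {
    if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
    chars <- if (length(x) == 1L && !nzchar(x)) character() else
        if (length(x) == 1L) strsplit(x, "")[[1L]] else x
    code <- match(chars, c(.GAP, .ALPHABET)) - 1L
    if (anyNA(code))
        .inputError("unknown symbol(s): ",
                    paste(unique(chars[is.na(code)]), collapse = ", "))
    code
}

#' Construct a scoring scheme
#'
#' The defaults are the scheme used throughout the breakpoint analyses:
#' pairwise scores (1, -1, -2) with sum-of-pairs weight W = 1.  The match
#' score must be positive and the mismatch and indel scores negative;
#' a mismatch score below the indel score triggers a warning because such
#' schemes favour spurious insertion/deletion pairs over substitutions.
#' The edge gap score g used on the boundary of the dynamic programming
#' tensor defaults to the indel score but is stored separately.
#'
#' @param match match score \eqn{\alpha > 0}.
#' @param mismatch mismatch score \eqn{\beta < 0}.
#' @param indel indel score \eqn{\delta < 0}.
#' @param edgeGap uniform edge gap score \eqn{g}; default \code{indel}.
#' @param sopWeight sum-of-pairs weight \eqn{W \ge 1}.
#' @return a \linkS4class{ScoringScheme}.
#' @examples
#' ScoringScheme()                 # (1, -1, -2), W = 1
#' ScoringScheme(2, -3, -3, sopWeight = 2)
#' @export
ScoringScheme <- function(match = 1, mismatch = -1, indel = -2,
                          edgeGap = indel, sopWeight = 1) {
    s <- new("ScoringScheme", matchScore = as.numeric(match),
             mismatchScore = as.numeric(mismatch),
             indelScore = as.numeric(indel),
             edgeGap = as.numeric(edgeGap),
             sopWeight = as.numeric(sopWeight))
    validObject(s)
    if (s@mismatchScore < s@indelScore)
        warning("mismatch score below indel score: ",
                "insertions+deletions will outcompete substitutions")
    s
}

.sigmaInt <- function(a, b, scheme) {
    if (a == 0L && b == 0L) return(0)
    if (a == 0L || b == 0L) return(scheme@indelScore)
    if (a == b && a != 5L) return(scheme@matchScore)
    scheme@mismatchScore
}

#' Pairwise score sigma
#'
#' \code{sigma(a,a) = } match, \code{sigma(a,b) = } mismatch for distinct
#' letters, \code{sigma(a,'-') = sigma('-',a) = } indel and
#' \code{sigma('-','-') = 0}.  The ambiguity letter N scores as a mismatch
#' against every letter, including N itself.
#'
#' @param a,b single letters from \code{A,C,G,T,N} or the gap \code{"-"}.
#' @param scheme a \linkS4class{ScoringScheme}.
#' @return the pairwise score (numeric scalar).
#' @examples
#' sigmaScore("A", "A", ScoringScheme())   # 1
#' sigmaScore("A", "-", ScoringScheme())   # -2
#' @export
sigmaScore <- function(a, b, scheme = ScoringScheme()) {
    .sigmaInt(.encode(a), .encode(b), scheme)
}

#' Three-way score gamma (sum of pairs)
#'
#' \code{gamma(a,b,c) = (sigma(a,b) + sigma(a,c) + sigma(b,c)) / w} where
#' the divisor \code{w} equals the sum-of-pairs weight W when all three
#' arguments are letters and 1 as soon as any argument is a gap.  An
#' all-gap column is rejected: it cannot occur in a valid alignment.
#'
#' @inheritParams sigmaScore
#' @param c single letter or gap.
#' @return the column score (numeric scalar).
#' @examples
#' gammaScore("A", "A", "A", ScoringScheme())             # 3
#' gammaScore("A", "-", "-", ScoringScheme())             # -4
#' @export
gammaScore <- function(a, b, c, scheme = ScoringScheme()) {
    ai <- .encode(a); bi <- .encode(b); ci <- .encode(c)
    if (ai == 0L && bi == 0L && ci == 0L)
        .inputError("gamma undefined for an all-gap column")
    s <- .sigmaInt(ai, bi, scheme) + .sigmaInt(ai, ci, scheme) +
        .sigmaInt(bi, ci, scheme)
    if (ai != 0L && bi != 0L && ci != 0L) s / scheme@sopWeight else s
}

#' @describeIn ScoringScheme display method
#' @param object a \code{ScoringScheme}.
#' @export
setMethod("show", "ScoringScheme", function(object) {
    cat(sprintf(
        "ScoringScheme: match %g, mismatch %g, indel %g, edge gap %g, W %g\n",
        object@matchScore, object@mismatchScore, object@indelScore,
        object@edgeGap, object@sopWeight))
    invisible(object)
})
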