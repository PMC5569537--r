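# S4 classes for the partially local three-way alignment model.

#' Scoring scheme for partially local three-way alignment
#'
#' Holds the pairwise scores (match \eqn{\alpha}, mismatch \eqn{\beta},
#' indel \eqn{\delta}), the uniform gap score \eqn{g} used on the tensor
#' edges, and the sum-of-pairs weight \eqn{W} that divides the pairwise
#' score sum of columns in which all three sequences carry a letter.
#'
#' @slot matchScore positive match score \eqn{\alpha}.
#' @slot mismatchScore negative mismatch score \eqn{\beta}.
#' @slot indelScore negative indel score \eqn{\delta}.
#' @slot edgeGap uniform gap score \eqn{g} applied on the edges of the
#'   dynamic programming tensor; defaults to \code{indelScore}.
#' @slot sopWeight sum-of-pairs weight \eqn{W \ge 1}.
#' @seealso [ScoringScheme()], [sigmaScore()], [gammaScore()]
#' @exportClass ScoringScheme
setClass("ScoringScheme",
    representation(
        matchScore    = "numeric",
        mismatchScore = "numeric",
        indelScore    = "numeric",
        edgeGap       = "numeric",
        sopWeight     = "numeric"
    )
)

setValidity("ScoringScheme", function(object) {
    msg <- character()
    if (length(object@matchScore) != 1L || !is.finite(object@matchScore) ||
        object@matchScore <= 0)
        msg <- c(msg, "matchScore must be a single positive number")
    if (length(object@mismatchScore) != 1L || !is.finite(object@mismatchScore) ||
        object@mismatchScore >= 0)
        msg <- c(msg, "mismatchScore must be negative")
    if (length(object@indelScore) != 1L || !is.finite(object@indelScore) ||
        object@indelScore >= 0)
        msg <- c(msg, "indelScore must be negative")
    if (length(object@edgeGap) != 1L || !is.finite(object@edgeGap))
        msg <- c(msg, "edgeGap must be a single finite number")
    if (length(object@sopWeight) != 1L || !is.finite(object@sopWeight) ||
        object@sopWeight < 1)
        msg <- c(msg, "sopWeight must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Dynamic programming state of the three-way aligner
#'
#' The three-dimensional score tensor \code{S} (dimensions
#' \code{(m+1) x (n+1) x (p+1)} for sequence lengths \code{m}, \code{n},
#' \code{p}), the matrix \code{M} of optimal scores of an F-R alignment
#' continuing after the aligned part of L, and the prefix-maximum array
#' \code{mtilde[i] = max_{i'<i} max_j S[i',j,0]} (1-based storage:
#' \code{mtilde[i+1]} holds the value for reference prefix length
#' \code{i}).  \code{M} and \code{mtilde} are empty until [fillMatrix()]
#' has been applied.
#'
#' @slot S numeric 3d array of prefix alignment scores.
#' @slot M numeric matrix, empty until completed.
#' @slot mtilde numeric vector, empty until completed.
#' @seealso [fillTensor()], [fillMatrix()]
#' @exportClass DPState
setClass("DPState",
    representation(S = "array", M = "matrix", mtilde = "numeric")
)

setValidity("DPState", function(object) {
    d <- dim(object@S)
    if (length(d) != 3L)
        return("S must be a three-dimensional array")
    if (length(object@mtilde) && length(object@mtilde) != d[1L])
        return("mtilde length must equal dim(S)[1]")
    if (length(object@M) && !identical(dim(object@M), d[c(1L, 3L)]))
        return("M must have dimensions dim(S)[c(1,3)]")
    TRUE
})

#' Partially local three-way alignment
#'
#' Column-wise alignment of the reference \code{F} and the two derived
#' fragments \code{L} and \code{R}.  Each column carries a region tag:
#' \code{FL} (pairwise F-L part), \code{FLR} (three-way part, including
#' columns in which one row is gapped), \code{FR} (pairwise F-R part
#' after the end of L's aligned region), and the unscored regions
#' \code{F_FREE} (reference interval between the fragments), \code{L_FREE}
#' (unaligned suffix of L) and \code{R_FREE} (unaligned prefix of R).
#'
#' @slot seqF,seqL,seqR the input sequences ([Biostrings::DNAString]).
#' @slot alignedF,alignedL,alignedR gapped rows (character, '-' gaps).
#' @slot regions per-column region tag (character vector).
#' @slot score optimal alignment score.
#' @slot lEndInF 1-based reference position of the last F letter in a
#'   column containing an L letter (0 if none).
#' @slot rStartInF 1-based reference position of the first F letter in a
#'   column containing an R letter (0 if none).
#' @slot scheme the [ScoringScheme] used.
#' @seealso [alignBreakpoint()], [measureOverlap()], [writeStockholm()]
#' @exportClass TriAlignment
setClass("TriAlignment",
    representation(
        seqF = "DNAString", seqL = "DNAString", seqR = "DNAString",
        alignedF = "character", alignedL = "character", alignedR = "character",
        regions = "character",
        score = "numeric",
        lEndInF = "integer", rStartInF = "integer",
        scheme = "ScoringScheme"
    )
)

.REGION_TAGS <- c("FL", "FLR", "FR", "F_FREE", "L_FREE", "R_FREE")

setValidity("TriAlignment", function(object) {
    msg <- character()
    w <- nchar(object@alignedF)
    if (nchar(object@alignedL) != w || nchar(object@alignedR) != w)
        msg <- c(msg, "aligned rows must have equal width")
    if (length(object@regions) != w)
        msg <- c(msg, "one region tag per column required")
    if (!all(object@regions %in% .REGION_TAGS))
        msg <- c(msg, "invalid region tag")
    if (gsub("-", "", object@alignedF, fixed = TRUE) != as.character(object@seqF))
        msg <- c(msg, "row F does not spell the input sequence F")
    if (gsub("-", "", object@alignedL, fixed = TRUE) != as.character(object@seqL))
        msg <- c(msg, "row L does not spell the input sequence L")
    if (gsub("-", "", object@alignedR, fixed = TRUE) != as.character(object@seqR))
        msg <- c(msg, "row R does not spell the input sequence R")
    if (w > 0) {
        cf <- strsplit(object@alignedF, "")[[1L]]
        cl <- strsplit(object@alignedL, "")[[1L]]
        cr <- strsplit(object@alignedR, "")[[1L]]
        if (any(cf == "-" & cl == "-" & cr == "-"))
            msg <- c(msg, "all-gap column")
    }
    if (length(msg)) msg else TRUE
})

#' Breakpoint geometry measured from an alignment
#'
#' Classification of a [TriAlignment] as \code{overlap} (columns from the
#' first to the last position at which all of F, L and R are aligned),
#' \code{gap} (reference nucleotides between L's and R's aligned regions
#' matched by neither fragment) or \code{flush} (the fragments abut
#' exactly).  \code{signedValue} is \code{+length} for an overlap,
#' \code{-length} for a gap and 0 for flush.
#'
#' @slot kind one of "overlap", "gap", "flush".
#' @slot length overlap length in alignment columns, or gap length in
#'   reference nucleotides.
#' @slot signedValue signed overlap (negative = gap).
#' @slot degenerate TRUE when the alignment lacks an L-containing or an
#'   R-containing column so that the geometry is undefined.
#' @seealso [measureOverlap()]
#' @exportClass BreakpointGeometry
setClass("BreakpointGeometry",
    representation(kind = "character", length = "integer",
                   signedValue = "integer", degenerate = "logical")
)

setValidity("BreakpointGeometry", function(object) {
    if (!object@kind %in% c("overlap", "gap", "flush"))
        return("kind must be overlap, gap or flush")
    if (object@kind == "flush" && object@length != 0L)
        return("flush implies length 0")
    expected <- switch(object@kind, overlap = object@length,
                       gap = -object@length, flush = 0L)
    if (object@signedValue != expected)
        return("signedValue inconsistent with kind/length")
    TRUE
})

#' Synthetic breakpoint-region instance
#'
#' One simulated (F, L, R) triple with a designed overlap or gap of known
#' length, as produced by [makeInstance()].
#'
#' @slot seqF,seqL,seqR the sequences ([Biostrings::DNAString]).
#' @slot truthKind "overlap" or "gap".
#' @slot truthLength designed overlap/gap length in nucleotides.
#' @slot mutationRate position-wise substitution probability applied to
#'   the homologous portions of L and R.
#' @slot seed RNG seed the instance was generated from.
#' @seealso [makeInstance()], [runScan()]
#' @exportClass SimInstance
setClass("SimInstance",
    representation(
        seqF = "DNAString", seqL = "DNAString", seqR = "DNAString",
        truthKind = "character", truthLength = "integer",
        mutationRate = "numeric", seed = "integer"
    )
)

#' Extracted breakpoint region
#'
#' The (F, L, R) triple extracted from a pair of annotated genomes for
#' one breakpoint, with provenance (coordinate windows, strands,
#' reverse-complement flags, reference intergenic length) and an optional
#' exclusion reason set by [applyFilters()].
#'
#' @slot seqF,seqL,seqR the sequences ([Biostrings::DNAString]).
#' @slot provenance named list of extraction metadata.
#' @slot exclusion exclusion reason, or NA when the region is retained.
#' @seealso [extractBreakpointRegion()], [applyFilters()]
#' @exportClass BreakpointRegion
setClass("BreakpointRegion",
    representation(
        seqF = "DNAString", seqL = "DNAString", seqR = "DNAString",
        provenance = "list", exclusion = "character"
    )
)
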