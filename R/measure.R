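# Overlap / gap statistic.

#' Measure breakpoint geometry from an alignment
#'
#' The overlap is the number of alignment columns from the first to the
#' last position at which all three sequences are aligned (intervening
#' columns count even when one row is gapped).  If no such column exists
#' and R's aligned region starts more than one reference position after
#' L's ends, the geometry is a gap whose length is the number of
#' reference nucleotides strictly between the two that are aligned to
#' neither fragment.  Otherwise the fragments abut exactly (flush).
#' Alignments lacking any L-containing or any R-containing column have
#' undefined geometry and are flagged degenerate.
#'
#' @param aln a \linkS4class{TriAlignment} from [alignBreakpoint()].
#' @return a \linkS4class{BreakpointGeometry}.
#' @examples
#' measureOverlap(alignBreakpoint("ACGT", "ACG", "CGT"))  # overlap 2
#' @export
measureOverlap <- function(aln) {
    cols <- alignmentColumns(aln)
    cf <- cols["F", ]; cl <- cols["L", ]; cr <- cols["R", ]
    hasL <- any(cl != "-"); hasR <- any(cr != "-")
    if (!hasL || !hasR)
        return(new("BreakpointGeometry", kind = "flush", length = 0L,
                   signedValue = 0L, degenerate = TRUE))
    triple <- which(cf != "-" & cl != "-" & cr != "-")
    if (length(triple)) {
        len <- max(triple) - min(triple) + 1L
        return(new("BreakpointGeometry", kind = "overlap",
                   length = as.integer(len),
                   signedValue = as.integer(len), degenerate = FALSE))
    }
    lEnd <- aln@lEndInF; rStart <- aln@rStartInF
    if (rStart > lEnd + 1L) {
        fpos <- cumsum(cf != "-")
        between <- cf != "-" & fpos > lEnd & fpos < rStart &
            cl == "-" & cr == "-"
        return(new("BreakpointGeometry", kind = "gap",
                   length = as.integer(sum(between)),
                   signedValue = -as.integer(sum(between)),
                   degenerate = FALSE))
    }
    new("BreakpointGeometry", kind = "flush", length = 0L,
        signedValue = 0L, degenerate = FALSE)
}

#' @describeIn measureOverlap display method
#' @param object a \code{BreakpointGeometry}.
#' @export
setMethod("show", "BreakpointGeometry", function(object) {
    cat(sprintf("BreakpointGeometry: %s, length %d (signed %+d)%s\n",
                object@kind, object@length, object@signedValue,
                if (object@degenerate) " [degenerate]" else ""))
    invisible(object)
})
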