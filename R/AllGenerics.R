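# Generics and accessors.  BiocGenerics::score is reused for alignment
# scores; everything else is small accessor generics.

#' @export
setGeneric("matchScore", function(x) standardGeneric("matchScore"))
#' @export
setGeneric("mismatchScore", function(x) standardGeneric("mismatchScore"))
#' @export
setGeneric("indelScore", function(x) standardGeneric("indelScore"))
#' @export
setGeneric("edgeGap", function(x) standardGeneric("edgeGap"))
#' @export
setGeneric("sopWeight", function(x) standardGeneric("sopWeight"))

#' @export
setGeneric("alignedRows", function(x) standardGeneric("alignedRows"))
#' @export
setGeneric("alignmentRegions", function(x) standardGeneric("alignmentRegions"))
#' @export
setGeneric("alignmentColumns", function(x) standardGeneric("alignmentColumns"))
#' @export
setGeneric("lEndInF", function(x) standardGeneric("lEndInF"))
#' @export
setGeneric("rStartInF", function(x) standardGeneric("rStartInF"))

#' @export
setGeneric("geometryKind", function(x) standardGeneric("geometryKind"))
#' @export
setGeneric("geometryLength", function(x) standardGeneric("geometryLength"))
#' @export
setGeneric("signedOverlap", function(x) standardGeneric("signedOverlap"))

#' @export
setGeneric("exclusionReason", function(x) standardGeneric("exclusionReason"))
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Accessors
#'
#' @param x a \linkS4class{ScoringScheme}, \linkS4class{TriAlignment},
#'   \linkS4class{BreakpointGeometry} or \linkS4class{BreakpointRegion}.
#' @return the corresponding slot value; see the class documentation.
#' @name accessors
#' @aliases matchScore mismatchScore indelScore edgeGap sopWeight
#'   alignedRows alignmentRegions alignmentColumns lEndInF rStartInF
#'   geometryKind geometryLength signedOverlap exclusionReason provenance
NULL

#' @describeIn accessors match score of a scheme
#' @export
setMethod("matchScore", "ScoringScheme", function(x) x@matchScore)
#' @describeIn accessors mismatch score of a scheme
#' @export
setMethod("mismatchScore", "ScoringScheme", function(x) x@mismatchScore)
#' @describeIn accessors indel score of a scheme
#' @export
setMethod("indelScore", "ScoringScheme", function(x) x@indelScore)
#' @describeIn accessors edge gap score of a scheme
#' @export
setMethod("edgeGap", "ScoringScheme", function(x) x@edgeGap)
#' @describeIn accessors sum-of-pairs weight of a scheme
#' @export
setMethod("sopWeight", "ScoringScheme", function(x) x@sopWeight)

#' @describeIn accessors alignment score
#' @importMethodsFrom BiocGenerics score
#' @export
setMethod("score", "TriAlignment", function(x, ...) x@score)

#' @describeIn accessors named character vector of the three gapped rows
#' @export
setMethod("alignedRows", "TriAlignment", function(x)
    c(F = x@alignedF, L = x@alignedL, R = x@alignedR))

#' @describeIn accessors per-column region tags
#' @export
setMethod("alignmentRegions", "TriAlignment", function(x) x@regions)

#' @describeIn accessors 3 x ncol character matrix of alignment columns
#' @export
setMethod("alignmentColumns", "TriAlignment", function(x) {
    m <- rbind(F = strsplit(x@alignedF, "")[[1L]],
               L = strsplit(x@alignedL, "")[[1L]],
               R = strsplit(x@alignedR, "")[[1L]])
    m
})

#' @describeIn accessors last F position aligned in an L-containing column
#' @export
setMethod("lEndInF", "TriAlignment", function(x) x@lEndInF)

#' @describeIn accessors first F position aligned in an R-containing column
#' @export
setMethod("rStartInF", "TriAlignment", function(x) x@rStartInF)

#' @describeIn accessors geometry kind ("overlap", "gap", "flush")
#' @export
setMethod("geometryKind", "BreakpointGeometry", function(x) x@kind)
#' @describeIn accessors overlap/gap length
#' @export
setMethod("geometryLength", "BreakpointGeometry", function(x) x@length)
#' @describeIn accessors signed overlap (+overlap, -gap, 0 flush)
#' @export
setMethod("signedOverlap", "BreakpointGeometry", function(x) x@signedValue)
#' @describeIn accessors signed overlap measured from an alignment
#' @export
setMethod("signedOverlap", "TriAlignment", function(x)
    signedOverlap(measureOverlap(x)))

#' @describeIn accessors exclusion reason of a region (NA if retained)
#' @export
setMethod("exclusionReason", "BreakpointRegion", function(x) x@exclusion)
#' @describeIn accessors extraction provenance list
#' @export
setMethod("provenance", "BreakpointRegion", function(x) x@provenance)
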