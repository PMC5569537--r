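# Readers and writers: FASTA input, Stockholm and plain-text alignment
# output.

#' Read breakpoint sequences from FASTA
#'
#' Reads a FASTA file with [Biostrings::readBStringSet()], uppercases the
#' residues, normalizes IUPAC ambiguity codes other than N to N (with a
#' warning) and validates the alphabet.  Empty files and duplicated
#' record identifiers are input errors.
#'
#' @param path FASTA file path.
#' @return a [Biostrings::DNAStringSet], one element per record.
#' @export
readBreakpointFasta <- function(path) {
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L) .inputError("no FASTA records in ", path)
    ids <- sub("\\s.*$", "", names(raw))
    if (anyDuplicated(ids))
        .inputError("duplicate FASTA identifiers in ", path)
    out <- Biostrings::DNAStringSet(lapply(seq_along(raw), function(q)
        .normalizeSeq(raw[[q]], what = ids[q])))
    names(out) <- ids
    out
}

.REGION_CHARS <- c(FL = "L", FLR = "O", FR = "R",
                   F_FREE = "f", L_FREE = "l", R_FREE = "r")

.regionLine <- function(regions)
    paste(.REGION_CHARS[regions], collapse = "")

#' Write an alignment in Stockholm 1.0 format
#'
#' One line per sequence (names F, L, R), a \code{#=GC region} line
#' carrying the per-column region tags as single characters (L = pairwise
#' F-L, O = three-way, R = pairwise F-R, f/l/r = unscored free regions),
#' and \code{#=GF SC} / \code{#=GF OV} metadata (score and signed
#' overlap).  [readStockholm()] round-trips the file bit-exactly.
#'
#' @param aln a \linkS4class{TriAlignment}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeStockholm <- function(aln, path) {
    if (nchar(aln@alignedF) != nchar(aln@alignedL) ||
        nchar(aln@alignedF) != nchar(aln@alignedR))
        stop("unequal alignment row lengths: corrupt TriAlignment")
    geom <- measureOverlap(aln)
    lines <- c(
        "# STOCKHOLM 1.0",
        sprintf("#=GF SC %.9g", aln@score),
        sprintf("#=GF OV %d", geom@signedValue),
        sprintf("F %s", aln@alignedF),
        sprintf("L %s", aln@alignedL),
        sprintf("R %s", aln@alignedR),
        sprintf("#=GC region %s", .regionLine(aln@regions)),
        "//")
    writeLines(lines, path)
    invisible(path)
}

#' Read an alignment written by [writeStockholm()]
#'
#' @param path Stockholm file path.
#' @param scheme scoring scheme to attach (the file does not store one).
#' @return a \linkS4class{TriAlignment} (score taken from the file).
#' @export
readStockholm <- function(path, scheme = ScoringScheme()) {
    lines <- readLines(path)
    if (!length(lines) || !startsWith(lines[1L], "# STOCKHOLM"))
        .inputError(path, " is not a Stockholm file")
    getSeq <- function(tag) {
        hit <- grep(paste0("^", tag, " "), lines, value = TRUE)
        if (length(hit) != 1L)
            .inputError("expected exactly one '", tag, "' row")
        sub(paste0("^", tag, "\\s+"), "", hit)
    }
    sc <- as.numeric(sub("^#=GF SC\\s+", "",
                         grep("^#=GF SC ", lines, value = TRUE)))
    rgn <- sub("^#=GC region\\s+", "",
               grep("^#=GC region ", lines, value = TRUE))
    regChars <- strsplit(rgn, "")[[1L]]
    regions <- names(.REGION_CHARS)[match(regChars, .REGION_CHARS)]
    if (anyNA(regions)) .inputError("unknown region tag character")
    af <- getSeq("F"); al <- getSeq("L"); ar <- getSeq("R")
    degap <- function(x) Biostrings::DNAString(gsub("-", "", x, fixed = TRUE))
    coords <- .coordFromColumns(strsplit(af, "")[[1L]],
                                strsplit(al, "")[[1L]],
                                strsplit(ar, "")[[1L]])
    aln <- new("TriAlignment", seqF = degap(af), seqL = degap(al),
               seqR = degap(ar), alignedF = af, alignedL = al,
               alignedR = ar, regions = regions, score = sc,
               lEndInF = coords$lEnd, rStartInF = coords$rStart,
               scheme = scheme)
    validObject(aln)
    aln
}

.formatAlignmentBlocks <- function(aln, width = 60L) {
    cf <- strsplit(aln@alignedF, "")[[1L]]
    cl <- strsplit(aln@alignedL, "")[[1L]]
    cr <- strsplit(aln@alignedR, "")[[1L]]
    rg <- strsplit(.regionLine(aln@regions), "")[[1L]]
    w <- length(cf)
    out <- character(0)
    starts <- seq(1L, max(w, 1L), by = width)
    for (s in starts) {
        e <- min(s + width - 1L, w)
        idx <- s:e
        out <- c(out,
                 sprintf("F    %s", paste(cf[idx], collapse = "")),
                 sprintf("L    %s", paste(cl[idx], collapse = "")),
                 sprintf("R    %s", paste(cr[idx], collapse = "")),
                 sprintf("rgn  %s", paste(rg[idx], collapse = "")),
                 "")
    }
    out
}

#' Write a human-readable alignment rendering
#'
#' Fixed-width blocks (60 columns by default) of the three rows plus an
#' annotation line of region characters; the overlap span is the run of
#' 'O' characters.  Output is deterministic.
#'
#' @param aln a \linkS4class{TriAlignment}.
#' @param path output path, or "" for stdout.
#' @param width block width in columns.
#' @return invisibly, the formatted lines.
#' @export
writeTextAlignment <- function(aln, path = "", width = 60L) {
    geom <- measureOverlap(aln)
    header <- sprintf(
        "# score %.9g  %s %d (signed %+d)  l_end_in_F %d  r_start_in_F %d",
        aln@score, geom@kind, geom@length, geom@signedValue,
        aln@lEndInF, aln@rStartInF)
    lines <- c(header, "", .formatAlignmentBlocks(aln, width))
    if (nzchar(path)) writeLines(lines, path) else writeLines(lines)
    invisible(lines)
}
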