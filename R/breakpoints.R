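# Breakpoints from signed gene orders and (F, L, R) extraction from
# annotated genomes.

.parseSigned <- function(tokens) {
    neg <- startsWith(tokens, "-")
    list(gene = sub("^-", "", tokens), sign = ifelse(neg, -1L, 1L))
}

.adjKey <- function(ga, sa, gb, sb) {
    k1 <- paste0(sa, ga, ">", sb, gb)
    k2 <- paste0(-sb, gb, ">", -sa, ga)   # reading the adjacency reversed
    pmin(k1, k2)
}

#' Find breakpoints between two signed gene orders
#'
#' A reference adjacency (a, b) is a breakpoint when it occurs in the
#' derived order neither as (a, b) with the same relative orientations
#' nor as the inverted reading (-b, -a).  For circular orders the
#' wrap-around adjacency is included and the result is invariant under
#' rotation of either order.
#'
#' @param refOrder,derivedOrder signed gene orders: character vectors of
#'   gene names, a leading \code{"-"} marking reverse orientation.  Both
#'   must be permutations of the same gene set.
#' @param circular treat the orders as circular (default TRUE, the
#'   mitochondrial case).
#' @return a data.frame with one row per breakpoint: \code{leftGene},
#'   \code{rightGene} (the disrupted reference adjacency) and
#'   \code{leftFlipped}, \code{rightFlipped} (orientation of the gene
#'   changed between the orders).
#' @examples
#' findBreakpoints(c("a","b","c","d"), c("a","-c","-b","d"),
#'                 circular = FALSE)   # (a,b) and (c,d); (b,c) survives
#' @export
findBreakpoints <- function(refOrder, derivedOrder, circular = TRUE) {
    ref <- .parseSigned(refOrder); der <- .parseSigned(derivedOrder)
    if (anyDuplicated(ref$gene) || anyDuplicated(der$gene))
        .inputError("duplicated gene names in a gene order")
    if (!setequal(ref$gene, der$gene))
        .inputError("gene orders are over different gene sets")
    nr <- length(ref$gene)
    if (nr < 2L) .inputError("gene orders need at least two genes")

    adjIdx <- function(n) {
        i <- seq_len(if (circular) n else n - 1L)
        cbind(i, ifelse(i == n, 1L, i + 1L))
    }
    ri <- adjIdx(nr)
    di <- adjIdx(length(der$gene))
    derKeys <- .adjKey(der$gene[di[, 1L]], der$sign[di[, 1L]],
                       der$gene[di[, 2L]], der$sign[di[, 2L]])
    refKeys <- .adjKey(ref$gene[ri[, 1L]], ref$sign[ri[, 1L]],
                       ref$gene[ri[, 2L]], ref$sign[ri[, 2L]])
    broken <- !(refKeys %in% derKeys)
    derSign <- setNames(der$sign, der$gene)
    lg <- ref$gene[ri[broken, 1L]]
    rg <- ref$gene[ri[broken, 2L]]
    data.frame(leftGene = lg, rightGene = rg,
               leftFlipped = derSign[lg] != ref$sign[ri[broken, 1L]],
               rightFlipped = derSign[rg] != ref$sign[ri[broken, 2L]],
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a gene annotation table
#'
#' Accepts a 1-based inclusive TSV with columns gene, start, end, strand,
#' or BED (0-based half-open; converted at the boundary; the name column
#' supplies the gene).
#'
#' @param path file path.
#' @param format "tsv" or "bed".
#' @return a data.frame with columns gene, start, end, strand.
#' @export
readGeneAnnotation <- function(path, format = c("tsv", "bed")) {
    format <- match.arg(format)
    if (format == "tsv") {
        x <- read.table(path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
        need <- c("gene", "start", "end", "strand")
        if (!all(need %in% names(x)))
            .inputError("annotation TSV needs columns ",
                        paste(need, collapse = ", "))
        x <- x[, need]
    } else {
        x <- read.table(path, header = FALSE, sep = "\t",
                        stringsAsFactors = FALSE)
        if (ncol(x) < 6L)
            .inputError("BED annotation needs 6 columns (incl. name, strand)")
        x <- data.frame(gene = x[[4L]], start = x[[2L]] + 1L, end = x[[3L]],
                        strand = x[[6L]], stringsAsFactors = FALSE)
    }
    .checkAnnotation(x)
    x
}

.checkAnnotation <- function(annot) {
    if (anyDuplicated(annot$gene))
        .inputError("duplicated gene names in annotation")
    if (any(annot$start < 1L) || any(annot$end < annot$start))
        .inputError("invalid annotation coordinates")
    if (!all(annot$strand %in% c("+", "-")))
        .inputError("annotation strand must be + or -")
    invisible(annot)
}

#' Signed gene order implied by an annotation
#'
#' Genes sorted by genomic start; genes on the minus strand get a leading
#' \code{"-"}.
#'
#' @param annot annotation data.frame (gene, start, end, strand).
#' @param ignoreFeatures feature names to drop (e.g. a control region)
#'   before the order is formed.
#' @return character vector of signed gene tokens.
#' @export
geneOrderFromAnnotation <- function(annot, ignoreFeatures = character()) {
    .checkAnnotation(annot)
    annot <- annot[!annot$gene %in% ignoreFeatures, , drop = FALSE]
    annot <- annot[order(annot$start), , drop = FALSE]
    paste0(ifelse(annot$strand == "-", "-", ""), annot$gene)
}

# Forward-strand window [from..to] in absolute coordinates that may run
# past the origin of a circular genome.
.windowSeq <- function(genome, from, to, circular) {
    len <- length(genome)
    if (to < from) .inputError("empty or inverted extraction window")
    if (!circular && (from < 1L || to > len))
        .inputError("window outside a linear genome")
    pos <- ((seq.int(from, to) - 1L) %% len) + 1L
    paste(strsplit(as.character(genome), "")[[1L]][pos], collapse = "")
}

.annotRow <- function(annot, gene) {
    i <- which(annot$gene == gene)
    if (length(i) != 1L) .inputError("gene not annotated (once): ", gene)
    annot[i, , drop = FALSE]
}

# Successor/predecessor of a gene in genomic start order (circular).
# On a linear genome a terminal gene has no neighbor: NA when missingOK,
# so callers can fall back to the genome end.
.neighbor <- function(annot, gene, dir = c("next", "prev"), circular = TRUE,
                      missingOK = FALSE) {
    dir <- match.arg(dir)
    ord <- order(annot$start)
    genes <- annot$gene[ord]
    i <- match(gene, genes)
    n <- length(genes)
    j <- if (dir == "next") i + 1L else i - 1L
    if (j < 1L || j > n) {
        if (!circular) {
            if (missingOK) return(NA_character_)
            .inputError("gene ", gene, " has no ", dir,
                        " neighbor on a linear genome")
        }
        j <- ((j - 1L) %% n) + 1L
    }
    genes[j]
}

#' Extract the reference breakpoint region F
#'
#' F is the forward-strand genomic window running from the last
#' \code{flank} nucleotides of the left gene, across the intergenic
#' region if there is one, to the first \code{flank} nucleotides of the
#' right gene (flanks capped at gene length).  The two genes must be
#' adjacent in the annotation; the window may wrap the origin of a
#' circular genome.
#'
#' @param genome a [Biostrings::DNAString] (or character).
#' @param annot annotation data.frame (gene, start, end, strand).
#' @param bp breakpoint: list or one-row data.frame with \code{leftGene}
#'   and \code{rightGene} (as from [findBreakpoints()]).
#' @param flank flank length in nucleotides (default 60).
#' @param circular is the genome circular?
#' @return a [Biostrings::DNAString]; its \code{metadata}-like provenance
#'   is available through [extractBreakpointRegion()].
#' @export
extractReference <- function(genome, annot, bp, flank = 60L,
                             circular = TRUE) {
    genome <- .normalizeSeq(genome, "genome")
    .checkAnnotation(annot)
    if (flank < 1L) .inputError("flank must be >= 1")
    left <- .annotRow(annot, bp$leftGene)
    right <- .annotRow(annot, bp$rightGene)
    nb <- .neighbor(annot, bp$leftGene, "next", circular, missingOK = TRUE)
    if (is.na(nb) || nb != bp$rightGene)
        .inputError("genes ", bp$leftGene, " and ", bp$rightGene,
                    " are not adjacent in the reference annotation")
    len <- length(genome)
    flankL <- min(flank, left$end - left$start + 1L)
    flankR <- min(flank, right$end - right$start + 1L)
    rightStart <- right$start
    if (rightStart <= left$end) rightStart <- rightStart + len  # wraps origin
    Biostrings::DNAString(.windowSeq(genome, left$end - flankL + 1L,
                                     rightStart + flankR - 1L, circular))
}

# Intergenic length between adjacent reference genes (possibly wrapping).
.refIntergenic <- function(genome, annot, bp) {
    left <- .annotRow(annot, bp$leftGene)
    right <- .annotRow(annot, bp$rightGene)
    d <- right$start - left$end - 1L
    if (d < 0L) d <- d + length(.normalizeSeq(genome, "genome"))
    as.integer(d)
}

#' Extract the derived query fragments L and R
#'
#' On the derived genome, L is the last \code{flank} nucleotides of the
#' left query gene followed by the intergenic region toward its new
#' neighbor, and R is the intergenic region preceding the right query
#' gene followed by its first \code{flank} nucleotides.  For a gene whose
#' orientation flipped (inversion), the neighbor direction is mirrored
#' and the extracted query is reverse-complemented before alignment.
#'
#' @inheritParams extractReference
#' @param bp breakpoint with \code{leftGene}, \code{rightGene} and
#'   logical \code{leftFlipped}, \code{rightFlipped}.
#' @return list with elements \code{L} and \code{R}
#'   ([Biostrings::DNAString]) and \code{windows} (coordinate/strand
#'   provenance).
#' @export
extractQueries <- function(genome, annot, bp, flank = 60L, circular = TRUE) {
    genome <- .normalizeSeq(genome, "genome")
    .checkAnnotation(annot)
    if (flank < 1L) .inputError("flank must be >= 1")
    len <- length(genome)
    leftFlipped <- isTRUE(as.logical(bp$leftFlipped))
    rightFlipped <- isTRUE(as.logical(bp$rightFlipped))

    span <- function(from, to) {      # absolute, allow to wrap forward
        if (to < from) to <- to + len
        c(from, to)
    }
    nextStart <- function(gene) {      # start of the following gene, or
        nb <- .neighbor(annot, gene, "next", circular, missingOK = TRUE)
        if (is.na(nb)) len + 1L else {
            s <- .annotRow(annot, nb)$start
            if (s <= .annotRow(annot, gene)$end) s + len else s
        }
    }
    prevEnd <- function(gene) {        # end of the preceding gene, or 0
        nb <- .neighbor(annot, gene, "prev", circular, missingOK = TRUE)
        if (is.na(nb)) 0L else {
            e <- .annotRow(annot, nb)$end
            if (e >= .annotRow(annot, gene)$start) e - len else e
        }
    }

    gL <- .annotRow(annot, bp$leftGene)
    flankL <- min(flank, gL$end - gL$start + 1L)
    if (!leftFlipped) {
        w <- span(gL$end - flankL + 1L, nextStart(bp$leftGene) - 1L)
        Lseq <- Biostrings::DNAString(.windowSeq(genome, w[1L], w[2L], circular))
        Lrc <- FALSE
    } else {
        w <- span(prevEnd(bp$leftGene) + 1L, gL$start + flankL - 1L)
        Lseq <- Biostrings::reverseComplement(
            Biostrings::DNAString(.windowSeq(genome, w[1L], w[2L], circular)))
        Lrc <- TRUE
    }

    gR <- .annotRow(annot, bp$rightGene)
    flankR <- min(flank, gR$end - gR$start + 1L)
    if (!rightFlipped) {
        w2 <- span(prevEnd(bp$rightGene) + 1L, gR$start + flankR - 1L)
        Rseq <- Biostrings::DNAString(.windowSeq(genome, w2[1L], w2[2L], circular))
        Rrc <- FALSE
    } else {
        w2 <- span(gR$end - flankR + 1L, nextStart(bp$rightGene) - 1L)
        Rseq <- Biostrings::reverseComplement(
            Biostrings::DNAString(.windowSeq(genome, w2[1L], w2[2L], circular)))
        Rrc <- TRUE
    }
    list(L = Lseq, R = Rseq,
         windows = list(L = list(from = w[1L], to = w[2L], revcomp = Lrc),
                        R = list(from = w2[1L], to = w2[2L], revcomp = Rrc)))
}

#' Extract a complete breakpoint region (F, L, R)
#'
#' Convenience wrapper combining [extractReference()] on the reference
#' genome with [extractQueries()] on the derived genome, recording
#' provenance (windows, flips, reference intergenic length).
#'
#' @param refGenome,qryGenome sequences ([Biostrings::DNAString] or
#'   character) of the reference (ancestral state) and derived genome.
#' @param refAnnot,qryAnnot annotation data.frames.
#' @inheritParams extractQueries
#' @param labels optional character(2): genome labels for provenance.
#' @return a \linkS4class{BreakpointRegion}.
#' @export
extractBreakpointRegion <- function(refGenome, refAnnot, qryGenome, qryAnnot,
                                    bp, flank = 60L, circular = TRUE,
                                    labels = c("ref", "qry")) {
    Fseq <- extractReference(refGenome, refAnnot, bp, flank, circular)
    q <- extractQueries(qryGenome, qryAnnot, bp, flank, circular)
    new("BreakpointRegion", seqF = Fseq, seqL = q$L, seqR = q$R,
        provenance = list(
            labels = labels,
            leftGene = bp$leftGene, rightGene = bp$rightGene,
            leftFlipped = isTRUE(as.logical(bp$leftFlipped)),
            rightFlipped = isTRUE(as.logical(bp$rightFlipped)),
            flank = as.integer(flank),
            refIntergenic = .refIntergenic(refGenome, refAnnot, bp),
            queryWindows = q$windows),
        exclusion = NA_character_)
}

#' Apply the breakpoint-region exclusion filters
#'
#' A region is excluded from statistics when the reference sequence
#' contains an intergenic stretch longer than \code{maxRefIntergenic}
#' nucleotides, or when after alignment the aligned span of L or of R
#' within F covers fewer than \code{minQueryInF} reference nucleotides.
#' Excluded regions are returned with the exclusion reason set, not
#' dropped.
#'
#' @param region a \linkS4class{BreakpointRegion}.
#' @param aln optional precomputed \linkS4class{TriAlignment}; computed
#'   with \code{scheme} when missing.
#' @param maxRefIntergenic maximum tolerated reference intergenic length.
#' @param minQueryInF minimum reference nucleotides each query must align.
#' @param scheme scoring scheme for the alignment-based filter.
#' @return the region, possibly with \code{exclusionReason()} set.
#' @export
applyFilters <- function(region, aln = NULL, maxRefIntergenic = 40L,
                         minQueryInF = 10L, scheme = ScoringScheme()) {
    ig <- region@provenance$refIntergenic
    if (!is.null(ig) && ig > maxRefIntergenic) {
        region@exclusion <- "ref_intergenic_gt_40"
        return(region)
    }
    if (is.null(aln))
        aln <- alignBreakpoint(region@seqF, region@seqL, region@seqR, scheme)
    cols <- alignmentColumns(aln)
    spanL <- sum(cols["F", ] != "-" & cols["L", ] != "-")
    spanR <- sum(cols["F", ] != "-" & cols["R", ] != "-")
    if (min(spanL, spanR) < minQueryInF)
        region@exclusion <- "query_lt_10_in_F"
    region
}

#' @describeIn extractBreakpointRegion display method
#' @param object a \code{BreakpointRegion}.
#' @export
setMethod("show", "BreakpointRegion", function(object) {
    cat(sprintf("BreakpointRegion %s|%s: |F| %d, |L| %d, |R| %d%s\n",
                object@provenance$leftGene, object@provenance$rightGene,
                length(object@seqF), length(object@seqL), length(object@seqR),
                if (!is.na(object@exclusion))
                    paste0(" [excluded: ", object@exclusion, "]") else ""))
    invisible(object)
})

#' Run the full breakpoint pipeline on one genome pair
#'
#' Derives the signed gene orders from the two annotations, finds the
#' breakpoints, extracts each (F, L, R) region, aligns it, measures the
#' overlap/gap and applies the exclusion filters.
#'
#' @inheritParams extractBreakpointRegion
#' @param scheme scoring scheme.
#' @param flank flank length (default 60).
#' @param ignoreFeatures feature names dropped before the gene orders are
#'   compared (e.g. control regions).
#' @param pairId label used in the report.
#' @return a data.frame with one row per breakpoint: pair_id, breakpoint
#'   (left|right), score, signed_overlap, l_end_in_F, r_start_in_F,
#'   exclusion_reason.
#' @export
breakpointPipeline <- function(refGenome, refAnnot, qryGenome, qryAnnot,
                               scheme = ScoringScheme(), flank = 60L,
                               circular = TRUE,
                               ignoreFeatures = character(),
                               pairId = "pair") {
    refAnnot <- refAnnot[!refAnnot$gene %in% ignoreFeatures, , drop = FALSE]
    qryAnnot <- qryAnnot[!qryAnnot$gene %in% ignoreFeatures, , drop = FALSE]
    bps <- findBreakpoints(geneOrderFromAnnotation(refAnnot),
                           geneOrderFromAnnotation(qryAnnot), circular)
    rows <- lapply(seq_len(nrow(bps)), function(b) {
        bp <- as.list(bps[b, ])
        region <- extractBreakpointRegion(refGenome, refAnnot, qryGenome,
                                          qryAnnot, bp, flank, circular)
        aln <- alignBreakpoint(region@seqF, region@seqL, region@seqR, scheme)
        region <- applyFilters(region, aln, scheme = scheme)
        geom <- measureOverlap(aln)
        data.frame(pair_id = pairId,
                   breakpoint = paste0(bp$leftGene, "|", bp$rightGene),
                   score = score(aln),
                   signed_overlap = geom@signedValue,
                   l_end_in_F = aln@lEndInF,
                   r_start_in_F = aln@rStartInF,
                   exclusion_reason = region@exclusion,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
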