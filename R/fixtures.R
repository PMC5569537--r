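# Packaged toy-genome fixture generator: two small circular genomes
# related by a single planted rearrangement, so the whole pipeline can be
# exercised offline with a known expected geometry.

.assembleGenome <- function(elems) {
    seqs <- vapply(elems, function(e) paste(e$seq, collapse = ""),
                   character(1L))
    lens <- nchar(seqs)
    starts <- cumsum(c(1L, head(lens, -1L)))
    isGene <- vapply(elems, function(e) e$type == "gene", logical(1L))
    annot <- data.frame(
        gene = vapply(elems[isGene], `[[`, character(1L), "name"),
        start = starts[isGene],
        end = starts[isGene] + lens[isGene] - 1L,
        strand = "+", stringsAsFactors = FALSE)
    list(genome = Biostrings::DNAString(paste(seqs, collapse = "")),
         annot = annot)
}

#' Toy circular genome pair with a planted rearrangement
#'
#' Builds a reference genome of six forward-strand genes separated by
#' short intergenic spacers and a derived genome related to it by either
#' a clean cut-and-paste transposition of one gene (expected geometry at
#' the g2|g3 breakpoint: flush, signed overlap 0) or a tandem duplication
#' of a \code{dupLen}-nucleotide block spanning the g2/g3 boundary
#' followed by complementary losses, leaving pseudogene remnants
#' (expected: overlap of exactly \code{dupLen}).  Gene sequences are
#' drawn over \{A,C\} and spacers over \{G,T\}, so sequence homology
#' exists exactly where it was planted and the expected geometry is
#' unambiguous.
#'
#' @param type "transposition" or "tdrl".
#' @param seed integer seed.
#' @param geneLength,intergenicLength element sizes in nucleotides.
#' @param dupLen duplicated block length for the tdrl fixture (split as
#'   evenly as possible across the g2/g3 boundary).
#' @return list with elements \code{ref} and \code{qry} (each a list with
#'   \code{genome} and \code{annot}), \code{breakpoint} (the tested g2|g3
#'   breakpoint) and \code{truth} (expected kind and signed overlap).
#' @examples
#' fx <- toyGenomePair("tdrl", seed = 7)
#' fx$truth
#' @export
toyGenomePair <- function(type = c("transposition", "tdrl"), seed = 101L,
                          geneLength = 200L, intergenicLength = 10L,
                          dupLen = 12L) {
    type <- match.arg(type)
    set.seed(as.integer(seed))
    geneNames <- paste0("g", 1:6)
    genes <- setNames(lapply(geneNames, function(n)
        sample(c("A", "C"), geneLength, replace = TRUE)), geneNames)
    spacerPatterns <- c(I12 = "GT", I23 = "G", I34 = "T", I45 = "TG",
                        I56 = "GGT", I61 = "TTG")
    ig <- lapply(spacerPatterns, function(p)
        strsplit(strrep(p, intergenicLength), "")[[1L]][
            seq_len(intergenicLength)])

    if (type == "transposition") {
        truth <- list(kind = "flush", signed = 0L)
    } else {
        ig$I23 <- character(0)               # genes abut at the breakpoint
        truth <- list(kind = "overlap", signed = as.integer(dupLen))
    }

    el <- function(name, seq, type) list(name = name, seq = seq, type = type)
    gene <- function(n) el(n, genes[[n]], "gene")
    spacer <- function(n) el(n, ig[[n]], "intergenic")
    refElems <- list(gene("g1"), spacer("I12"), gene("g2"), spacer("I23"),
                     gene("g3"), spacer("I34"), gene("g4"), spacer("I45"),
                     gene("g5"), spacer("I56"), gene("g6"), spacer("I61"))
    if (type == "transposition") {
        # excise (I23, g3), reinsert between g5 and I56
        qryElems <- list(gene("g1"), spacer("I12"), gene("g2"), spacer("I34"),
                         gene("g4"), spacer("I45"), gene("g5"), spacer("I23"),
                         gene("g3"), spacer("I56"), gene("g6"), spacer("I61"))
    } else {
        a <- dupLen %/% 2L; b <- dupLen - a
        remA <- el("remA", tail(genes$g2, a), "intergenic")
        remB <- el("remB", head(genes$g3, b), "intergenic")
        qryElems <- list(gene("g1"), spacer("I12"), remA, gene("g3"),
                         gene("g2"), remB, spacer("I34"), gene("g4"),
                         spacer("I45"), gene("g5"), spacer("I56"),
                         gene("g6"), spacer("I61"))
    }
    list(ref = .assembleGenome(refElems),
         qry = .assembleGenome(qryElems),
         breakpoint = list(leftGene = "g2", rightGene = "g3",
                           leftFlipped = FALSE, rightFlipped = FALSE),
         truth = truth)
}
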