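test_that("breakpoints are the reference adjacencies lost in the derived order", {
    bp <- findBreakpoints(c("a", "b", "c", "d"), c("a", "c", "b", "d"),
                          circular = FALSE)
    expect_setequal(paste(bp$leftGene, bp$rightGene),
                    c("a b", "b c", "c d"))
    expect_equal(nrow(findBreakpoints(c("a", "b", "c"), c("a", "b", "c"),
                                      circular = FALSE)), 0L)
    # an inverted block conserves its internal adjacency
    bp2 <- findBreakpoints(c("a", "b", "c", "d"), c("a", "-c", "-b", "d"),
                           circular = FALSE)
    expect_setequal(paste(bp2$leftGene, bp2$rightGene), c("a b", "c d"))
    expect_true(all(bp2$leftFlipped == c(FALSE, TRUE)))
    expect_error(findBreakpoints(c("a", "b"), c("a", "x")), "gene sets")
})

test_that("circular breakpoint detection is rotation invariant", {
    ref <- c("a", "b", "c", "d", "e")
    der <- c("a", "c", "b", "d", "e")
    key <- function(bp) sort(paste(bp$leftGene, bp$rightGene))
    base <- key(findBreakpoints(ref, der, circular = TRUE))
    for (r in 1:4) {
        rot <- c(der[-seq_len(r)], der[seq_len(r)])
        expect_equal(key(findBreakpoints(ref, rot, circular = TRUE)), base)
    }
    # wrap-around adjacency participates
    expect_true(nrow(findBreakpoints(c("a", "b", "c"), c("b", "a", "c"),
                                     circular = TRUE)) > 0)
})

test_that("reference extraction spans flank + intergenic + flank", {
    set.seed(21)
    genome <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
    annot <- data.frame(gene = c("x", "y"), start = c(11L, 61L),
                        end = c(40L, 90L), strand = "+",
                        stringsAsFactors = FALSE)
    bp <- list(leftGene = "x", rightGene = "y")
    F <- extractReference(genome, annot, bp, flank = 10, circular = FALSE)
    expect_equal(as.character(F), substr(genome, 31, 70))
    expect_equal(length(F), 40L)
    # abutting genes: no intergenic part
    annot2 <- data.frame(gene = c("x", "y"), start = c(11L, 41L),
                         end = c(40L, 70L), strand = "+",
                         stringsAsFactors = FALSE)
    expect_equal(length(extractReference(genome, annot2, bp, flank = 10,
                                         circular = FALSE)), 20L)
    # flank capped at gene length
    annot3 <- data.frame(gene = c("x", "y"), start = c(35L, 41L),
                         end = c(40L, 70L), strand = "+",
                         stringsAsFactors = FALSE)
    expect_equal(length(extractReference(genome, annot3, bp, flank = 10,
                                         circular = FALSE)), 16L)
    expect_error(extractReference(genome, annot, list(leftGene = "y",
                                                      rightGene = "x"),
                                  flank = 10, circular = FALSE),
                 "not adjacent")
})

test_that("reference extraction crosses the origin of a circular genome", {
    set.seed(22)
    genome <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    annot <- data.frame(gene = c("y", "x"), start = c(11L, 41L),
                        end = c(30L, 60L), strand = "+",
                        stringsAsFactors = FALSE)
    F <- extractReference(genome, annot, list(leftGene = "x", rightGene = "y"),
                          flank = 5, circular = TRUE)
    expect_equal(as.character(F),
                 paste0(substr(genome, 56, 60), substr(genome, 1, 15)))
})

test_that("query extraction follows neighbors and handles inversions", {
    set.seed(23)
    genome <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    annot <- data.frame(gene = c("u", "v", "w"),
                        start = c(1L, 46L, 91L), end = c(30L, 75L, 110L),
                        strand = "+", stringsAsFactors = FALSE)
    q <- extractQueries(genome, annot,
                        list(leftGene = "u", rightGene = "w",
                             leftFlipped = FALSE, rightFlipped = FALSE),
                        flank = 10, circular = FALSE)
    expect_equal(as.character(q$L), substr(genome, 21, 45))    # 10 + 15 nt
    expect_equal(length(q$L), 25L)
    expect_equal(as.character(q$R), substr(genome, 76, 100))   # 15 + 10 nt
    # zero-length intergenic regions leave just the flank
    annot2 <- data.frame(gene = c("u", "v"), start = c(1L, 31L),
                         end = c(30L, 60L), strand = "+",
                         stringsAsFactors = FALSE)
    q2 <- extractQueries(genome, annot2,
                         list(leftGene = "u", rightGene = "v",
                              leftFlipped = FALSE, rightFlipped = FALSE),
                         flank = 10, circular = FALSE)
    expect_equal(length(q2$L), 10L)
    expect_equal(length(q2$R), 10L)
    # flipped right gene: neighbor direction mirrored (the region after
    # the gene, running to the genome end here) and reverse-complemented
    qf <- extractQueries(genome, annot,
                         list(leftGene = "u", rightGene = "w",
                              leftFlipped = FALSE, rightFlipped = TRUE),
                         flank = 10, circular = FALSE)
    expect_equal(as.character(qf$R),
                 as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(substr(genome, 101, 120)))))
})

test_that("a planted inverted duplication is recovered after revcomp", {
    # Derived genome where the right gene flipped: its first-flank block is
    # present in reverse complement; extraction must undo that so the
    # alignment still sees the duplication footprint.
    set.seed(24)
    core <- paste(sample(c("A", "C", "G", "T"), 140, TRUE), collapse = "")
    refAnnot <- data.frame(gene = c("a", "b"), start = c(1L, 71L),
                           end = c(70L, 140L), strand = "+",
                           stringsAsFactors = FALSE)
    bp <- list(leftGene = "a", rightGene = "b",
               leftFlipped = FALSE, rightFlipped = TRUE)
    # derived: a kept, b inverted in place (same coordinates, - strand)
    rc <- function(x) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(x)))
    derGenome <- paste0(substr(core, 1, 70), rc(substr(core, 71, 140)))
    derAnnot <- data.frame(gene = c("a", "b"), start = c(1L, 71L),
                           end = c(70L, 140L), strand = c("+", "-"),
                           stringsAsFactors = FALSE)
    Fref <- extractReference(core, refAnnot, bp, flank = 30,
                             circular = FALSE)
    q <- extractQueries(derGenome, derAnnot, bp, flank = 30,
                        circular = FALSE)
    # the de-inverted R equals the reference right flank exactly
    expect_equal(as.character(q$R), substr(core, 71, 100))
    aln <- alignBreakpoint(Fref, q$L, q$R)
    expect_equal(signedOverlap(aln), 0L)
})

test_that("exclusion filters follow the survey rules", {
    inst <- cleanInstance(m = 40L, t = 25L, s = 16L, seed = 31L)
    region <- new("BreakpointRegion",
                  seqF = Biostrings::DNAString(inst$F),
                  seqL = Biostrings::DNAString(inst$L),
                  seqR = Biostrings::DNAString(inst$R),
                  provenance = list(refIntergenic = 45L),
                  exclusion = NA_character_)
    expect_equal(exclusionReason(applyFilters(region)),
                 "ref_intergenic_gt_40")
    region@provenance$refIntergenic <- 0L
    expect_true(is.na(exclusionReason(applyFilters(region))))
    # query spanning fewer than 10 reference positions is excluded
    set.seed(32)
    f <- paste(sample(c("A", "C"), 60, TRUE), collapse = "")
    shortL <- paste0(substr(f, 1, 6), strrep("G", 24))
    r <- paste0(strrep("T", 6), substr(f, 11, 60))
    region2 <- new("BreakpointRegion",
                   seqF = Biostrings::DNAString(f),
                   seqL = Biostrings::DNAString(shortL),
                   seqR = Biostrings::DNAString(r),
                   provenance = list(refIntergenic = 0L),
                   exclusion = NA_character_)
    expect_equal(exclusionReason(applyFilters(region2)), "query_lt_10_in_F")
})

test_that("gene orders derive from annotations with strand signs", {
    annot <- data.frame(gene = c("b", "a", "c"), start = c(50L, 1L, 90L),
                        end = c(80L, 40L, 120L),
                        strand = c("-", "+", "+"), stringsAsFactors = FALSE)
    expect_equal(geneOrderFromAnnotation(annot), c("a", "-b", "c"))
    expect_equal(geneOrderFromAnnotation(annot, ignoreFeatures = "b"),
                 c("a", "c"))
})
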