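.mkAln <- function(f, l, r, regions, score = 0) {
    new("TriAlignment",
        seqF = Biostrings::DNAString(gsub("-", "", f)),
        seqL = Biostrings::DNAString(gsub("-", "", l)),
        seqR = Biostrings::DNAString(gsub("-", "", r)),
        alignedF = f, alignedL = l, alignedR = r, regions = regions,
        score = score,
        lEndInF = plalign:::.coordFromColumns(strsplit(f, "")[[1]],
                                              strsplit(l, "")[[1]],
                                              strsplit(r, "")[[1]])$lEnd,
        rStartInF = plalign:::.coordFromColumns(strsplit(f, "")[[1]],
                                                strsplit(l, "")[[1]],
                                                strsplit(r, "")[[1]])$rStart,
        scheme = ScoringScheme())
}

test_that("overlap spans first to last all-three column", {
    g <- measureOverlap(.mkAln("ACGT", "ACG-", "-CGT",
                               c("FL", "FLR", "FLR", "FR")))
    expect_equal(geometryKind(g), "overlap")
    expect_equal(geometryLength(g), 2L)
    expect_equal(signedOverlap(g), 2L)
    # intervening gapped columns count toward the span
    g2 <- measureOverlap(.mkAln("ACGGT", "ACG-T", "-CGGT",
                                c("FL", "FLR", "FLR", "FLR", "FLR")))
    expect_equal(geometryKind(g2), "overlap")
    expect_equal(geometryLength(g2), 4L)   # C..T span includes the L-gap col
})

test_that("gap counts reference positions aligned to neither fragment", {
    g <- measureOverlap(alignBreakpoint("ACGTAC", "AC", "AC"))
    expect_equal(geometryKind(g), "gap")
    expect_equal(geometryLength(g), 2L)
    expect_equal(signedOverlap(g), -2L)
})

test_that("abutting fragments are flush; one-sided alignments degenerate", {
    g <- measureOverlap(.mkAln("AC", "A-", "-C", c("FL", "FR")))
    expect_equal(geometryKind(g), "flush")
    expect_equal(signedOverlap(g), 0L)
    expect_false(g@degenerate)
    g2 <- measureOverlap(.mkAln("AC", "AC", "--", c("FL", "FL")))
    expect_true(g2@degenerate)
})

test_that("planted geometry is recovered exactly on clean instances", {
    # unique flanks (letters absent from F) so chance matches cannot blur
    for (cfg in list(list(t = 25L, s = 16L),      # overlap 10
                      list(t = 25L, s = 26L),      # flush
                      list(t = 18L, s = 26L))) {   # gap 7
        inst <- cleanInstance(m = 40L, t = cfg$t, s = cfg$s, seed = 5L)
        aln <- alignBreakpoint(inst$F, inst$L, inst$R)
        expect_equal(signedOverlap(aln), inst$signed)
        g <- measureOverlap(aln)
        expect_lte(geometryLength(g), 40L)
        if (geometryKind(g) == "overlap")
            expect_lte(geometryLength(g),
                       min(nchar(inst$F), nchar(inst$L), nchar(inst$R)))
    }
})
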