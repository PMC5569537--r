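test_that("tensor edges and the pairwise face are initialized correctly", {
    st <- fillTensor("ACGT", "ACG", "CGT", ScoringScheme(1, -1, -2))
    expect_equal(st@S[4, 1, 1], -6)          # S[3,0,0] = 3 g
    expect_equal(st@S[1, 1, 3], -8)          # S[0,0,2] = 2 * 2g
    expect_equal(st@S[1, 4, 1], -6)          # S[0,3,0] = 3 g
    # edge gap g decoupled from the interior indel score
    st2 <- fillTensor("ACGT", "ACG", "CGT",
                      ScoringScheme(1, -1, -2, edgeGap = -1))
    expect_equal(st2@S[4, 1, 1], -3)
    expect_equal(st2@S[1, 1, 3], -4)
    # k = 0 face is the global pairwise F-L alignment
    st3 <- fillTensor("AC", "AC", "", ScoringScheme(1, -1, -2))
    expect_equal(st3@S[3, 3, 1], 2)          # S[2,2,0]
})

test_that("the matrix M reproduces the hand-derived optima", {
    sch <- ScoringScheme(1, -1, -2)
    mAt <- function(F, L, R) {
        st <- fillMatrix(fillTensor(F, L, R, sch), F, L, R, sch)
        st@M[nchar(F) + 1L, nchar(R) + 1L]
    }
    expect_equal(mAt("ACGT", "AC", "GT"), 4)      # abutting junction
    expect_equal(mAt("ACGT", "ACG", "CGT"), 8)    # three-way overlap
    expect_equal(mAt("ACGTAC", "AC", "AC"), 4)    # free reference interval
    # mtilde is non-decreasing
    st <- fillMatrix(fillTensor("ACGTAC", "AC", "AC", sch),
                     "ACGTAC", "AC", "AC", sch)
    expect_true(all(diff(st@mtilde[-1L]) >= 0))
})

test_that("traceback reconstructs the expected optimal alignments", {
    aln <- alignBreakpoint("ACGT", "ACG", "CGT")
    expect_equal(score(aln), 8)
    expect_equal(unname(alignedRows(aln)), c("ACGT", "ACG-", "-CGT"))
    expect_equal(alignmentRegions(aln), c("FL", "FLR", "FLR", "FR"))
    expect_equal(lEndInF(aln), 3L)
    expect_equal(rStartInF(aln), 2L)

    aln2 <- alignBreakpoint("ACGTAC", "AC", "AC")
    expect_equal(score(aln2), 4)
    expect_equal(sum(alignmentRegions(aln2) == "F_FREE"), 2L)
    expect_equal(lEndInF(aln2), 2L)
    expect_equal(rStartInF(aln2), 5L)

    aln3 <- alignBreakpoint("ACGT", "ACGT", "ACGT")
    expect_equal(score(aln3), 12)
    expect_equal(alignmentRegions(aln3), rep("FLR", 4L))

    # degenerate reduction: empty R leaves a global F-L alignment
    aln4 <- alignBreakpoint("ACGT", "ACGT", "")
    expect_equal(score(aln4), 4)
    # empty F or L is outside the model
    expect_error(alignBreakpoint("", "AC", "AC"), "outside the model")
    expect_error(alignBreakpoint("AC", "", "AC"), "outside the model")
})

test_that("a clean constructed 40-nt instance recovers its 10-nt overlap", {
    inst <- cleanInstance(m = 40L, t = 25L, s = 16L, seed = 7L)
    aln <- alignBreakpoint(inst$F, inst$L, inst$R)
    expect_equal(signedOverlap(aln), 10L)
})

test_that("engine equals the brute-force oracle on random small instances", {
    set.seed(101)
    schemes <- gridSchemes()
    for (q in 1:60) {
        F <- randSeq(sample(1:5, 1))
        L <- randSeq(sample(1:5, 1))
        R <- if (runif(1) < 0.15) "" else randSeq(sample(1:5, 1))
        sch <- schemes[[sample(length(schemes), 1)]]
        expect_equal(score(alignBreakpoint(F, L, R, sch)),
                     bruteForceScore(F, L, R, sch), tolerance = 1e-9,
                     info = paste(F, L, R))
    }
    expect_error(bruteForceScore(randSeq(7), "AC", "AC"), "length <= 6")
})

test_that("rescoring the tagged columns reproduces the reported score", {
    set.seed(202)
    for (q in 1:25) {
        F <- randSeq(sample(4:12, 1), c("A", "C", "G", "T"))
        L <- randSeq(sample(4:12, 1), c("A", "C", "G", "T"))
        R <- randSeq(sample(0:12, 1), c("A", "C", "G", "T"))
        sch <- suppressWarnings(ScoringScheme(sample(1:3, 1), -sample(1:3, 1),
                                              -sample(1:3, 1),
                                              sopWeight = sample(1:3, 1)))
        aln <- alignBreakpoint(F, L, R, sch)
        expect_equal(rescoreAlignment(aln), score(aln), tolerance = 1e-9)
    }
})

test_that("the problem is symmetric under joint reversal and L/R swap", {
    rev1 <- function(x) paste(rev(strsplit(x, "")[[1L]]), collapse = "")
    set.seed(303)
    for (q in 1:20) {
        F <- randSeq(sample(3:10, 1), c("A", "C", "G", "T"))
        L <- randSeq(sample(2:10, 1), c("A", "C", "G", "T"))
        R <- randSeq(sample(2:10, 1), c("A", "C", "G", "T"))
        expect_equal(score(alignBreakpoint(F, L, R)),
                     score(alignBreakpoint(rev1(F), rev1(R), rev1(L))),
                     tolerance = 1e-9)
    }
})

test_that("score dominates the no-overlap concatenation structure", {
    set.seed(404)
    sch <- ScoringScheme()
    for (q in 1:15) {
        F <- randSeq(sample(6:14, 1), c("A", "C", "G", "T"))
        L <- randSeq(sample(3:8, 1), c("A", "C", "G", "T"))
        R <- randSeq(sample(3:8, 1), c("A", "C", "G", "T"))
        m <- nchar(F)
        concat <- max(vapply(0:m, function(s)
            nwScore(substr(F, 1, s), L, sch) +
                nwScore(substr(F, s + 1, m), R, sch), numeric(1)))
        expect_gte(score(alignBreakpoint(F, L, R, sch)), concat - 1e-9)
    }
})

test_that("matching outer context shifts the score by alpha per position", {
    inst <- cleanInstance(m = 30L, t = 18L, s = 12L, seed = 11L)
    base <- score(alignBreakpoint(inst$F, inst$L, inst$R))
    ext <- "ACCA"
    # prepend to F and L (outer left end), append to F and R (outer right)
    s2 <- score(alignBreakpoint(paste0(ext, inst$F), paste0(ext, inst$L),
                                inst$R))
    expect_equal(s2, base + nchar(ext))
    s3 <- score(alignBreakpoint(paste0(inst$F, ext), inst$L,
                                paste0(inst$R, ext)))
    expect_equal(s3, base + nchar(ext))
})
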