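test_that("sigma follows the pairwise scoring model", {
    sch <- ScoringScheme(1, -1, -2)
    expect_equal(sigmaScore("A", "A", sch), 1)
    expect_equal(sigmaScore("-", "-", sch), 0)
    expect_equal(sigmaScore("A", "-", sch), -2)
    expect_equal(sigmaScore("-", "A", sch), -2)
    expect_equal(sigmaScore("A", "C", sch), -1)
    # N is a mismatch against everything, including N
    for (x in c("A", "C", "G", "T", "N"))
        expect_equal(sigmaScore("N", x, sch), -1)
    expect_error(sigmaScore("X", "A", sch), "unknown symbol")
})

test_that("gamma is the (weighted) sum of pairs", {
    expect_equal(gammaScore("A", "A", "A", ScoringScheme(1, -1, -2)), 3)
    expect_equal(gammaScore("A", "C", "G",
                            ScoringScheme(1, -1, -2, sopWeight = 2)), -1.5)
    expect_equal(gammaScore("A", "-", "-", ScoringScheme(1, -1, -2)), -4)
    expect_error(gammaScore("-", "-", "-", ScoringScheme()), "all-gap")
})

test_that("gamma is symmetric and collapses correctly with gaps", {
    sch <- ScoringScheme(2, -1, -3, sopWeight = 2)
    letters4 <- c("A", "C", "G", "T")
    for (x in letters4) for (y in letters4) {
        # one gap present: divisor 1, value sigma(x,y) + 2 delta
        expect_equal(gammaScore(x, y, "-", sch),
                     sigmaScore(x, y, sch) + 2 * indelScore(sch))
        # permutation invariance on a letter triple
        for (z in letters4) {
            v <- gammaScore(x, y, z, sch)
            expect_equal(gammaScore(z, x, y, sch), v)
            expect_equal(gammaScore(y, z, x, sch), v)
        }
    }
    # with W = 1 gamma is the plain sum of pairs for every column type
    sch1 <- ScoringScheme(2, -1, -3, sopWeight = 1)
    expect_equal(gammaScore("A", "A", "A", sch1), 6)
    expect_equal(gammaScore("A", "A", "C", sch1), 2 - 1 - 1)
})

test_that("scheme validity constraints are enforced", {
    expect_error(ScoringScheme(match = 0), "positive")
    expect_error(ScoringScheme(mismatch = 1), "negative")
    expect_error(ScoringScheme(indel = 0.5), "negative")
    expect_error(ScoringScheme(sopWeight = 0.5), "sopWeight")
    expect_warning(ScoringScheme(1, -3, -1), "indel")
    expect_silent(ScoringScheme(1, -2, -2))
    # edge gap defaults to the indel score but is stored separately
    expect_equal(edgeGap(ScoringScheme(1, -1, -2)), -2)
    expect_equal(edgeGap(ScoringScheme(1, -1, -2, edgeGap = -1)), -1)
})
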