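# Exhaustive structure-enumeration oracle for tiny instances.
#
# Independent of the forward tensor/M recursion: the optimum is taken over
# all legal partially local structures, composed from
#   * a pairwise sigma-scored global F-L prefix (the k = 0 face),
#   * an optional gamma-scored three-way middle, entered either by paying
#     for R's first letters or by the free R-prefix jump (which requires
#     at least one F and one L letter already consumed),
#   * alternatively an unpenalized reference interval (with a free
#     R prefix) between the F-L part and the F-R part,
#   * a pairwise sigma-scored global F-R suffix,
# with L's unaligned suffix and R's unaligned prefix unscored.  The
# middle is maximized by a backward recursion over suffixes, a different
# decomposition than the engine's forward recursion.

#' Brute-force reference score for tiny instances
#'
#' Exhaustively maximizes over all legal partially local alignment
#' structures of F, L, R.  Only intended as a correctness oracle:
#' sequences are limited to length 6 and the scheme must have
#' \code{edgeGap == indelScore}.
#'
#' @inheritParams fillTensor
#' @return the optimal score (numeric scalar).
#' @examples
#' bruteForceScore("ACGT", "ACG", "CGT")   # 8
#' @export
bruteForceScore <- function(F, L, R, scheme = ScoringScheme()) {
    F <- .normalizeSeq(F, "F"); L <- .normalizeSeq(L, "L")
    R <- .normalizeSeq(R, "R")
    fI <- .encode(F); lI <- .encode(L); rI <- .encode(R)
    m <- length(fI); n <- length(lI); p <- length(rI)
    if (m > 6L || n > 6L || p > 6L)
        .inputError("oracle restricted to sequences of length <= 6")
    if (m == 0L || n == 0L)
        .inputError("empty F or L is outside the model")
    if (!isTRUE(all.equal(scheme@edgeGap, scheme@indelScore)))
        .inputError("oracle requires edgeGap == indelScore")
    de <- scheme@indelScore
    sg <- function(a, b) .sigmaInt(a, b, scheme)
    gm <- function(a, b, c) {
        s <- sg(a, b) + sg(a, c) + sg(b, c)
        if (a != 0L && b != 0L && c != 0L) s / scheme@sopWeight else s
    }

    # nwFL[i+1, j+1]: global pairwise alignment of F[1..i], L[1..j]
    nwFL <- matrix(0, m + 1L, n + 1L)
    for (i in 1L:(m + 1L)) nwFL[i, 1L] <- (i - 1L) * de
    for (j in 1L:(n + 1L)) nwFL[1L, j] <- (j - 1L) * de
    if (m >= 1L && n >= 1L) for (i in 2L:(m + 1L)) for (j in 2L:(n + 1L))
        nwFL[i, j] <- max(nwFL[i - 1L, j - 1L] + sg(fI[i - 1L], lI[j - 1L]),
                          nwFL[i - 1L, j] + de, nwFL[i, j - 1L] + de)

    # nwFRsuf[i+1, k+1]: global pairwise alignment of F[i+1..m], R[k+1..p]
    nwFRsuf <- matrix(0, m + 1L, p + 1L)
    for (i in m:1L) nwFRsuf[i, p + 1L] <- (m - i + 1L) * de
    if (p >= 1L) for (k in p:1L) nwFRsuf[m + 1L, k] <- (p - k + 1L) * de
    if (m >= 1L && p >= 1L) for (i in m:1L) for (k in p:1L)
        nwFRsuf[i, k] <- max(nwFRsuf[i + 1L, k + 1L] + sg(fI[i], rI[k]),
                             nwFRsuf[i + 1L, k] + de, nwFRsuf[i, k + 1L] + de)

    # B[i+1, j+1, k+1]: best completion from (i, j, k letters consumed):
    # a gamma-scored middle over suffixes followed by the pairwise F-R
    # suffix; ending the middle anywhere frees L's remaining suffix.
    B <- array(-Inf, dim = c(m + 1L, n + 1L, p + 1L))
    for (i in (m + 1L):1L) for (j in (n + 1L):1L) for (k in (p + 1L):1L) {
        best <- nwFRsuf[i, k]
        fi <- if (i <= m) fI[i] else NA
        lj <- if (j <= n) lI[j] else NA
        rk <- if (k <= p) rI[k] else NA
        if (i <= m && j <= n && k <= p)
            best <- max(best, B[i + 1L, j + 1L, k + 1L] + gm(fi, lj, rk))
        if (i <= m && j <= n)
            best <- max(best, B[i + 1L, j + 1L, k] + gm(fi, lj, 0L))
        if (i <= m && k <= p)
            best <- max(best, B[i + 1L, j, k + 1L] + gm(fi, 0L, rk))
        if (i <= m)
            best <- max(best, B[i + 1L, j, k] + gm(fi, 0L, 0L))
        if (j <= n && k <= p)
            best <- max(best, B[i, j + 1L, k + 1L] + gm(0L, lj, rk))
        if (j <= n)
            best <- max(best, B[i, j + 1L, k] + gm(0L, lj, 0L))
        if (k <= p)
            best <- max(best, B[i, j, k + 1L] + gm(0L, 0L, rk))
        B[i, j, k] <- best
    }

    best <- -Inf
    for (i0 in 0L:m) for (j0 in 0L:n) {
        base <- nwFL[i0 + 1L, j0 + 1L]
        best <- max(best, base + B[i0 + 1L, j0 + 1L, 1L])
        if (i0 >= 1L && j0 >= 1L && p >= 1L)       # free R-prefix jump
            best <- max(best, base + max(B[i0 + 1L, j0 + 1L, 2L:(p + 1L)]))
    }

    # free reference interval F[i'+1..i1] (i' < i1) with free R prefix
    planeMax <- vapply(0L:m, function(i) max(nwFL[i + 1L, ]), numeric(1L))
    prefMax <- cummax(planeMax)                    # prefMax[i'+1] over <= i'
    for (i1 in 1L:m)
        best <- max(best, prefMax[i1] + max(nwFRsuf[i1 + 1L, ]))
    best
}
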