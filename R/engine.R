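# Dynamic programming engine: tensor fill, M matrix, traceback.

.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U")

# Uppercase and reduce the alphabet to A,C,G,T,N.  Other IUPAC codes are
# normalized to N with a warning; anything else is an input error.
.normalizeSeq <- function(x, what = "sequence") {
    if (is(x, "XStringSet")) {
        if (length(x) != 1L)
            .inputError(what, ": expected a single sequence")
        x <- x[[1L]]
    }
    chr <- toupper(as.character(x))
    chars <- strsplit(chr, "")[[1L]]
    amb <- chars %in% .IUPAC_AMBIG
    if (any(amb)) {
        warning(what, ": ", sum(amb),
                " IUPAC ambiguity letter(s) normalized to N")
        chars[amb] <- "N"
    }
    bad <- !(chars %in% .ALPHABET)
    if (any(bad))
        .inputError(what, ": unknown symbol(s) ",
                    paste(unique(chars[bad]), collapse = ", "))
    Biostrings::DNAString(paste(chars, collapse = ""))
}

#' Fill the three-way score tensor S
#'
#' Computes the \code{(m+1) x (n+1) x (p+1)} tensor of optimal partially
#' local alignment scores of all prefixes of F, L and R.  The k = 0 face
#' is the pairwise global F-L alignment; the j = 0 and i = 0 faces use the
#' three-way score so that the missing sequence is penalized; interior
#' cells additionally allow the free deletion of R's prefix (the fallback
#' on \code{S[i,j,0]}).  Edge values are \code{S[i,0,0] = i g},
#' \code{S[0,j,0] = j g} and \code{S[0,0,k] = 2 g k}.
#'
#' @param F,L,R sequences (character or [Biostrings::DNAString]).  L and
#'   F must be non-empty; an empty R degenerates to a global F-L
#'   alignment with a free L suffix.
#' @param scheme a \linkS4class{ScoringScheme}.
#' @return a \linkS4class{DPState} with the S slot filled.
#' @examples
#' st <- fillTensor("ACGT", "ACG", "CGT")
#' st@S[4, 1, 1]   # S[3,0,0] = 3 * edge gap
#' @export
fillTensor <- function(F, L, R, scheme = ScoringScheme()) {
    F <- .normalizeSeq(F, "F"); L <- .normalizeSeq(L, "L")
    R <- .normalizeSeq(R, "R")
    if (length(F) == 0L) .inputError("empty reference F is outside the model")
    if (length(L) == 0L) .inputError("empty left fragment L is outside the model")
    S <- pla_fill_s(.encode(F), .encode(L), .encode(R),
                    scheme@matchScore, scheme@mismatchScore,
                    scheme@indelScore, scheme@edgeGap, scheme@sopWeight)
    new("DPState", S = S, M = matrix(numeric(0), 0, 0), mtilde = numeric(0))
}

#' Complete the DP state with the matrix M
#'
#' Fills the matrix \code{M[i,k]} of optimal scores of an F-R alignment
#' that continues after the end of L's aligned part, using pairwise
#' extensions, the "L ends at j" entry \code{max_j S[i,j,k]}, and the
#' unpenalized reference interval entry
#' \code{mtilde[i] = max_{i'<i} max_j S[i',j,0]}, which is accumulated
#' incrementally so the whole matrix costs O(m n + m p n) like the tensor
#' itself.  The optimal alignment score is \code{M[m,p]}.
#'
#' @param state a \linkS4class{DPState} from [fillTensor()].
#' @inheritParams fillTensor
#' @return the completed \linkS4class{DPState}.
#' @export
fillMatrix <- function(state, F, L, R, scheme = ScoringScheme()) {
    F <- .normalizeSeq(F, "F"); L <- .normalizeSeq(L, "L")
    R <- .normalizeSeq(R, "R")
    res <- pla_fill_m(state@S, .encode(F), .encode(R), length(L),
                      scheme@matchScore, scheme@mismatchScore,
                      scheme@indelScore)
    new("DPState", S = state@S, M = res$M, mtilde = as.numeric(res$mtilde))
}

.near <- function(x, y, tol = 1e-9) {
    (is.infinite(x) && is.infinite(y) && sign(x) == sign(y)) ||
        (is.finite(x) && is.finite(y) && abs(x - y) <= tol)
}

# Deterministic traceback.  Tie-breaking is "compact": whenever several
# cases achieve the optimum, unscored resolutions are preferred over
# scored ones (in M: pairwise extensions, then the free reference
# interval, then the "L ends at j" entry with the smallest j; in the
# tensor: the free R-prefix deletion first, then columns with fewer
# letters, the triple column last).  Ties arise exactly when a
# zero-net-score extension of the aligned region exists, i.e. when the
# extra homology is not supported by the score; resolving them toward
# the free regions keeps the measured overlap/gap from drifting on
# chance matches in the unrelated flanks, while any truly score-positive
# overlap is still found.  Columns are collected right-to-left.
.tracebackPLA <- function(S, M, mtilde, fI, lI, rI, scheme, tol = 1e-9) {
    m <- length(fI); n <- length(lI); p <- length(rI)
    de <- scheme@indelScore; g <- scheme@edgeGap
    letters <- c("-", .ALPHABET)
    fc <- letters[fI + 1L]; lc <- letters[lI + 1L]; rc <- letters[rI + 1L]
    sg <- function(a, b) .sigmaInt(a, b, scheme)
    gm <- function(a, b, c) {
        s <- sg(a, b) + sg(a, c) + sg(b, c)
        if (a != 0L && b != 0L && c != 0L) s / scheme@sopWeight else s
    }
    colF <- character(0); colL <- character(0); colR <- character(0)
    tags <- character(0)
    push <- function(f, l, r, tag) {
        colF[[length(colF) + 1L]] <<- f
        colL[[length(colL) + 1L]] <<- l
        colR[[length(colR) + 1L]] <<- r
        tags[[length(tags) + 1L]] <<- tag
    }
    pushLFree <- function(j) if (j < n) for (jj in n:(j + 1L))
        push("-", lc[jj], "-", "L_FREE")
    pushRFree <- function(k) if (k >= 1L) for (kk in k:1L)
        push("-", "-", rc[kk], "R_FREE")
    bug <- function(where, i, j, k)
        stop("internal traceback inconsistency at ", where,
             " (", i, ",", j, ",", k, "): engine bug")

    i <- m; j <- NA_integer_; k <- p; mode <- "M"
    repeat {
        if (mode == "M") {
            v <- M[i + 1L, k + 1L]
            if (i >= 1L && k >= 1L &&
                .near(M[i, k] + sg(fI[i], rI[k]), v, tol)) {
                push(fc[i], "-", rc[k], "FR"); i <- i - 1L; k <- k - 1L; next
            }
            if (i >= 1L && .near(M[i, k + 1L] + de, v, tol)) {
                push(fc[i], "-", "-", "FR"); i <- i - 1L; next
            }
            if (k >= 1L && .near(M[i + 1L, k] + de, v, tol)) {
                push("-", "-", rc[k], "FR"); k <- k - 1L; next
            }
            if (i >= 1L && .near(mtilde[i + 1L], v, tol)) {  # free F interval
                i2 <- NA_integer_
                for (cand in (i - 1L):0L) {
                    if (.near(max(S[cand + 1L, , 1L]), v, tol)) {
                        i2 <- cand; break
                    }
                }
                if (is.na(i2)) bug("M/free-interval", i, NA, k)
                j <- min(which(abs(S[i2 + 1L, , 1L] - v) <= tol)) - 1L
                pushRFree(k)
                if (i > i2) for (ii in i:(i2 + 1L))
                    push(fc[ii], "-", "-", "F_FREE")
                pushLFree(j)
                i <- i2; k <- 0L; mode <- "S"; next
            }
            js <- which(abs(S[i + 1L, , k + 1L] - v) <= tol)
            if (length(js)) {                      # L ends at position j
                j <- min(js) - 1L
                pushLFree(j)
                mode <- "S"; next
            }
            bug("M", i, NA, k)
        }
        # mode == "S"
        if (k == 0L) {                             # pairwise F-L face
            if (i == 0L && j == 0L) break
            v <- S[i + 1L, j + 1L, 1L]
            if (i >= 1L && j >= 1L &&
                .near(S[i, j, 1L] + sg(fI[i], lI[j]), v, tol)) {
                push(fc[i], lc[j], "-", "FL"); i <- i - 1L; j <- j - 1L; next
            }
            costF <- if (j == 0L) g else de
            if (i >= 1L && .near(S[i, j + 1L, 1L] + costF, v, tol)) {
                push(fc[i], "-", "-", "FL"); i <- i - 1L; next
            }
            costL <- if (i == 0L) g else de
            if (j >= 1L && .near(S[i + 1L, j, 1L] + costL, v, tol)) {
                push("-", lc[j], "-", "FL"); j <- j - 1L; next
            }
            bug("S-plane", i, j, 0L)
        }
        v <- S[i + 1L, j + 1L, k + 1L]
        if (i >= 1L && j >= 1L && .near(S[i + 1L, j + 1L, 1L], v, tol)) {
            pushRFree(k); k <- 0L; next           # free deletion of R[1..k]
        }
        if (k >= 1L && .near(S[i + 1L, j + 1L, k] + gm(0L, 0L, rI[k]), v, tol)) {
            push("-", "-", rc[k], "FLR"); k <- k - 1L; next
        }
        if (j >= 1L && .near(S[i + 1L, j, k + 1L] + gm(0L, lI[j], 0L), v, tol)) {
            push("-", lc[j], "-", "FLR"); j <- j - 1L; next
        }
        if (i >= 1L && .near(S[i, j + 1L, k + 1L] + gm(fI[i], 0L, 0L), v, tol)) {
            push(fc[i], "-", "-", "FLR"); i <- i - 1L; next
        }
        if (j >= 1L && k >= 1L &&
            .near(S[i + 1L, j, k] + gm(0L, lI[j], rI[k]), v, tol)) {
            push("-", lc[j], rc[k], "FLR"); j <- j - 1L; k <- k - 1L; next
        }
        if (i >= 1L && k >= 1L &&
            .near(S[i, j + 1L, k] + gm(fI[i], 0L, rI[k]), v, tol)) {
            push(fc[i], "-", rc[k], "FLR"); i <- i - 1L; k <- k - 1L; next
        }
        if (i >= 1L && j >= 1L &&
            .near(S[i, j, k + 1L] + gm(fI[i], lI[j], 0L), v, tol)) {
            push(fc[i], lc[j], "-", "FLR"); i <- i - 1L; j <- j - 1L; next
        }
        if (i >= 1L && j >= 1L && k >= 1L &&
            .near(S[i, j, k] + gm(fI[i], lI[j], rI[k]), v, tol)) {
            push(fc[i], lc[j], rc[k], "FLR")
            i <- i - 1L; j <- j - 1L; k <- k - 1L; next
        }
        if (i == 0L && j == 0L && k >= 1L &&
            .near(S[1L, 1L, k] + 2 * g, v, tol)) { # tensor edge, R first
            push("-", "-", rc[k], "FLR"); k <- k - 1L; next
        }
        bug("S-tensor", i, j, k)
    }

    list(F = rev(colF), L = rev(colL), R = rev(colR), regions = rev(tags))
}

.coordFromColumns <- function(cf, cl, cr) {
    fpos <- cumsum(cf != "-")
    lCols <- which(cl != "-" & cf != "-")
    rCols <- which(cr != "-" & cf != "-")
    list(lEnd = if (length(lCols)) as.integer(fpos[max(lCols)]) else 0L,
         rStart = if (length(rCols)) as.integer(fpos[min(rCols)]) else 0L)
}

#' Align a reference breakpoint region against its two fragments
#'
#' Computes one optimal partially local three-way alignment of the
#' reference F and the derived fragments L (homologous to F's left part)
#' and R (homologous to F's right part).  The alignment is global at F's
#' ends, at L's start and at R's end; L's suffix and R's prefix toward
#' the breakpoint are unscored, and when L and R do not meet on F the
#' intervening reference interval is unpenalized.  Ties are broken
#' deterministically in favour of scored (explicit homology) columns.
#'
#' @inheritParams fillTensor
#' @return a \linkS4class{TriAlignment}.
#' @examples
#' aln <- alignBreakpoint("ACGT", "ACG", "CGT")
#' score(aln)            # 8
#' signedOverlap(aln)    # 2
#' @export
alignBreakpoint <- function(F, L, R, scheme = ScoringScheme()) {
    F <- .normalizeSeq(F, "F"); L <- .normalizeSeq(L, "L")
    R <- .normalizeSeq(R, "R")
    if (length(F) == 0L) .inputError("empty reference F is outside the model")
    if (length(L) == 0L) .inputError("empty left fragment L is outside the model")
    fI <- .encode(F); lI <- .encode(L); rI <- .encode(R)
    S <- pla_fill_s(fI, lI, rI, scheme@matchScore, scheme@mismatchScore,
                    scheme@indelScore, scheme@edgeGap, scheme@sopWeight)
    res <- pla_fill_m(S, fI, rI, length(lI), scheme@matchScore,
                      scheme@mismatchScore, scheme@indelScore)
    tb <- .tracebackPLA(S, res$M, as.numeric(res$mtilde), fI, lI, rI, scheme)
    coords <- .coordFromColumns(tb$F, tb$L, tb$R)
    aln <- new("TriAlignment",
        seqF = F, seqL = L, seqR = R,
        alignedF = paste(tb$F, collapse = ""),
        alignedL = paste(tb$L, collapse = ""),
        alignedR = paste(tb$R, collapse = ""),
        regions = tb$regions,
        score = res$M[length(fI) + 1L, length(rI) + 1L],
        lEndInF = coords$lEnd, rStartInF = coords$rStart,
        scheme = scheme)
    validObject(aln)
    aln
}

#' Recompute an alignment score from its columns
#'
#' Sums the per-column contributions dictated by the region tags: gamma
#' over \code{FLR} columns, pairwise sigma over \code{FL} and \code{FR}
#' columns, and zero over the free regions.  Exact for schemes with
#' \code{edgeGap == indelScore} (the default); useful as an internal
#' consistency check of the traceback.
#'
#' @param aln a \linkS4class{TriAlignment}.
#' @param scheme scoring scheme; defaults to the one stored in \code{aln}.
#' @return numeric score.
#' @export
rescoreAlignment <- function(aln, scheme = aln@scheme) {
    cols <- alignmentColumns(aln)
    total <- 0
    for (idx in seq_len(ncol(cols))) {
        tag <- aln@regions[idx]
        f <- cols["F", idx]; l <- cols["L", idx]; r <- cols["R", idx]
        total <- total + switch(tag,
            FLR = gammaScore(f, l, r, scheme),
            FL = sigmaScore(f, l, scheme),
            FR = sigmaScore(f, r, scheme),
            0)
    }
    total
}

#' @describeIn alignBreakpoint display method for alignments
#' @param object a \code{TriAlignment}.
#' @export
setMethod("show", "TriAlignment", function(object) {
    geom <- measureOverlap(object)
    cat(sprintf("TriAlignment: %d columns, score %g\n",
                nchar(object@alignedF), object@score))
    cat(sprintf("  |F| %d, |L| %d, |R| %d; %s %d (signed %+d); L ends at F[%d], R starts at F[%d]\n",
                length(object@seqF), length(object@seqL), length(object@seqR),
                geom@kind, geom@length, geom@signedValue,
                object@lEndInF, object@rStartInF))
    txt <- .formatAlignmentBlocks(object, width = 60L)
    cat(txt, sep = "\n")
    invisible(object)
})
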