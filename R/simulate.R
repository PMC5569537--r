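# Synthetic breakpoint-region instances and the scoring parameter scan.

.randBases <- function(k) sample(c("A", "C", "G", "T"), k, replace = TRUE)

# Position-wise substitution: each position mutates independently with
# probability `rate` to a uniformly chosen different base.  No indels.
.mutateChars <- function(chars, rate) {
    if (rate <= 0 || !length(chars)) return(chars)
    hit <- runif(length(chars)) < rate
    if (any(hit)) {
        chars[hit] <- vapply(chars[hit], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
    }
    chars
}

#' Generate one synthetic breakpoint-region instance
#'
#' Draws a uniform random reference F, places the breakpoint at
#' \code{floor(fLength/2)} and derives the homologous parts of L and R so
#' that they overlap by \code{truthLength} nucleotides (scenario
#' "overlap", split symmetrically across the breakpoint) or leave a
#' \code{truthLength}-nucleotide stretch of F covered by neither
#' (scenario "gap").  The homologous parts are substitution-mutated
#' position-wise at \code{mutationRate}; random flanks (a suffix for L, a
#' prefix for R) complement both fragments to the length of F, mimicking
#' extraction windows that run into the neighbouring annotation.
#'
#' @param truthKind "overlap" or "gap".
#' @param truthLength designed overlap/gap length in nucleotides.
#' @param fLength reference length; must exceed \code{2*truthLength + 20}.
#' @param mutationRate position-wise substitution probability in [0, 1].
#' @param seed integer seed; the instance is fully reproducible from it.
#' @return a \linkS4class{SimInstance}.
#' @examples
#' inst <- makeInstance("overlap", 10, 120, 0, seed = 1)
#' length(inst@seqL)   # 120
#' @export
makeInstance <- function(truthKind = c("overlap", "gap"), truthLength = 10L,
                         fLength = 120L, mutationRate = 0, seed = 1L) {
    truthKind <- match.arg(truthKind)
    truthLength <- as.integer(truthLength)
    fLength <- as.integer(fLength)
    if (truthLength < 0L) .inputError("truthLength must be >= 0")
    if (fLength <= 2L * truthLength + 20L)
        .inputError("fLength must exceed 2*truthLength + 20")
    if (mutationRate < 0 || mutationRate > 1)
        .inputError("mutationRate must be in [0, 1]")
    set.seed(as.integer(seed))
    f <- .randBases(fLength)
    b <- fLength %/% 2L; t <- truthLength
    if (truthKind == "overlap") {
        lEnd <- b + as.integer(ceiling(t / 2))
        rStart <- b - t %/% 2L + 1L
    } else {
        lEnd <- b - as.integer(ceiling(t / 2))
        rStart <- b + t %/% 2L + 1L
    }
    if (lEnd < 1L || rStart > fLength)
        .inputError("infeasible geometry for the requested lengths")
    lHom <- .mutateChars(f[seq_len(lEnd)], mutationRate)
    rHom <- .mutateChars(f[rStart:fLength], mutationRate)
    l <- c(lHom, .randBases(fLength - lEnd))
    r <- c(.randBases(rStart - 1L), rHom)
    new("SimInstance",
        seqF = Biostrings::DNAString(paste(f, collapse = "")),
        seqL = Biostrings::DNAString(paste(l, collapse = "")),
        seqR = Biostrings::DNAString(paste(r, collapse = "")),
        truthKind = truthKind, truthLength = truthLength,
        mutationRate = mutationRate, seed = as.integer(seed))
}

#' @describeIn makeInstance display method
#' @param object a \code{SimInstance}.
#' @export
setMethod("show", "SimInstance", function(object) {
    cat(sprintf(
        "SimInstance: designed %s of %d nt, |F| %d, mutation %.2f, seed %d\n",
        object@truthKind, object@truthLength, length(object@seqF),
        object@mutationRate, object@seed))
    invisible(object)
})

#' Scan scoring parameters on synthetic instances
#'
#' For every combination of match, mismatch, gap (indel) score,
#' sum-of-pairs weight W, mutation rate and scenario, aligns
#' \code{nPerCell} synthetic instances and records the mean and standard
#' deviation of the signed overlap estimate (positive overlap, negative
#' gap).  Instances are shared across scoring schemes within a
#' (scenario, mutation) cell and derived deterministically from
#' \code{baseSeed} plus an instance index, so the whole table is
#' bit-reproducible.
#'
#' @param match,mismatch,gap vectors of pairwise scores to scan.
#' @param W vector of sum-of-pairs weights.
#' @param mutation vector of position-wise mutation rates.
#' @param scenario scenarios to simulate ("overlap", "gap" or both).
#' @param nPerCell instances per parameter combination.
#' @param truthLength designed overlap/gap length (nucleotides).
#' @param fLength reference length for [makeInstance()].
#' @param baseSeed integer base seed.
#' @return a data.frame with columns match, mismatch, gap, W, mutation,
#'   scenario, n, mean, sd (mean/sd of the signed overlap estimate; sd is
#'   0 when \code{nPerCell} is 1).
#' @examples
#' runScan(match = 1, mismatch = -1, gap = -2, W = 1, mutation = 0,
#'         scenario = "overlap", nPerCell = 3, baseSeed = 7)
#' @export
runScan <- function(match = c(1, 2, 3), mismatch = c(-1, -2, -3),
                    gap = c(-1, -2, -3), W = c(1, 2, 3),
                    mutation = c(0, 0.15, 0.30),
                    scenario = c("overlap", "gap"), nPerCell = 50L,
                    truthLength = 10L, fLength = 120L, baseSeed = 1L) {
    scenario <- match.arg(scenario, several.ok = TRUE)
    nPerCell <- as.integer(nPerCell)
    if (nPerCell < 1L) .inputError("nPerCell must be >= 1")
    baseSeed <- as.integer(baseSeed)

    # shared instances per (scenario, mutation) cell
    instKey <- expand.grid(inst = seq_len(nPerCell), mutation = mutation,
                           scenario = scenario, stringsAsFactors = FALSE)
    instances <- vector("list", nrow(instKey))
    for (q in seq_len(nrow(instKey)))
        instances[[q]] <- makeInstance(instKey$scenario[q], truthLength,
                                       fLength, instKey$mutation[q],
                                       seed = baseSeed + q - 1L)
    cellOf <- function(sc, mu) which(instKey$scenario == sc &
                                     instKey$mutation == mu)

    grid <- expand.grid(match = match, mismatch = mismatch, gap = gap,
                        W = W, mutation = mutation, scenario = scenario,
                        stringsAsFactors = FALSE)
    grid$n <- nPerCell
    grid$mean <- NA_real_
    grid$sd <- NA_real_
    for (g in seq_len(nrow(grid))) {
        scheme <- suppressWarnings(ScoringScheme(grid$match[g],
                                                 grid$mismatch[g],
                                                 grid$gap[g],
                                                 sopWeight = grid$W[g]))
        est <- vapply(cellOf(grid$scenario[g], grid$mutation[g]),
                      function(q) {
            inst <- instances[[q]]
            as.numeric(signedOverlap(alignBreakpoint(
                inst@seqF, inst@seqL, inst@seqR, scheme)))
        }, numeric(1L))
        grid$mean[g] <- mean(est)
        grid$sd[g] <- if (length(est) > 1L) sd(est) else 0
    }
    grid
}
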