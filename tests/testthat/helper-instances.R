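# Shared test helpers: random instances, grid schemes, a tiny independent
# pairwise aligner for lower-bound checks.

randSeq <- function(n, alphabet = c("A", "C")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Clean constructed instance with designed signed overlap t - s + 1 and
# flanks over letters absent from F, so chance matches cannot blur the
# planted geometry.
cleanInstance <- function(m = 40L, t = 25L, s = 16L, seed = 1L,
                          flankLen = 8L) {
    set.seed(seed)
    f <- sample(c("A", "C"), m, replace = TRUE)
    list(F = paste(f, collapse = ""),
         L = paste(c(f[1:t], rep("G", flankLen)), collapse = ""),
         R = paste(c(rep("T", flankLen), f[s:m]), collapse = ""),
         signed = t - s + 1L)
}

gridSchemes <- function() {
    g <- expand.grid(a = 1:3, b = -(1:3), d = -(1:3), W = 1:3)
    lapply(seq_len(nrow(g)), function(i)
        suppressWarnings(ScoringScheme(g$a[i], g$b[i], g$d[i],
                                       sopWeight = g$W[i])))
}

# Plain global Needleman-Wunsch over characters, for independent bounds.
nwScore <- function(x, y, scheme) {
    xc <- strsplit(x, "")[[1L]]; yc <- strsplit(y, "")[[1L]]
    a <- matchScore(scheme); b <- mismatchScore(scheme); d <- indelScore(scheme)
    n <- length(xc); m <- length(yc)
    prev <- (0:m) * d
    for (i in seq_len(n)) {
        cur <- numeric(m + 1L); cur[1L] <- i * d
        for (j in seq_len(m)) {
            cur[j + 1L] <- max(prev[j] + if (xc[i] == yc[j]) a else b,
                               prev[j + 1L] + d, cur[j] + d)
        }
        prev <- cur
    }
    prev[m + 1L]
}
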