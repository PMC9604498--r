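# Independent oracles and fixture helpers shared across the test files.

# Brute-force pattern scan: tests every window with plain character-set
# membership (no regex, no Biostrings). Returns 1-based start positions.
bruteScanStarts <- function(seqChar, pattern = "NGGGNN") {
    map <- Biostrings::IUPAC_CODE_MAP
    sets <- strsplit(unname(map[strsplit(pattern, "")[[1]]]), "")
    m <- length(sets)
    chars <- strsplit(seqChar, "")[[1]]
    L <- length(chars)
    if (L < m) return(integer(0))
    starts <- integer(0)
    for (w in seq_len(L - m + 1)) {
        ok <- TRUE
        for (j in seq_len(m)) {
            if (!(chars[w + j - 1] %in% sets[[j]])) {
                ok <- FALSE
                break
            }
        }
        if (ok) starts <- c(starts, w)
    }
    starts
}

randSeq <- function(L, prob = c(0.25, 0.25, 0.25, 0.25),
                    letters = c("A", "C", "G", "T")) {
    paste(sample(letters, L, replace = TRUE, prob = prob), collapse = "")
}

uniformProfile <- function() {
    CompositionProfile(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
}

# Profile with a given G frequency, remainder split evenly.
gProfile <- function(pg) {
    r <- (1 - pg) / 3
    CompositionProfile(c(A = r, C = r, G = pg, T = r))
}

# Random strictly-positive composition.
randProfile <- function() {
    f <- runif(4, 0.05, 1)
    CompositionProfile(setNames(f / sum(f), c("A", "C", "G", "T")))
}

# Trapezoidal integral.
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Write a throwaway FASTA and return its path.
tmpFasta <- function(lines) {
    fa <- tempfile(fileext = ".fa")
    writeLines(lines, fa)
    fa
}
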