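# Internal helpers: IUPAC sets, seed derivation, pattern probabilities.

# Per-position sets of concrete bases an IUPAC pattern allows. The code N
# denotes {A,C,G,T}: it never matches a literal N residue in a subject.
iupacSets <- function(pattern) {
    chars <- strsplit(toupper(pattern), "")[[1]]
    map <- Biostrings::IUPAC_CODE_MAP
    bad <- setdiff(chars, names(map))
    if (length(bad))
        stop("pattern contains non-IUPAC characters: ",
             paste(unique(bad), collapse = ", "))
    lapply(chars, function(ch) strsplit(map[[ch]], "")[[1]])
}

# Probability that one fixed window matches the pattern under an i.i.d.
# background with the given composition.
patternMatchProb <- function(profile, pattern) {
    freq <- compositionFreqs(profile)
    sets <- iupacSets(pattern)
    prod(vapply(sets, function(s) sum(freq[s]), numeric(1)))
}

# Deterministic per-stage substream seed, so individual pipeline stages can
# be re-run in isolation under the one top-level seed. Stays below 2^31.
deriveSeed <- function(seed, stage) {
    stopifnot(length(seed) == 1L, is.finite(seed))
    v <- utf8ToInt(stage)
    h <- sum(v * seq_along(v)) %% 1048573
    as.integer(((abs(seed) %% 48611) * 33391 + h * 7919 + 17) %% 2147483629)
}

# Coerce character / DNAString input to a named DNAStringSet.
asDNAStringSet <- function(x) {
    if (is(x, "DNAStringSet")) {
        ss <- x
    } else if (is(x, "DNAString")) {
        ss <- Biostrings::DNAStringSet(x)
    } else if (is.character(x)) {
        ss <- Biostrings::DNAStringSet(toupper(x))
    } else {
        stop("cannot interpret object of class '", class(x)[1],
             "' as DNA sequences")
    }
    if (is.null(names(ss)))
        names(ss) <- paste0("seq", seq_along(ss))
    ss
}

# Check residues are within {A,C,G,T,N}.
checkAlphabet <- function(seqs) {
    af <- Biostrings::alphabetFrequency(seqs)
    keep <- colnames(af) %in% c("A", "C", "G", "T", "N")
    extra <- rowSums(af[, !keep, drop = FALSE])
    if (any(extra > 0)) {
        bad <- names(seqs)[extra > 0]
        stop("sequence(s) contain residues outside {A,C,G,T,N}: ",
             paste(bad, collapse = ", "))
    }
    invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
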