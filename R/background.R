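#' Simulate a composition-matched null ensemble
#'
#' Generates `n` random sequences of a fixed length whose positions are
#' drawn i.i.d. from a mononucleotide composition profile (an order-0
#' background). This is the null model every enrichment statistic is
#' calibrated against: same length, same composition, no structure.
#'
#' @param profile A [CompositionProfile-class].
#' @param length Member length in bp (>= 1).
#' @param n Ensemble size (>= 1).
#' @param seed Integer RNG seed; the ensemble is reproduced bit-for-bit
#'   under the same seed.
#' @return A [NullEnsemble-class].
#' @examples
#' prof <- CompositionProfile(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
#' ens <- simulateBackground(prof, length = 100, n = 5, seed = 1)
#' ens
#' @export
simulateBackground <- function(profile, length, n, seed) {
    stopifnot(is(profile, "CompositionProfile"))
    length <- as.integer(length)
    n <- as.integer(n)
    if (length < 1L) stop("'length' must be >= 1")
    if (n < 1L) stop("'n' must be >= 1")
    freq <- compositionFreqs(profile)
    if (all(freq == 0))
        stop("profile assigns zero probability to every base")
    set.seed(as.integer(seed))
    # chunked generation caps the transient character-vector footprint
    chunk <- max(1L, min(n, as.integer(ceiling(5e6 / length))))
    pieces <- vector("list", ceiling(n / chunk))
    done <- 0L
    i <- 1L
    while (done < n) {
        k <- min(chunk, n - done)
        chars <- sample(c("A", "C", "G", "T"), k * length,
                        replace = TRUE, prob = freq)
        big <- paste(chars, collapse = "")
        starts <- (seq_len(k) - 1L) * length + 1L
        pieces[[i]] <- Biostrings::DNAStringSet(
            substring(big, starts, starts + length - 1L))
        done <- done + k
        i <- i + 1L
    }
    seqs <- do.call(c, pieces)
    names(seqs) <- paste0("null_", seq_len(n))
    new("NullEnsemble", sequences = seqs, profile = profile,
        targetLength = length, n = n, seed = as.integer(seed))
}

#' Dump a null ensemble to FASTA for audit
#'
#' @param ensemble A [NullEnsemble-class].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
writeEnsembleFasta <- function(ensemble, path) {
    stopifnot(is(ensemble, "NullEnsemble"))
    writeFastaSequences(nullSequences(ensemble), path)
}
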