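#' Mononucleotide composition of a region
#'
#' Holds the A/C/G/T frequencies of a nucleotide sequence, computed over
#' unambiguous residues only. The profile defines the background model: it
#' parameterises the null-sequence simulator, the background term of the
#' site log-likelihood ratio, and every analytic expectation.
#'
#' @slot freq Named numeric of length 4 (`A`, `C`, `G`, `T`), each in
#'   `[0, 1]`, summing to 1.
#' @slot nCounted Integer, number of unambiguous residues the frequencies
#'   were computed from (0 for a profile stated a priori).
#'
#' @seealso [baseComposition()], [simulateBackground()]
#' @export
setClass("CompositionProfile",
    representation(freq = "numeric", nCounted = "integer"),
    prototype(freq = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
              nCounted = 0L))

setValidity("CompositionProfile", function(object) {
    f <- object@freq
    if (!identical(names(f), c("A", "C", "G", "T")))
        return("'freq' must be named A, C, G, T (in that order)")
    if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
        return("frequencies must be finite and in [0, 1]")
    if (abs(sum(f) - 1) > 1e-12)
        return("frequencies must sum to 1 (within 1e-12)")
    if (length(object@nCounted) != 1L || is.na(object@nCounted) ||
        object@nCounted < 0L)
        return("'nCounted' must be a single non-negative integer")
    TRUE
})

#' @describeIn CompositionProfile-class Constructor. `freq` may be counts or
#'   frequencies; it is normalised to sum to 1.
#' @param freq Named numeric vector with entries `A`, `C`, `G`, `T`
#'   (counts or frequencies; any order).
#' @param nCounted Number of residues behind the frequencies.
#' @return A `CompositionProfile`.
#' @examples
#' CompositionProfile(c(A = 1, C = 1, G = 1, T = 1))
#' @export
CompositionProfile <- function(freq, nCounted = 0L) {
    if (is.null(names(freq)) || !setequal(names(freq), c("A", "C", "G", "T")))
        stop("'freq' must be a named vector with entries A, C, G, T")
    freq <- freq[c("A", "C", "G", "T")]
    tot <- sum(freq)
    if (!is.finite(tot) || tot <= 0)
        stop("'freq' must have a positive finite total")
    new("CompositionProfile", freq = freq / tot,
        nCounted = as.integer(nCounted))
}

#' Position weight matrix for a short binding motif
#'
#' Per-position base frequencies of a motif, stored as a 4 x m matrix with
#' rows `A`, `C`, `G`, `T`. A pseudocount is folded in at construction so
#' every stored frequency is strictly positive and site log-likelihood
#' ratios are always finite.
#'
#' @slot freqs 4 x m numeric matrix of per-position base frequencies;
#'   columns sum to 1, all entries > 0.
#' @slot pseudocount The probability floor applied at ingest.
#' @slot name Free-text motif label.
#'
#' @seealso [readPWM()], [scoreSite()], [successThreshold()]
#' @export
setClass("PositionWeightMatrix",
    representation(freqs = "matrix", pseudocount = "numeric",
                   name = "character"))

setValidity("PositionWeightMatrix", function(object) {
    fr <- object@freqs
    if (!is.numeric(fr) || nrow(fr) != 4L)
        return("'freqs' must be a numeric matrix with 4 rows")
    if (!identical(rownames(fr), c("A", "C", "G", "T")))
        return("'freqs' rows must be named A, C, G, T")
    if (ncol(fr) < 1L)
        return("matrix must have at least one position")
    if (any(!is.finite(fr)) || any(fr <= 0))
        return("all frequencies must be finite and > 0 (pseudocount missing?)")
    if (any(abs(colSums(fr) - 1) > 1e-9))
        return("each position's frequencies must sum to 1 (within 1e-9)")
    TRUE
})

#' @describeIn PositionWeightMatrix-class Constructor. Columns of `freqs`
#'   (counts or frequencies) are normalised, then the pseudocount is applied
#'   as `(f + pc) / (1 + 4 pc)` per cell.
#' @param freqs 4 x m matrix (rows A, C, G, T; counts or frequencies).
#' @param pseudocount Probability floor (default `1e-4`).
#' @param name Motif label.
#' @return A `PositionWeightMatrix`.
#' @examples
#' fr <- matrix(c(2, 2, 2, 2,  0, 0, 8, 0), nrow = 4,
#'              dimnames = list(c("A", "C", "G", "T"), NULL))
#' PositionWeightMatrix(fr, name = "toy")
#' @export
PositionWeightMatrix <- function(freqs, pseudocount = 1e-4, name = "motif") {
    freqs <- as.matrix(freqs)
    if (nrow(freqs) != 4L)
        stop("PWM must have exactly 4 rows (A, C, G, T); got ", nrow(freqs))
    if (is.null(rownames(freqs))) {
        rownames(freqs) <- c("A", "C", "G", "T")
    } else {
        rn <- toupper(rownames(freqs))
        if (!setequal(rn, c("A", "C", "G", "T")))
            stop("PWM rows must be labelled A, C, G, T")
        rownames(freqs) <- rn
        freqs <- freqs[c("A", "C", "G", "T"), , drop = FALSE]
    }
    if (any(!is.finite(freqs)) || any(freqs < 0))
        stop("PWM cells must be finite and non-negative")
    tot <- colSums(freqs)
    if (any(tot <= 0))
        stop("every PWM column must have a positive total")
    freqs <- sweep(freqs, 2L, tot, "/")
    freqs <- (freqs + pseudocount) / (1 + 4 * pseudocount)
    colnames(freqs) <- NULL
    new("PositionWeightMatrix", freqs = freqs,
        pseudocount = pseudocount, name = name)
}

#' Composition-matched null-sequence ensemble
#'
#' A collection of i.i.d. random sequences with a common length and the
#' mononucleotide composition of a source region; the enrichment baseline
#' everything observed is compared against.
#'
#' @slot sequences `DNAStringSet` of the ensemble members.
#' @slot profile The `CompositionProfile` the members were drawn from.
#' @slot targetLength Common member length (bp).
#' @slot n Ensemble size.
#' @slot seed RNG seed the ensemble was generated under; regenerating with
#'   the same seed reproduces the ensemble exactly.
#'
#' @seealso [simulateBackground()]
#' @export
setClass("NullEnsemble",
    representation(sequences = "DNAStringSet", profile = "CompositionProfile",
                   targetLength = "integer", n = "integer", seed = "integer"))

setValidity("NullEnsemble", function(object) {
    if (length(object@sequences) != object@n)
        return("'n' must equal the number of member sequences")
    if (object@n < 1L)
        return("ensemble must have at least one member")
    if (any(BiocGenerics::width(object@sequences) != object@targetLength))
        return("every member must have length 'targetLength'")
    TRUE
})

#' Full enrichment analysis report
#'
#' Output of [runAnalysis()]: one result block per input sequence (observed
#' count, null summary, Z-test, compound-Poisson and Monte-Carlo enrichment,
#' site-quality comparisons, window profile) plus the configuration and
#' provenance needed to reproduce every stochastic field.
#'
#' @slot results Named list, one entry per input sequence.
#' @slot config The `analysisConfig()` list the run used.
#' @slot provenance List: package version, input checksums, timestamps.
#'
#' @seealso [runAnalysis()], [writeReport()]
#' @export
setClass("EnrichmentReport",
    representation(results = "list", config = "list", provenance = "list"))

setValidity("EnrichmentReport", function(object) {
    if (length(object@results) && is.null(names(object@results)))
        return("'results' must be named by sequence id")
    TRUE
})
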