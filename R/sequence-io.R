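#' Read promoter-region sequences from a FASTA file
#'
#' Reads a (multi-record) FASTA file into a `DNAStringSet`. Record ids are
#' taken from the headers up to the first whitespace, residues are
#' upper-cased, and any residue outside `{A,C,G,T,N}` is rejected.
#' Soft-masked (lowercase) stretches are kept, upper-cased, and not treated
#' specially.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`, one element per record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s some description", "acgGGt"), fa)
#' readFastaSequences(fa)
#' @seealso [writeFastaSequences()], [baseComposition()]
#' @export
readFastaSequences <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    seqs <- withCallingHandlers(
        tryCatch(
            Biostrings::readDNAStringSet(path, format = "fasta"),
            error = function(e)
                stop("malformed FASTA in '", path, "': ",
                     conditionMessage(e), call. = FALSE)),
        warning = function(w) {
            # the reader silently drops invalid letters; treat as malformed
            if (grepl("invalid", conditionMessage(w)))
                stop("residues outside {A,C,G,T,N} in '", path, "': ",
                     conditionMessage(w), call. = FALSE)
            invokeRestart("muffleWarning")
        })
    if (length(seqs) == 0L)
        stop("empty input: no FASTA records in '", path, "'")
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    checkAlphabet(seqs)
    seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs A `DNAStringSet` (or character vector) of sequences.
#' @param path Output file path.
#' @param width Line-wrap width (bp).
#' @return `path`, invisibly.
#' @export
writeFastaSequences <- function(seqs, path, width = 70L) {
    seqs <- asDNAStringSet(seqs)
    Biostrings::writeXStringSet(seqs, filepath = path, format = "fasta",
                                width = width)
    invisible(path)
}

#' @describeIn baseComposition Frequencies of one `DNAString`.
setMethod("baseComposition", "DNAString", function(x) {
    counts <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
    counts <- setNames(as.numeric(counts), c("A", "C", "G", "T"))
    n <- sum(counts)
    if (n == 0)
        stop("degenerate input: sequence has no unambiguous A/C/G/T residue")
    CompositionProfile(counts, nCounted = n)
})

#' @describeIn baseComposition A length-1 `DNAStringSet`.
setMethod("baseComposition", "DNAStringSet", function(x) {
    if (length(x) != 1L)
        stop("expected a single sequence; got ", length(x),
             " (use lapply for per-sequence profiles)")
    baseComposition(x[[1L]])
})

#' @describeIn baseComposition A character string.
setMethod("baseComposition", "character", function(x) {
    baseComposition(Biostrings::DNAString(toupper(x)))
})
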