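#' @rdname CompositionProfile-class
#' @param object,x A `CompositionProfile`.
#' @export
setGeneric("compositionFreqs", function(x) standardGeneric("compositionFreqs"))

#' @rdname CompositionProfile-class
#' @export
setGeneric("nCounted", function(x) standardGeneric("nCounted"))

#' @rdname PositionWeightMatrix-class
#' @param x A `PositionWeightMatrix`.
#' @export
setGeneric("pwmFreqs", function(x) standardGeneric("pwmFreqs"))

#' @rdname PositionWeightMatrix-class
#' @export
setGeneric("pwmWidth", function(x) standardGeneric("pwmWidth"))

#' @rdname NullEnsemble-class
#' @param x A `NullEnsemble`.
#' @export
setGeneric("nullSequences", function(x) standardGeneric("nullSequences"))

#' Mononucleotide composition of a sequence
#'
#' Computes A/C/G/T frequencies over the unambiguous residues of a
#' sequence. `N` residues are excluded from both numerator and denominator;
#' a sequence with no unambiguous residue is an error.
#'
#' @param x A `DNAString`, a length-1 `DNAStringSet`, or a character string.
#' @return A [CompositionProfile-class] object.
#' @examples
#' baseComposition("ACGNT")   # N excluded: all four at 0.25, nCounted 4
#' @export
setGeneric("baseComposition", function(x) standardGeneric("baseComposition"))

#' @rdname EnrichmentReport-class
#' @param x An `EnrichmentReport`.
#' @export
setGeneric("reportResults", function(x) standardGeneric("reportResults"))

#' @rdname EnrichmentReport-class
#' @export
setGeneric("reportConfig", function(x) standardGeneric("reportConfig"))
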