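# Accessors and show() methods for the S4 data classes.

#' @rdname CompositionProfile-class
setMethod("compositionFreqs", "CompositionProfile", function(x) x@freq)

#' @rdname CompositionProfile-class
setMethod("nCounted", "CompositionProfile", function(x) x@nCounted)

setMethod("show", "CompositionProfile", function(object) {
    f <- object@freq
    cat("CompositionProfile over", object@nCounted, "unambiguous residues\n")
    cat(sprintf("  A=%.4f C=%.4f G=%.4f T=%.4f\n",
                f["A"], f["C"], f["G"], f["T"]))
})

#' @rdname PositionWeightMatrix-class
setMethod("pwmFreqs", "PositionWeightMatrix", function(x) x@freqs)

#' @rdname PositionWeightMatrix-class
setMethod("pwmWidth", "PositionWeightMatrix", function(x) ncol(x@freqs))

setMethod("show", "PositionWeightMatrix", function(object) {
    cat("PositionWeightMatrix '", object@name, "' (width ",
        ncol(object@freqs), ", pseudocount ", object@pseudocount, ")\n",
        sep = "")
    print(round(object@freqs, 4))
})

#' @rdname NullEnsemble-class
setMethod("nullSequences", "NullEnsemble", function(x) x@sequences)

setMethod("show", "NullEnsemble", function(object) {
    cat("NullEnsemble:", object@n, "sequences of", object@targetLength,
        "bp (seed", paste0(object@seed, ")"), "\n")
    f <- compositionFreqs(object@profile)
    cat(sprintf("  source composition A=%.3f C=%.3f G=%.3f T=%.3f\n",
                f["A"], f["C"], f["G"], f["T"]))
})

#' @rdname EnrichmentReport-class
setMethod("reportResults", "EnrichmentReport", function(x) x@results)

#' @rdname EnrichmentReport-class
setMethod("reportConfig", "EnrichmentReport", function(x) x@config)

setMethod("show", "EnrichmentReport", function(object) {
    cat("EnrichmentReport for", length(object@results), "sequence(s)\n")
    for (id in names(object@results)) {
        r <- object@results[[id]]
        cat(sprintf(
            paste0("  %s: %d hits | null %.2f +/- %.2f | z=%.2f ",
                   "(p=%.3g) | fold=%.2f (p_cp=%.3g) | P(bio>sim)=%.3f\n"),
            id, r$observed, r$nullSummary$mean, r$nullSummary$sd,
            r$zTest$z, r$zTest$p, r$compoundPoisson$fold,
            r$compoundPoisson$pValue, r$abTest$pBioGreater))
    }
    cat("  seed:", object@config$seed,
        "| pattern:", object@config$pattern, "\n")
})
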