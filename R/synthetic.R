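#' Toy G-core position weight matrix
#'
#' Builds a width-6 PWM shaped like a Churchill-type binding model:
#' uniform flanking positions (1, 5, 6) and a G-dominant core (positions
#' 2-4) with G at `gCoreWeight` and the remainder split equally.
#'
#' @param gCoreWeight G frequency at the core positions, in
#'   `[0.25, 1 - 3*pseudocount]`; the boundary value 0.25 gives a fully
#'   uniform (degenerate) matrix.
#' @param pseudocount Probability floor (see [PositionWeightMatrix()]).
#' @return A [PositionWeightMatrix-class] of width 6.
#' @examples
#' makeToyPWM(0.9)
#' @export
makeToyPWM <- function(gCoreWeight = 0.9, pseudocount = 1e-4) {
    if (gCoreWeight < 0.25 || gCoreWeight > 1 - 3 * pseudocount)
        stop("'gCoreWeight' must be in [0.25, 1 - 3*pseudocount]")
    rest <- (1 - gCoreWeight) / 3
    flank <- rep(0.25, 4)
    core <- c(rest, rest, gCoreWeight, rest)
    fr <- cbind(flank, core, core, core, flank, flank)
    rownames(fr) <- c("A", "C", "G", "T")
    PositionWeightMatrix(fr, pseudocount = pseudocount, name = "toy-G-core")
}

#' Describe a synthetic promoter scenario
#'
#' Bundles the parameters of one synthetic test sequence: background
#' composition, length, target motif enrichment fold, and optional cluster
#' intervals that receive the planted sites.
#'
#' @param label Free-text scenario name.
#' @param composition A [CompositionProfile-class] (or named frequency
#'   vector) for the background.
#' @param length Sequence length in bp.
#' @param plantedFold Target enrichment multiplier (>= 1; 1 = pure
#'   background).
#' @param clusterIntervals `IRanges` of non-overlapping spans (1-based,
#'   closed, within the sequence) receiving the insertions; `NULL` plants
#'   genome-wide.
#' @param flankProbs Optional named A/C/G/T probabilities for the planted
#'   sites' flanking bases (default: the background composition).
#' @param seed Integer RNG seed.
#' @return A classed list (`"syntheticScenario"`).
#' @seealso [makeScenarioSequence()]
#' @export
syntheticScenario <- function(label, composition, length, plantedFold = 1,
                              clusterIntervals = NULL, flankProbs = NULL,
                              seed = 1L) {
    if (!is(composition, "CompositionProfile"))
        composition <- CompositionProfile(composition)
    length <- as.integer(length)
    if (plantedFold < 1)
        stop("'plantedFold' must be >= 1")
    if (!is.null(clusterIntervals)) {
        stopifnot(is(clusterIntervals, "IRanges"))
        if (any(BiocGenerics::start(clusterIntervals) < 1L) ||
            any(BiocGenerics::end(clusterIntervals) > length))
            stop("cluster intervals must lie within the sequence")
        if (!isDisjoint(clusterIntervals))
            stop("cluster intervals must not overlap")
    }
    if (!is.null(flankProbs)) {
        if (is.null(names(flankProbs)) ||
            !setequal(names(flankProbs), c("A", "C", "G", "T")))
            stop("'flankProbs' must be named A, C, G, T")
        flankProbs <- flankProbs[c("A", "C", "G", "T")] / sum(flankProbs)
    }
    structure(list(label = label, composition = composition,
                   length = length, plantedFold = plantedFold,
                   clusterIntervals = clusterIntervals,
                   flankProbs = flankProbs, seed = as.integer(seed)),
              class = "syntheticScenario")
}

# Count NGGGNN-type hits (G core at offsets 1-3 from the hit start) on a
# character vector; the generator's internal counter.
countGCore <- function(chars) {
    L <- length(chars)
    if (L < 6L)
        return(0L)
    isG <- chars == "G"
    sum(isG[2:(L - 4)] & isG[3:(L - 3)] & isG[4:(L - 2)])
}

#' Generate a synthetic promoter sequence with planted motif enrichment
#'
#' Draws an i.i.d. background at the scenario composition, then overwrites
#' (length-preserving, so analytic expectations stay valid) consensus
#' `xGGGyz` sites at uniformly chosen positions inside the cluster
#' intervals (or anywhere when none are given) until the realised hit count
#' reaches the background count plus `round((plantedFold - 1) * lambda)`,
#' with `lambda` the analytic expectation for the generating composition.
#' Flanking bases `x, y, z` are drawn from `flankProbs` (default: the
#' composition). Planted sites never overlap one another (each insertion's
#' G core survives) and always lie fully inside an interval, so no overlap
#' chain crosses an interval border. Fully reproducible from the scenario
#' seed.
#'
#' @param scenario A [syntheticScenario()].
#' @return A length-1 named `DNAStringSet`; `metadata()` holds a `truth`
#'   list (background count, final count, planted starts, `lambda`).
#' @export
makeScenarioSequence <- function(scenario) {
    stopifnot(inherits(scenario, "syntheticScenario"))
    freq <- compositionFreqs(scenario$composition)
    L <- scenario$length
    if (L < 6L)
        stop("scenario length must be at least the motif width")
    set.seed(scenario$seed)
    chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = freq)
    lambda <- (L - 5) * freq[["G"]]^3
    excess <- round((scenario$plantedFold - 1) * lambda)
    planted <- integer(0)
    if (excess > 0) {
        if (is.null(scenario$clusterIntervals)) {
            allowed <- seq_len(L - 5L)
        } else {
            ci <- scenario$clusterIntervals
            ok <- BiocGenerics::width(ci) >= 6L
            allowed <- unlist(lapply(which(ok), function(i)
                seq.int(BiocGenerics::start(ci)[i],
                        BiocGenerics::end(ci)[i] - 5L)))
        }
        # planted sites never overlap (each insertion's G core survives),
        # so capacity is one site per 6 bp of interval
        capacity <- length(allowed) %/% 6L + 1L
        if (length(allowed) == 0L || excess > capacity)
            stop("requested insertions exceed interval capacity (need ",
                 excess, ", capacity ", capacity, ")")
        fp <- scenario$flankProbs %||% freq
        c0 <- countGCore(chars)
        target <- c0 + excess
        while (countGCore(chars) < target) {
            if (length(allowed) == 0L)
                stop("requested insertions exceed interval capacity ",
                     "(interval space exhausted before the target count)")
            w <- allowed[sample.int(length(allowed), 1L)]
            allowed <- allowed[abs(allowed - w) > 5L]
            flanks <- sample(c("A", "C", "G", "T"), 3L, replace = TRUE,
                             prob = fp)
            chars[w:(w + 5L)] <- c(flanks[1L], "G", "G", "G",
                                   flanks[2L], flanks[3L])
            planted <- c(planted, w)
        }
    }
    seq <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
    names(seq) <- scenario$label
    S4Vectors::metadata(seq) <- list(truth = list(
        label = scenario$label, seed = scenario$seed, lambda = lambda,
        plantedFold = scenario$plantedFold,
        backgroundCount = if (excess > 0) c0 else countGCore(chars),
        finalCount = countGCore(chars), plantedStarts = planted))
    seq
}

#' Study-like biological fixture: promoter with two motif-rich clusters
#'
#' Emulates the statistical regime of a ~4.7 kb vertebrate promoter region
#' carrying roughly twice as many NGGGNN sites as its own composition
#' predicts, concentrated in two clusters (as seen upstream of first and
#' second exons of enriched promoters). Sites are planted into the two
#' clusters — with C-biased, G-free flanks, so planted sites are
#' higher-quality under the returned binding model than chance hits —
#' until the count reaches twice the expectation implied by the sequence's
#' *measured* composition. Returns everything a full analysis needs.
#'
#' @param seed Integer RNG seed.
#' @return A list with `sequence` (length-1 `DNAStringSet`; `metadata()`
#'   carries the planted truth), `profile` (the measured
#'   [CompositionProfile-class], as an analysis of a real region would use),
#'   `pwm` (a width-6 binding model with a 0.9 G core and C-leaning
#'   flanks), and `truth` (clusters, planted starts, final count).
#' @examples
#' fx <- makeStudyLikePair(seed = 7)
#' fx$sequence
#' @export
makeStudyLikePair <- function(seed) {
    L <- 4662L
    baseComp <- c(A = 0.30, C = 0.24, G = 0.20, T = 0.26)
    clusters <- IRanges::IRanges(start = c(1200L, 3300L),
                                 end = c(2199L, 4299L))
    flankProbs <- c(A = 0.25, C = 0.50, G = 0, T = 0.25)
    set.seed(deriveSeed(seed, "study-like"))
    chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                    prob = baseComp)
    allowed <- unlist(lapply(seq_along(clusters), function(i)
        seq.int(BiocGenerics::start(clusters)[i],
                BiocGenerics::end(clusters)[i] - 5L)))
    measuredLambda <- function(ch)
        (L - 5) * (sum(ch == "G") / L)^3
    planted <- integer(0)
    # plant non-overlapping sites until the count is ~2x the
    # measured-composition expectation; G-free flanks keep the measured G
    # content from chasing the target
    while (countGCore(chars) < 2 * measuredLambda(chars)) {
        if (length(allowed) == 0L)
            stop("fixture generation exhausted the cluster intervals")
        w <- allowed[sample.int(length(allowed), 1L)]
        allowed <- allowed[abs(allowed - w) > 5L]
        flanks <- sample(c("A", "C", "T"), 3L, replace = TRUE,
                         prob = c(0.25, 0.5, 0.25))
        chars[w:(w + 5L)] <- c(flanks[1L], "G", "G", "G",
                               flanks[2L], flanks[3L])
        planted <- c(planted, w)
    }
    seqset <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
    names(seqset) <- "synthetic_promoter"
    profile <- baseComposition(seqset)
    fr <- cbind(flankProbs,
                c(A = 1, C = 1, G = 27, T = 1) / 30,
                c(A = 1, C = 1, G = 27, T = 1) / 30,
                c(A = 1, C = 1, G = 27, T = 1) / 30,
                flankProbs, flankProbs)
    pwm <- PositionWeightMatrix(fr, name = "study-like-motif")
    truth <- list(seed = seed, length = L, clusters = clusters,
                  generatingComposition = baseComp,
                  plantedStarts = planted,
                  finalCount = countGCore(chars),
                  measuredLambda = measuredLambda(chars))
    S4Vectors::metadata(seqset) <- list(truth = truth)
    list(sequence = seqset, profile = profile, pwm = pwm, truth = truth)
}

#' Write a synthetic fixture to disk
#'
#' Dumps a scenario sequence as FASTA next to a JSON file of the planted
#' truth (positions, fold, clusters), for regression tests.
#'
#' @param scenario A [syntheticScenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
writeFixture <- function(scenario, dir) {
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    seq <- makeScenarioSequence(scenario)
    fa <- file.path(dir, paste0(scenario$label, ".fa"))
    js <- file.path(dir, paste0(scenario$label, ".truth.json"))
    writeFastaSequences(seq, fa)
    truth <- S4Vectors::metadata(seq)$truth
    truth$clusterIntervals <- if (is.null(scenario$clusterIntervals)) NULL
        else data.frame(start = BiocGenerics::start(scenario$clusterIntervals),
                        end = BiocGenerics::end(scenario$clusterIntervals))
    jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA)
    invisible(c(fasta = fa, truth = js))
}
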