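#' Analysis configuration
#'
#' Validated parameter bag for [runAnalysis()]. Defaults are the study
#' conditions of the underlying protocol: 10,000 background sequences,
#' 1,000 Kruskal-Wallis replicates at alpha 0.05, a symmetric Beta(0.35,
#' 0.35) prior with 100,000 posterior draws, a 150-nt sliding window with
#' step 1, natural-log logL, one-sided (enrichment) Z test, sense-strand
#' scanning.
#'
#' @param pattern IUPAC consensus string.
#' @param nBackground Null ensemble size.
#' @param window,step Sliding-window width and step (bp).
#' @param nKwReps Kruskal-Wallis replicates.
#' @param alpha KW significance level.
#' @param priorA,priorB Beta prior shapes for the A/B test.
#' @param nAbDraws Posterior draws for the A/B test.
#' @param loglBase `"e"`, `"2"` or `"10"`.
#' @param zDirection `"greater"` or `"two-sided"`.
#' @param strands `"sense"` or `"both"`.
#' @param nMcSims Monte-Carlo simulations for the count p-value.
#' @param thresholdMethod `"pwm-expectation"` or `"explicit"`.
#' @param thresholdValue Cutoff when `thresholdMethod = "explicit"`.
#' @param nSelexSample Size of the PWM-sampled logL reference used for the
#'   normality check.
#' @param seed Top-level integer seed; every stochastic stage derives its
#'   own substream from it.
#' @return A classed list (`"analysisConfig"`).
#' @export
analysisConfig <- function(pattern = "NGGGNN", nBackground = 10000L,
                           window = 150L, step = 1L, nKwReps = 1000L,
                           alpha = 0.05, priorA = 0.35, priorB = 0.35,
                           nAbDraws = 100000L,
                           loglBase = c("e", "2", "10"),
                           zDirection = c("greater", "two-sided"),
                           strands = c("sense", "both"),
                           nMcSims = 2000L,
                           thresholdMethod = c("pwm-expectation",
                                               "explicit"),
                           thresholdValue = NULL,
                           nSelexSample = 500L, seed = 1L) {
    loglBase <- match.arg(loglBase)
    zDirection <- match.arg(zDirection)
    strands <- match.arg(strands)
    thresholdMethod <- match.arg(thresholdMethod)
    m <- length(iupacSets(pattern))
    cfg <- list(pattern = toupper(pattern),
                nBackground = as.integer(nBackground),
                window = as.integer(window), step = as.integer(step),
                nKwReps = as.integer(nKwReps), alpha = alpha,
                priorA = priorA, priorB = priorB,
                nAbDraws = as.integer(nAbDraws), loglBase = loglBase,
                zDirection = zDirection, strands = strands,
                nMcSims = as.integer(nMcSims),
                thresholdMethod = thresholdMethod,
                thresholdValue = thresholdValue,
                nSelexSample = as.integer(nSelexSample),
                seed = as.integer(seed))
    counts <- c("nBackground", "window", "step", "nKwReps", "nAbDraws",
                "nMcSims", "nSelexSample")
    for (nm in counts)
        if (cfg[[nm]] < 1L)
            stop("'", nm, "' must be a positive count")
    if (cfg$window < m)
        stop("'window' must be at least the pattern width (", m, ")")
    if (alpha <= 0 || alpha >= 1)
        stop("'alpha' must be in (0, 1)")
    if (priorA <= 0 || priorB <= 0)
        stop("Beta prior shapes must be positive")
    if (thresholdMethod == "explicit" &&
        (is.null(thresholdValue) || !is.finite(thresholdValue)))
        stop("thresholdMethod 'explicit' requires a finite 'thresholdValue'")
    structure(cfg, class = "analysisConfig")
}

#' @export
print.analysisConfig <- function(x, ...) {
    cat("analysisConfig:", x$pattern, "| nBackground", x$nBackground,
        "| window", paste0(x$window, "/", x$step),
        "| KW", paste0(x$nKwReps, "@", x$alpha),
        "| prior Beta(", x$priorA, ",", x$priorB, ") x", x$nAbDraws,
        "| seed", x$seed, "\n")
    invisible(x)
}

# Scan a null ensemble and return pooled site logLs plus per-member counts.
scanEnsembleLogLs <- function(ensemble, pattern, pwm, bg, base) {
    seqs <- nullSequences(ensemble)
    counts <- motifCounts(seqs, pattern = pattern)
    mi <- Biostrings::vmatchPattern(
        pattern, seqs, fixed = c(pattern = FALSE, subject = TRUE))
    sites <- as.character(unlist(suppressWarnings(
        Biostrings::extractAt(seqs, methods::as(mi, "IRangesList")))))
    memberIdx <- rep.int(seq_along(seqs),
                         S4Vectors::elementNROWS(mi))
    logls <- siteLogL(sites, pwm, bg, base = base)$logL
    list(counts = counts, logls = logls, memberIdx = memberIdx)
}

#' Run the full motif-enrichment analysis
#'
#' Executes, per input sequence: composition profiling, composition-matched
#' null ensemble, motif scanning of both, null count summary and KDE,
#' one-sample Z-test, analytic expectation, compound-Poisson and
#' Monte-Carlo global enrichment tests, logL scoring, success threshold
#' plus normality check of the binding-model logL sample, replicated
#' Kruskal-Wallis quality comparison, Beta A/B success-rate test, and the
#' sliding-window profile. Each input sequence is processed independently;
#' no cross-sequence multiple-testing correction is applied.
#'
#' @param fasta Path to a FASTA file, or a `DNAStringSet`.
#' @param pwm Path to a PWM file (see [readPWM()]), or a
#'   [PositionWeightMatrix-class].
#' @param config An [analysisConfig()].
#' @param outDir Optional directory; when given, writes `report.json` plus
#'   per-sequence `*_hits.bed`, `*_windows.tsv`, `*_null_counts.tsv`.
#' @param nullEnsembles Optional named list of precomputed
#'   [NullEnsemble-class] objects (names = sequence ids) to reuse instead
#'   of simulating; must match each sequence's length.
#' @return An [EnrichmentReport-class].
#' @examples
#' fx <- makeStudyLikePair(seed = 1)
#' cfg <- analysisConfig(nBackground = 200, nKwReps = 50, nMcSims = 1000,
#'                       nAbDraws = 20000, seed = 1)
#' \donttest{
#' rep <- runAnalysis(fx$sequence, fx$pwm, cfg)
#' rep
#' }
#' @export
runAnalysis <- function(fasta, pwm, config = analysisConfig(),
                        outDir = NULL, nullEnsembles = NULL) {
    stopifnot(inherits(config, "analysisConfig"))
    checksums <- list()
    if (is.character(fasta)) {
        checksums$fasta <- unname(md5sum(fasta))
        seqs <- readFastaSequences(fasta)
    } else {
        seqs <- asDNAStringSet(fasta)
        checkAlphabet(seqs)
    }
    if (is.character(pwm)) {
        checksums$pwm <- unname(md5sum(pwm))
        pwm <- readPWM(pwm)
    }
    stopifnot(is(pwm, "PositionWeightMatrix"))
    if (length(iupacSets(config$pattern)) != pwmWidth(pwm))
        stop("pattern length must equal the PWM width")

    results <- list()
    for (i in seq_along(seqs)) {
        id <- names(seqs)[i]
        res <- tryCatch(
            analyseOne(seqs[i], id, pwm, config,
                       nullEnsembles[[id]] %||% NULL),
            error = function(e)
                stop("stage failure for sequence '", id, "': ",
                     conditionMessage(e), call. = FALSE))
        results[[id]] <- res
    }
    report <- new("EnrichmentReport", results = results,
                  config = unclass(config),
                  provenance = list(
                      package = "motifEnrich",
                      version = as.character(packageVersion("motifEnrich")),
                      checksums = checksums,
                      sequenceIds = names(seqs),
                      sequenceLengths = unname(
                          BiocGenerics::width(seqs))))
    if (!is.null(outDir))
        writeReport(report, outDir)
    report
}

# Full per-sequence analysis; `ens` optionally reuses a null ensemble.
analyseOne <- function(seqset, id, pwm, config, ens = NULL) {
    seqLen <- BiocGenerics::width(seqset)[1]
    profile <- baseComposition(seqset)
    seed <- config$seed

    if (is.null(ens)) {
        ens <- simulateBackground(profile, length = seqLen,
                                  n = config$nBackground,
                                  seed = deriveSeed(seed,
                                                    paste0("bg:", id)))
    } else {
        stopifnot(is(ens, "NullEnsemble"))
        if (ens@targetLength != seqLen)
            stop("reused ensemble length does not match sequence '",
                 id, "'")
    }

    hits <- scanMotif(seqset, pattern = config$pattern, pwm = pwm,
                      bg = profile, strand = config$strands,
                      base = config$loglBase)
    observed <- length(hits)

    simScan <- scanEnsembleLogLs(ens, config$pattern, pwm, profile,
                                 config$loglBase)
    nullSummary <- nullCountSummary(simScan$counts)
    kde <- kdeCounts(simScan$counts)
    zTest <- oneSampleZ(observed, nullSummary,
                        direction = config$zDirection)
    cp <- compoundPoissonPValue(observed, profile, seqLen,
                                pattern = config$pattern)
    mc <- mcCountPValue(observed, profile, seqLen,
                        pattern = config$pattern,
                        nSims = config$nMcSims,
                        seed = deriveSeed(seed, paste0("mc:", id)))

    threshold <- successThreshold(pwm, profile,
                                  method = config$thresholdMethod,
                                  value = config$thresholdValue,
                                  base = config$loglBase)
    refSites <- samplePWMSites(pwm, config$nSelexSample,
                               seed = deriveSeed(seed,
                                                 paste0("selex:", id)))
    refLogls <- siteLogL(refSites, pwm, profile,
                         base = config$loglBase)$logL
    normality <- tryCatch(logLNormality(refLogls),
                          error = function(e)
                              list(W = NA_real_, p = NA_real_))

    bioLogls <- hits$logL
    kw <- if (observed >= 3 && length(simScan$logls) >= observed)
        kwReplicates(bioLogls, simScan$logls, nReps = config$nKwReps,
                     alpha = config$alpha,
                     seed = deriveSeed(seed, paste0("kw:", id)))
    else list(nReps = config$nKwReps, k = observed, alpha = config$alpha,
              nSignificant = NA_integer_,
              fractionSignificant = NA_real_, pValues = numeric(0),
              seed = NA_integer_)

    successBio <- classifySuccess(bioLogls, threshold)
    successSim <- classifySuccess(simScan$logls, threshold)
    ab <- abBetaTest(successBio, successSim,
                     prior = c(config$priorA, config$priorB),
                     nDraws = config$nAbDraws,
                     seed = deriveSeed(seed, paste0("ab:", id)))

    windows <- windowProfile(hits, seqLength = seqLen, bg = profile,
                             window = config$window, step = config$step,
                             pattern = config$pattern)

    list(id = id, length = seqLen,
         composition = as.list(compositionFreqs(profile)),
         observed = observed, hits = hits,
         nullSummary = nullSummary, kde = kde, zTest = zTest,
         lambda = cp$lambda, compoundPoisson = cp, monteCarlo = mc,
         threshold = threshold, selexNormality = normality,
         kw = kw, successBio = successBio, successSim = successSim,
         abTest = ab, windows = windows)
}

#' Write an enrichment report and its side files
#'
#' Writes `report.json` (stable key order, full-precision numbers — two
#' identical runs produce byte-identical files) plus, per sequence, a BED6
#' hit track, a TSV window profile, and a TSV of the null counts.
#'
#' @param report An [EnrichmentReport-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path of `report.json`.
#' @export
writeReport <- function(report, dir) {
    stopifnot(is(report, "EnrichmentReport"))
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    out <- list(config = report@config, provenance = report@provenance,
                results = lapply(report@results, jsonResult))
    path <- file.path(dir, "report.json")
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    for (id in names(report@results)) {
        r <- report@results[[id]]
        safe <- gsub("[^A-Za-z0-9._-]", "_", id)
        writeBED(r$hits, file.path(dir, paste0(safe, "_hits.bed")),
                 trackName = paste0(id, "_motif_hits"))
        write.table(r$windows,
                    file.path(dir, paste0(safe, "_windows.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(data.frame(count = r$nullSummary$counts),
                    file.path(dir, paste0(safe, "_null_counts.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

# JSON-serialisable view of one per-sequence result block (drops the bulky
# GRanges / per-draw vectors; side files carry those).
jsonResult <- function(r) {
    list(id = r$id, length = r$length, composition = r$composition,
         observed = r$observed,
         null = list(n = r$nullSummary$n, mean = r$nullSummary$mean,
                     sd = r$nullSummary$sd,
                     kdeBandwidth = r$kde$bandwidth),
         zTest = r$zTest[c("z", "pOneSided", "pTwoSided", "p",
                           "direction")],
         lambda = r$lambda,
         compoundPoisson = r$compoundPoisson[c("fold", "pValue", "rho",
                                               "lambdaClump")],
         monteCarlo = r$monteCarlo[c("fold", "pValue", "nSims")],
         threshold = r$threshold,
         selexNormality = r$selexNormality,
         kw = r$kw[c("nReps", "k", "alpha", "nSignificant",
                     "fractionSignificant")],
         successBio = r$successBio[c("successes", "trials", "rate")],
         successSim = r$successSim[c("successes", "trials", "rate")],
         abTest = r$abTest[c("priorA", "priorB", "nDraws", "pBioGreater",
                             "ratioFractionGT1", "mode")],
         topWindow = as.list(r$windows[which.max(r$windows$count)[1],
                                       c("start", "end", "count",
                                         "expected", "pUpper")]))
}
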