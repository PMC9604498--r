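#' Locate all consensus-pattern motif occurrences
#'
#' Scans sequences for every window matching an IUPAC consensus pattern
#' (default `NGGGNN`, where `N` matches A/C/G/T — never a literal `N`
#' residue). Overlapping occurrences are all reported: a `GGGG` run yields
#' two overlapping `GGG` cores. Hit calling is consensus-based; the PWM, if
#' supplied together with a background profile, is used to score the hits,
#' not to call them.
#'
#' @param seqs A `DNAStringSet` (or character vector / `DNAString`).
#' @param pattern IUPAC consensus string (default `"NGGGNN"`).
#' @param pwm Optional [PositionWeightMatrix-class]; with `bg`, adds
#'   `pPwm`, `pBg`, `logL` metadata columns to the hits.
#' @param bg Optional [CompositionProfile-class] used for scoring.
#' @param strand `"sense"` (default) scans the given strand only;
#'   `"both"` also scans the reverse complement and reports minus-strand
#'   hits in plus-strand coordinates.
#' @param base Log base for `logL` (see [scoreSite()]).
#' @return A `GRanges` of hits (1-based, closed; `seqlengths` set from the
#'   input widths), sorted by sequence then start, with metadata column
#'   `site` and, if scored, `pPwm`, `pBg`, `logL`.
#' @examples
#' scanMotif(c(x = "AGGGGAA"))  # two overlapping hits
#' @seealso [windowProfile()], [writeBED()]
#' @export
scanMotif <- function(seqs, pattern = "NGGGNN", pwm = NULL, bg = NULL,
                      strand = c("sense", "both"), base = "e") {
    strand <- match.arg(strand)
    seqs <- asDNAStringSet(seqs)
    checkAlphabet(seqs)
    if (anyDuplicated(names(seqs)))
        stop("sequence names must be unique")
    sets <- iupacSets(pattern)  # validates the pattern
    m <- length(sets)
    sl <- setNames(BiocGenerics::width(seqs), names(seqs))

    scanOne <- function(ss, strandChar) {
        long <- ss[BiocGenerics::width(ss) >= m]
        if (length(long) == 0L)
            return(GenomicRanges::GRanges(seqlengths = sl))
        mi <- Biostrings::vmatchPattern(
            pattern, long, fixed = c(pattern = FALSE, subject = TRUE))
        ir <- unlist(mi)
        if (length(ir) == 0L)
            return(GenomicRanges::GRanges(seqlengths = sl))
        sites <- as.character(unlist(suppressWarnings(
            Biostrings::extractAt(long, methods::as(mi, "IRangesList")))))
        # pattern N must not match a literal N residue
        keep <- !grepl("N", sites, fixed = TRUE)
        gr <- GenomicRanges::GRanges(
            seqnames = factor(names(ir), levels = names(seqs)),
            ranges = IRanges::IRanges(start = BiocGenerics::start(ir),
                                      end = BiocGenerics::end(ir)),
            strand = strandChar, seqlengths = sl)[keep]
        gr$site <- unname(sites[keep])
        gr
    }

    hits <- scanOne(seqs, "+")
    if (strand == "both") {
        # minus-strand occurrences: scan the reverse complement, then map
        # back to plus-strand coordinates
        rc <- Biostrings::reverseComplement(seqs)
        rcHits <- scanOne(rc, "-")
        if (length(rcHits)) {
            L <- sl[as.character(seqnames(rcHits))]
            newStart <- unname(L) - BiocGenerics::end(rcHits) + 1L
            ranges(rcHits) <- IRanges::IRanges(start = newStart, width = m)
        }
        hits <- c(hits, rcHits)
    }
    hits <- BiocGenerics::sort(hits, ignore.strand = TRUE)
    if (!is.null(pwm) && !is.null(bg) && length(hits)) {
        sc <- siteLogL(hits$site, pwm, bg, base = base)
        hits$pPwm <- sc$pPwm
        hits$pBg <- sc$pBg
        hits$logL <- sc$logL
    }
    hits
}

#' Count motif occurrences per sequence
#'
#' Fast per-sequence hit counting; equals `length(scanMotif(...))` per
#' sequence but avoids materialising the hits.
#'
#' @param x A `DNAStringSet`, character vector, or [NullEnsemble-class].
#' @param pattern IUPAC consensus string.
#' @return Named integer vector of counts, one per sequence.
#' @export
motifCounts <- function(x, pattern = "NGGGNN") {
    if (is(x, "NullEnsemble"))
        x <- nullSequences(x)
    seqs <- asDNAStringSet(x)
    m <- length(iupacSets(pattern))
    counts <- setNames(integer(length(seqs)), names(seqs))
    long <- BiocGenerics::width(seqs) >= m
    if (!any(long))
        return(counts)
    hasN <- Biostrings::letterFrequency(seqs[long], "N")[, 1] > 0
    pure <- which(long)[!hasN]
    if (length(pure))
        counts[pure] <- Biostrings::vcountPattern(
            pattern, seqs[pure], fixed = c(pattern = FALSE, subject = TRUE))
    ambig <- which(long)[hasN]
    if (length(ambig)) {
        gr <- scanMotif(seqs[ambig], pattern = pattern)
        tab <- table(factor(as.character(seqnames(gr)),
                            levels = names(seqs)[ambig]))
        counts[ambig] <- as.integer(tab)
    }
    counts
}

#' Sliding-window positional enrichment profile
#'
#' Tiles one sequence with windows (default 150 bp, step 1) and, per
#' window, reports the number of motif hits whose start lies inside it, the
#' count expected under the background composition, and an upper-tail
#' Poisson p-value at that expectation. A hit is assigned to a window iff
#' the whole site fits: start in `[window_start, window_end - m + 1]`.
#'
#' @param hits `GRanges` of hits from [scanMotif()] for a single sequence.
#' @param seqLength Sequence length in bp (defaults to the `seqlengths` of
#'   `hits` when set).
#' @param bg A [CompositionProfile-class] for the expected count.
#' @param window Window width in bp (default 150; must be >= the pattern
#'   width and <= `seqLength`).
#' @param step Step between window starts (default 1, a true sliding
#'   window; `step = window` gives a non-overlapping tiling).
#' @param pattern IUPAC consensus the hits were called with.
#' @return A data.frame with columns `start`, `end` (1-based, closed),
#'   `count`, `expected`, `pUpper`, ordered by `start`; attributes
#'   `window`, `step`, `pattern`.
#' @examples
#' hits <- scanMotif(c(s = "AGGGGAAACGTAGGGTT"))
#' bg <- CompositionProfile(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
#' windowProfile(hits, bg = bg, window = 10)
#' @export
windowProfile <- function(hits, seqLength = NULL, bg, window = 150L,
                          step = 1L, pattern = "NGGGNN") {
    m <- length(iupacSets(pattern))
    window <- as.integer(window)
    step <- as.integer(step)
    if (window < m)
        stop("'window' must be at least the pattern width (", m, ")")
    if (step < 1L)
        stop("'step' must be >= 1")
    if (is.null(seqLength)) {
        sl <- seqlengths(hits)
        if (length(sl) != 1L || is.na(sl))
            stop("supply 'seqLength' (hits carry no unique seqlength)")
        seqLength <- sl
    }
    seqLength <- as.integer(seqLength)
    if (window > seqLength)
        stop("'window' exceeds the sequence length")
    if (length(hits) &&
        length(unique(as.character(seqnames(hits)))) > 1L)
        stop("windowProfile expects hits from a single sequence")

    starts <- seq.int(1L, seqLength - window + 1L, by = step)
    tab <- tabulate(BiocGenerics::start(hits), nbins = seqLength)
    cum0 <- c(0L, cumsum(tab))
    count <- cum0[starts + window - m + 1L] - cum0[starts]
    pHit <- patternMatchProb(bg, pattern)
    expected <- (window - m + 1) * pHit
    pUpper <- ppois(count - 1, lambda = expected, lower.tail = FALSE)
    out <- data.frame(start = starts, end = starts + window - 1L,
                      count = as.integer(count), expected = expected,
                      pUpper = pUpper)
    attr(out, "window") <- window
    attr(out, "step") <- step
    attr(out, "pattern") <- pattern
    out
}

#' Write motif hits as a BED6 track
#'
#' One BED line per hit: 0-based half-open coordinates, name = site string,
#' score = logL mapped affinely to `[0, 1000]` (the map is recorded in the
#' track header), strand as called.
#'
#' @param hits `GRanges` from [scanMotif()].
#' @param path Output file path.
#' @param trackName Track name for the header line.
#' @return `path`, invisibly.
#' @export
writeBED <- function(hits, path, trackName = "motif_hits") {
    if (length(hits) && !is.null(hits$logL)) {
        lo <- min(hits$logL)
        hi <- max(hits$logL)
        score <- if (hi > lo)
            as.integer(round(1000 * (hits$logL - lo) / (hi - lo)))
        else rep(500L, length(hits))
        desc <- sprintf("score=round(1000*(logL-%.6g)/(%.6g-%.6g))",
                        lo, hi, lo)
    } else {
        score <- rep(0L, length(hits))
        desc <- "score=0 (hits not scored)"
    }
    header <- sprintf('track name="%s" description="%s"', trackName, desc)
    lines <- character(0)
    if (length(hits)) {
        std <- as.character(BiocGenerics::strand(hits))
        std[std == "*"] <- "+"
        lines <- paste(as.character(seqnames(hits)),
                       BiocGenerics::start(hits) - 1L,
                       BiocGenerics::end(hits),
                       hits$site, score, std, sep = "\t")
    }
    writeLines(c(header, lines), path)
    invisible(path)
}
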