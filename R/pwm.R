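#' Read a position weight matrix from a tab-delimited file
#'
#' The file must hold a 4-row matrix (rows labelled A, C, G, T in the first
#' column) of per-position counts or frequencies, tab-delimited. Columns are
#' normalised to frequencies and a pseudocount is folded in (see
#' [PositionWeightMatrix()]).
#'
#' @param path Path to the matrix file.
#' @param pseudocount Probability floor (default `1e-4`).
#' @param name Motif label (default: file base name).
#' @return A [PositionWeightMatrix-class].
#' @export
readPWM <- function(path, pseudocount = 1e-4, name = NULL) {
    if (!file.exists(path))
        stop("PWM file not found: ", path)
    tab <- tryCatch(
        read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE),
        error = function(e)
            stop("cannot parse PWM file '", path, "': ",
                 conditionMessage(e), call. = FALSE))
    if (nrow(tab) != 4L)
        stop("PWM file must have exactly 4 rows (A, C, G, T); found ",
             nrow(tab))
    labels <- toupper(as.character(tab[[1]]))
    if (!setequal(labels, c("A", "C", "G", "T")))
        stop("PWM rows must be labelled A, C, G, T in the first column")
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m))
        stop("PWM file contains non-numeric cells")
    rownames(m) <- labels
    PositionWeightMatrix(m, pseudocount = pseudocount,
                         name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a position weight matrix to a tab-delimited file
#'
#' @param pwm A [PositionWeightMatrix-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePWM <- function(pwm, path) {
    stopifnot(is(pwm, "PositionWeightMatrix"))
    write.table(pwmFreqs(pwm), file = path, sep = "\t", quote = FALSE,
                col.names = FALSE, row.names = TRUE)
    invisible(path)
}

# Vectorised per-site log-likelihood ratio. Internal workhorse behind
# scoreSite() and the pipeline's bulk scoring.
siteLogL <- function(sites, pwm, bg, base = c("e", "2", "10")) {
    base <- match.arg(base)
    stopifnot(is(pwm, "PositionWeightMatrix"), is(bg, "CompositionProfile"))
    m <- pwmWidth(pwm)
    if (length(sites) == 0L)
        return(data.frame(site = character(0), pPwm = numeric(0),
                          pBg = numeric(0), logL = numeric(0)))
    if (any(nchar(sites) != m))
        stop("all sites must have the PWM width (", m, ")")
    letters <- matrix(unlist(strsplit(sites, ""), use.names = FALSE),
                      nrow = m)
    idx <- match(letters, c("A", "C", "G", "T"))
    if (anyNA(idx))
        stop("unscorable site: residues outside {A,C,G,T} ",
             "(sites containing N must be skipped by the caller)")
    bgFreq <- compositionFreqs(bg)
    if (any(bgFreq <= 0))
        stop("background composition must be strictly positive ",
             "for log-likelihood scoring")
    lp <- matrix(log(pwmFreqs(pwm))[cbind(idx, as.vector(row(letters)))],
                 nrow = m)
    lq <- matrix(log(bgFreq)[idx], nrow = m)
    logl <- colSums(lp) - colSums(lq)
    conv <- switch(base, e = 1, `2` = log(2), `10` = log(10))
    data.frame(site = sites, pPwm = exp(colSums(lp)), pBg = exp(colSums(lq)),
               logL = logl / conv, stringsAsFactors = FALSE)
}

#' Score one motif site against PWM and background
#'
#' Computes `P(site | PWM)` and `P(site | background)` as products of
#' per-position frequencies, and the log-likelihood ratio
#' `logL = log(P(site|PWM) / P(site|bg))` (natural log by default). This is
#' the per-site binding-quality score.
#'
#' @param site A string over `{A,C,G,T}` of the PWM width. A site
#'   containing `N` is unscorable and raises an error.
#' @param pwm A [PositionWeightMatrix-class].
#' @param bg A [CompositionProfile-class]; all four frequencies must be
#'   strictly positive.
#' @param base Log base for `logL`: `"e"` (default), `"2"`, or `"10"`.
#' @return A one-row data.frame with columns `site`, `pPwm`, `pBg`, `logL`.
#' @examples
#' pwm <- makeToyPWM(0.9)
#' bg <- CompositionProfile(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
#' scoreSite("AGGGTT", pwm, bg)
#' @export
scoreSite <- function(site, pwm, bg, base = c("e", "2", "10")) {
    stopifnot(length(site) == 1L)
    siteLogL(site, pwm, bg, base = base)
}

#' Success threshold for motif quality classification
#'
#' A motif occurrence is called "successful" when its logL exceeds the mean
#' logL of sites drawn from the binding model itself. With only the PWM
#' published, that reference mean is computed as the expectation of logL
#' under the PWM — which is exactly the per-position sum of Kullback-Leibler
#' divergences of the PWM columns from the background (in the chosen log
#' base); the expectation over all `4^m` sites factorises position by
#' position. Method `"explicit"` instead accepts a user-supplied cutoff
#' (e.g. the mean logL of an actual list of selection-experiment sites).
#'
#' @param pwm A [PositionWeightMatrix-class].
#' @param bg A [CompositionProfile-class].
#' @param method `"pwm-expectation"` (default) or `"explicit"`.
#' @param value Cutoff for `method = "explicit"`.
#' @param base Log base, as in [scoreSite()].
#' @return A list with `value` (the cutoff) and `method`.
#' @examples
#' bg <- CompositionProfile(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
#' successThreshold(makeToyPWM(0.9), bg)
#' @export
successThreshold <- function(pwm, bg,
                             method = c("pwm-expectation", "explicit"),
                             value = NULL, base = c("e", "2", "10")) {
    method <- tryCatch(match.arg(method),
                       error = function(e) stop("unknown threshold method: ",
                                                method[1], call. = FALSE))
    base <- match.arg(base)
    if (method == "explicit") {
        if (is.null(value) || !is.finite(value))
            stop("method 'explicit' requires a finite 'value'")
        return(list(value = as.numeric(value), method = method))
    }
    stopifnot(is(pwm, "PositionWeightMatrix"), is(bg, "CompositionProfile"))
    bgFreq <- compositionFreqs(bg)
    if (any(bgFreq <= 0))
        stop("background composition must be strictly positive")
    fr <- pwmFreqs(pwm)
    kl <- sum(vapply(seq_len(ncol(fr)), function(j)
        sum(fr[, j] * log(fr[, j] / bgFreq)), numeric(1)))
    conv <- switch(base, e = 1, `2` = log(2), `10` = log(10))
    list(value = kl / conv, method = method)
}

#' Sample sites from a PWM
#'
#' Draws `n` sites position-wise independently from the PWM columns; used to
#' form a reference logL sample (e.g. for the normality check of the
#' binding-model logL distribution).
#'
#' @param pwm A [PositionWeightMatrix-class].
#' @param n Number of sites (>= 1).
#' @param seed Integer RNG seed.
#' @return Character vector of `n` sites.
#' @export
samplePWMSites <- function(pwm, n, seed) {
    stopifnot(is(pwm, "PositionWeightMatrix"))
    n <- as.integer(n)
    if (n < 1L) stop("'n' must be >= 1")
    set.seed(as.integer(seed))
    fr <- pwmFreqs(pwm)
    cols <- lapply(seq_len(ncol(fr)), function(j)
        sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = fr[, j]))
    do.call(paste0, cols)
}

#' Shapiro-Wilk normality check for a logL sample
#'
#' Thin wrapper around [stats::shapiro.test()] with the degenerate cases
#' made explicit: fewer than 3 values, more than 5000 values, or an
#' all-constant sample are errors.
#'
#' @param values Numeric vector of logL scores.
#' @return A list with `W` and `p`.
#' @export
logLNormality <- function(values) {
    values <- as.numeric(values)
    if (length(values) < 3L)
        stop("need at least 3 values")
    if (length(values) > 5000L)
        stop("shapiro.test supports at most 5000 values; subsample first")
    if (diff(range(values)) == 0)
        stop("degenerate sample: all values identical")
    st <- shapiro.test(values)
    list(W = unname(st$statistic), p = st$p.value)
}
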