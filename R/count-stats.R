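#' Summarise per-sequence motif counts of a null ensemble
#'
#' @param counts Integer vector of per-member hit counts (length >= 2).
#' @return A list with `counts`, `n`, `mean`, `sd` (sample SD, n-1
#'   denominator).
#' @seealso [oneSampleZ()], [kdeCounts()]
#' @export
nullCountSummary <- function(counts) {
    counts <- as.numeric(counts)
    if (length(counts) < 2L)
        stop("need at least 2 counts (sample SD undefined)")
    list(counts = counts, n = length(counts),
         mean = mean(counts), sd = stats::sd(counts))
}

#' One-sample Z-test of an observed count against the simulated null
#'
#' Standardises the single observed motif count against the null ensemble:
#' `z = (observed - mean) / sd`. The headline p-value is the upper tail
#' (enrichment direction) by default. The alternative normalisation
#' `sd / sqrt(n)` — which instead treats the simulated mean as the tested
#' statistic — is available via `normalization`.
#'
#' @param observed Observed motif count.
#' @param summary Output of [nullCountSummary()].
#' @param direction `"greater"` (default; headline p is one-sided upper
#'   tail) or `"two-sided"`.
#' @param normalization `"single-observation"` (default) divides by `sd`;
#'   `"mean-standard-error"` divides by `sd / sqrt(n)`.
#' @return A list with `observed`, `z`, `pOneSided`, `pTwoSided`, `p` (the
#'   headline value per `direction`).
#' @examples
#' s <- nullCountSummary(c(60, 70, 65, 68, 62))
#' oneSampleZ(117, s)
#' @export
oneSampleZ <- function(observed, summary,
                       direction = c("greater", "two-sided"),
                       normalization = c("single-observation",
                                         "mean-standard-error")) {
    direction <- match.arg(direction)
    normalization <- match.arg(normalization)
    if (summary$sd <= 0)
        stop("null SD is zero: Z-test undefined")
    denom <- if (normalization == "single-observation") summary$sd
             else summary$sd / sqrt(summary$n)
    z <- (observed - summary$mean) / denom
    pOne <- pnorm(z, lower.tail = FALSE)
    pTwo <- 2 * pnorm(-abs(z))
    list(observed = observed, z = z, pOneSided = pOne, pTwoSided = pTwo,
         p = if (direction == "greater") pOne else pTwo,
         direction = direction, normalization = normalization)
}

#' Analytic expected motif count under the background model
#'
#' Closed form the simulated null converges to:
#' `lambda = (L - m + 1) * prod_j q_j`, where `q_j` is the total background
#' frequency of the bases the pattern allows at position `j`. For `NGGGNN`
#' this is `(L - 5) * p_G^3`.
#'
#' @param bg A [CompositionProfile-class].
#' @param length Sequence length in bp (>= pattern width).
#' @param pattern IUPAC consensus string.
#' @return Expected count `lambda` (numeric).
#' @examples
#' bg <- CompositionProfile(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
#' expectedMotifCount(bg, 1005)  # 1000 * 0.25^3 = 15.625
#' @export
expectedMotifCount <- function(bg, length, pattern = "NGGGNN") {
    m <- length(iupacSets(pattern))
    if (length < m)
        stop("'length' must be at least the pattern width (", m, ")")
    (length - m + 1) * patternMatchProb(bg, pattern)
}

# Self-overlap structure of a pattern under an i.i.d. background.
# For each shift d in 1..m-1 the conditional probability gamma_d of a match
# at t+d given a match at t is computed by enumerating the per-position
# intersection of the two instances' allowed base sets. Shifts whose
# gamma_d exceeds the unconditional match probability are the "principal"
# overlaps (for NGGGNN: d = 1, 2, from the shared G core); rho, the
# probability that a hit is continued by an overlapping hit, is their
# inclusion-exclusion union. For NGGGNN rho reduces to p_G.
patternSelfOverlap <- function(bg, pattern) {
    freq <- compositionFreqs(bg)
    sets <- iupacSets(pattern)
    m <- length(sets)
    setProb <- function(s) sum(freq[s])
    q <- prod(vapply(sets, setProb, numeric(1)))
    jointProb <- function(offsets) {
        span <- max(offsets) + m
        posSets <- vector("list", span)
        for (o in offsets) {
            for (j in seq_len(m)) {
                k <- o + j
                posSets[[k]] <- if (is.null(posSets[[k]])) sets[[j]]
                                else intersect(posSets[[k]], sets[[j]])
            }
        }
        prod(vapply(posSets, function(s)
            if (is.null(s)) 1 else setProb(s), numeric(1)))
    }
    if (q == 0)
        return(list(q = 0, gamma = numeric(0), principal = integer(0),
                    rho = 0))
    gamma <- vapply(seq_len(m - 1), function(d) jointProb(c(0L, d)) / q,
                    numeric(1))
    principal <- which(gamma > q * (1 + 1e-9) & gamma > 0)
    rho <- 0
    if (length(principal)) {
        for (k in seq_along(principal)) {
            combs <- utils::combn(principal, k, simplify = FALSE)
            sgn <- (-1)^(k + 1)
            rho <- rho + sgn * sum(vapply(combs, function(s)
                jointProb(c(0L, s)) / q, numeric(1)))
        }
    }
    list(q = q, gamma = gamma, principal = principal,
         rho = min(max(rho, 0), 1 - 1e-12))
}

# Upper tail P(X >= obs) of a Polya-Aeppli (compound Poisson with geometric
# clump sizes) distribution, via the Panjer recursion on the exact PMF.
polyaAeppliUpper <- function(obs, lambdaClump, rho) {
    if (obs <= 0)
        return(1)
    if (rho <= 0)
        return(ppois(obs - 1, lambdaClump, lower.tail = FALSE))
    g0 <- exp(-lambdaClump)
    if (obs == 1)
        return(1 - g0)
    xmax <- obs - 1
    f <- (1 - rho) * rho^(seq_len(xmax) - 1)  # clump-size PMF, k = 1..xmax
    g <- numeric(xmax)
    for (x in seq_len(xmax)) {
        y <- seq_len(x)
        prev <- c(g0, g)[x - y + 1L]  # g[x - y], with g[0] = g0
        g[x] <- (lambdaClump / x) * sum(y * f[y] * prev)
    }
    max(0, 1 - g0 - sum(g))
}

#' Compound-Poisson global enrichment test
#'
#' Models the motif hit count of an i.i.d.-background sequence as compound
#' Poisson (Polya-Aeppli): clumps of overlapping hits arrive as a Poisson
#' process and clump sizes are geometric. Self-overlap of the pattern (for
#' `NGGGNN`, the shared G core at shifts 1 and 2: G-runs make hits clump)
#' is handled exactly: the per-shift conditional match probabilities are
#' enumerated, giving the exact mean and variance of the count over the
#' finite sequence, and the clump parameters are fitted to those two
#' moments (`rho = (V - lambda) / (V + lambda)`,
#' `lambda_c = lambda (1 - rho)`; for long sequences `rho` approaches the
#' overlap-continuation probability, `p_G` for `NGGGNN`). Returns the
#' upper-tail probability of the observed count and the fold enrichment
#' `observed / lambda`. With no self-overlap the variance drops to (just
#' below) the mean, `rho` is clipped to 0, and the test reduces to a plain
#' Poisson upper tail.
#'
#' @param observed Observed hit count (>= 0).
#' @param bg A [CompositionProfile-class].
#' @param length Sequence length in bp.
#' @param pattern IUPAC consensus string.
#' @return A list with `observed`, `lambda` (analytic expectation), `fold`,
#'   `pValue`, `rho`, `lambdaClump`, `variance` (exact count variance),
#'   `method = "compound-poisson"`.
#' @seealso [mcCountPValue()] for the Monte-Carlo cross-check.
#' @export
compoundPoissonPValue <- function(observed, bg, length,
                                  pattern = "NGGGNN") {
    if (observed < 0)
        stop("'observed' must be non-negative")
    lambda <- expectedMotifCount(bg, length, pattern)
    if (lambda <= 0)
        stop("analytic expectation is zero under this background")
    ov <- patternSelfOverlap(bg, pattern)
    m <- length(iupacSets(pattern))
    M <- length - m + 1
    q <- ov$q
    # exact variance: window indicators correlate only at overlapping
    # shifts (gamma_d = q for core-disjoint shifts contributes 0)
    V <- M * q * (1 - q) +
        2 * sum((M - seq_along(ov$gamma)) * q * (ov$gamma - q))
    rho <- min(max((V - lambda) / (V + lambda), 0), 1 - 1e-12)
    lambdaClump <- lambda * (1 - rho)
    list(observed = observed, lambda = lambda, fold = observed / lambda,
         pValue = polyaAeppliUpper(observed, lambdaClump, rho),
         rho = rho, lambdaClump = lambdaClump, variance = V,
         method = "compound-poisson")
}

#' Monte-Carlo global enrichment test
#'
#' Simulation counterpart of [compoundPoissonPValue()]: generates `nSims`
#' background sequences, counts pattern hits in each, and reports the
#' add-one-corrected empirical upper tail
#' `p = (1 + #\{count >= observed\}) / (nSims + 1)` (never exactly 0).
#'
#' @param observed Observed hit count.
#' @param bg A [CompositionProfile-class].
#' @param length Sequence length in bp.
#' @param pattern IUPAC consensus string.
#' @param nSims Number of simulated sequences (>= 1000).
#' @param seed Integer RNG seed.
#' @return A list with `observed`, `lambda`, `fold`, `pValue`, `nSims`,
#'   `counts` (the simulated counts), `method = "monte-carlo"`.
#' @export
mcCountPValue <- function(observed, bg, length, pattern = "NGGGNN",
                          nSims = 2000L, seed = 1L) {
    nSims <- as.integer(nSims)
    if (nSims < 1000L)
        stop("'nSims' must be >= 1000")
    lambda <- expectedMotifCount(bg, length, pattern)
    ens <- simulateBackground(bg, length = length, n = nSims, seed = seed)
    counts <- motifCounts(ens, pattern = pattern)
    p <- (1 + sum(counts >= observed)) / (nSims + 1)
    list(observed = observed, lambda = lambda, fold = observed / lambda,
         pValue = p, nSims = nSims, counts = unname(counts),
         method = "monte-carlo")
}

#' Gaussian kernel density summary of null counts
#'
#' Density of the per-member null counts on an even grid spanning
#' `[min - 3 bw, max + 3 bw]`; bandwidth defaults to Silverman's
#' rule-of-thumb.
#'
#' @param counts Numeric vector (length >= 2).
#' @param bandwidth Kernel bandwidth in count units; `NULL` for Silverman.
#' @param gridSize Number of grid points.
#' @return A list with `grid`, `density`, `bandwidth`, `n`.
#' @export
kdeCounts <- function(counts, bandwidth = NULL, gridSize = 512L) {
    counts <- as.numeric(counts)
    if (length(counts) < 2L)
        stop("need at least 2 counts")
    if (is.null(bandwidth)) {
        if (diff(range(counts)) == 0)
            stop("constant sample: supply an explicit bandwidth")
        bandwidth <- bw.nrd0(counts)
    }
    if (bandwidth <= 0)
        stop("'bandwidth' must be > 0")
    d <- density(counts, bw = bandwidth, kernel = "gaussian",
                 from = min(counts) - 3 * bandwidth,
                 to = max(counts) + 3 * bandwidth, n = gridSize)
    list(grid = d$x, density = d$y, bandwidth = bandwidth,
         n = length(counts))
}
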