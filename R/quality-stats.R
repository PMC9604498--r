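#' Subsample a pooled logL collection
#'
#' Draws `k` values without replacement from the pooled simulated-motif
#' logL collection; one replicate's comparison sample.
#'
#' @param pool Numeric vector of pooled logL values.
#' @param k Subsample size (<= pool size).
#' @param seed Integer RNG seed.
#' @return Numeric vector of `k` values.
#' @export
poolSubsample <- function(pool, k, seed) {
    k <- as.integer(k)
    if (k > length(pool))
        stop("'k' exceeds the pool size")
    set.seed(as.integer(seed))
    pool[sample.int(length(pool), k)]
}

#' Replicated Kruskal-Wallis comparison of logL distributions
#'
#' Repeats `nReps` times: draw from the pooled simulated-motif logL values
#' a fresh subsample of the same size as the biological collection, and run
#' a two-group Kruskal-Wallis rank test (chi-square approximation with tie
#' correction) between the biological values and the subsample. Reports how
#' often the test was significant at `alpha`.
#'
#' @param bioLogls Numeric vector of biological-site logL values (>= 3).
#' @param simPool Numeric vector of pooled simulated-site logL values
#'   (>= `length(bioLogls)`).
#' @param nReps Number of replicates (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer RNG seed.
#' @return A list with `nReps`, `k`, `alpha`, `nSignificant`,
#'   `fractionSignificant`, `pValues`, `seed`.
#' @export
kwReplicates <- function(bioLogls, simPool, nReps = 1000L, alpha = 0.05,
                         seed = 1L) {
    bioLogls <- as.numeric(bioLogls)
    simPool <- as.numeric(simPool)
    if (length(bioLogls) < 3L || length(simPool) < 3L)
        stop("both logL collections need at least 3 values")
    k <- length(bioLogls)
    if (k > length(simPool))
        stop("simulated pool smaller than the biological collection")
    if (diff(range(c(bioLogls, simPool))) == 0)
        stop("degenerate data: every logL value is identical")
    nReps <- as.integer(nReps)
    set.seed(as.integer(seed))
    pv <- vapply(seq_len(nReps), function(i) {
        sub <- simPool[sample.int(length(simPool), k)]
        p <- suppressWarnings(
            kruskal.test(list(bioLogls, sub))$p.value)
        if (is.na(p)) 1 else p
    }, numeric(1))
    nSig <- sum(pv < alpha)
    list(nReps = nReps, k = k, alpha = alpha, nSignificant = nSig,
         fractionSignificant = nSig / nReps, pValues = pv,
         seed = as.integer(seed))
}

#' Classify motif occurrences as binding successes
#'
#' A motif is a "success" when its logL strictly exceeds the threshold
#' (ties count as failures).
#'
#' @param logls Numeric vector of logL values.
#' @param threshold A [successThreshold()] result, or a single number.
#' @return A list with `successes`, `trials`, `rate`, `threshold`.
#' @export
classifySuccess <- function(logls, threshold) {
    if (is.list(threshold))
        thr <- threshold$value
    else thr <- as.numeric(threshold)
    stopifnot(length(thr) == 1L, is.finite(thr) || is.infinite(thr))
    s <- sum(logls > thr)
    n <- length(logls)
    list(successes = s, trials = n,
         rate = if (n > 0) s / n else NA_real_,
         threshold = thr)
}

#' Monte-Carlo Beta A/B test of success rates
#'
#' Compares the biological and simulated motif success rates through their
#' Beta posteriors: with a `Beta(priorA, priorB)` prior on each rate, the
#' posterior for a side with `s` successes in `t` trials is
#' `Beta(priorA + s, priorB + t - s)`. `nDraws` independent posterior pairs
#' are drawn and the fraction with `rate_bio > rate_sim` is reported — by
#' construction identical (up to measure-zero ties) to the fraction of
#' draws whose rate ratio exceeds 1, which is what the ratio ECDF displays.
#'
#' When `sim` is a list of per-ensemble-member success counts, each draw
#' samples a member uniformly and draws the simulated rate from that
#' member's posterior (the ratio-distribution-across-members variant).
#'
#' @param bio [classifySuccess()] result for the biological sites.
#' @param sim [classifySuccess()] result for the pooled simulated sites, or
#'   a list of such results (one per ensemble member).
#' @param prior Length-2 numeric, the Beta shape parameters (default
#'   `c(0.35, 0.35)`).
#' @param nDraws Number of posterior draws (default 100000).
#' @param seed Integer RNG seed.
#' @return A list with `priorA`, `priorB`, `nDraws`, `pBioGreater`,
#'   `ratioFractionGT1`, `posteriorBio`, `posteriorSim`, `seed`, `mode`.
#' @seealso [abPosteriorExact()] for the deterministic quadrature value.
#' @export
abBetaTest <- function(bio, sim, prior = c(0.35, 0.35), nDraws = 100000L,
                       seed = 1L) {
    stopifnot(length(prior) == 2L, all(prior > 0))
    nDraws <- as.integer(nDraws)
    if (bio$trials < 1L)
        stop("biological side has no trials")
    set.seed(as.integer(seed))
    x <- rbeta(nDraws, prior[1] + bio$successes,
               prior[2] + bio$trials - bio$successes)
    if (!is.null(sim$successes)) {
        if (sim$trials < 1L)
            stop("simulated side has no trials")
        y <- rbeta(nDraws, prior[1] + sim$successes,
                   prior[2] + sim$trials - sim$successes)
        mode <- "pooled"
        postSim <- c(prior[1] + sim$successes,
                     prior[2] + sim$trials - sim$successes)
    } else {
        s <- vapply(sim, `[[`, numeric(1), "successes")
        t <- vapply(sim, `[[`, numeric(1), "trials")
        if (any(t < 1))
            stop("every ensemble member needs at least one trial")
        j <- sample.int(length(sim), nDraws, replace = TRUE)
        y <- rbeta(nDraws, prior[1] + s[j], prior[2] + t[j] - s[j])
        mode <- "per-member"
        postSim <- NULL
    }
    list(priorA = prior[1], priorB = prior[2], nDraws = nDraws,
         pBioGreater = mean(x > y), ratioFractionGT1 = mean(x / y > 1),
         posteriorBio = c(prior[1] + bio$successes,
                          prior[2] + bio$trials - bio$successes),
         posteriorSim = postSim, seed = as.integer(seed), mode = mode)
}

#' Exact posterior probability P(rate_bio > rate_sim)
#'
#' Deterministic counterpart of [abBetaTest()]: integrates the biological
#' posterior density against the simulated posterior CDF,
#' `P(X > Y) = int f_bio(x) F_sim(x) dx`, by adaptive quadrature to
#' absolute error <= 1e-6.
#'
#' @inheritParams abBetaTest
#' @return A single probability.
#' @export
abPosteriorExact <- function(bio, sim, prior = c(0.35, 0.35)) {
    stopifnot(length(prior) == 2L, all(prior > 0))
    a1 <- prior[1] + bio$successes
    b1 <- prior[2] + bio$trials - bio$successes
    a2 <- prior[1] + sim$successes
    b2 <- prior[2] + sim$trials - sim$successes
    res <- tryCatch(
        integrate(function(x) dbeta(x, a1, b1) * pbeta(x, a2, b2),
                  lower = 0, upper = 1, rel.tol = 1e-10, abs.tol = 1e-9,
                  subdivisions = 2000L),
        error = function(e)
            stop("posterior integration did not converge: ",
                 conditionMessage(e), call. = FALSE))
    min(max(res$value, 0), 1)
}
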