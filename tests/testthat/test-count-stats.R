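test_that("null count summary uses the n-1 sample SD", {
    s <- nullCountSummary(c(2, 4))
    expect_equal(s$mean, 3)
    expect_equal(s$sd, sqrt(2))
    expect_equal(nullCountSummary(rep(7, 10))$sd, 0)
    expect_error(nullCountSummary(5), "at least 2")
    set.seed(701)
    x <- rpois(10000, 60)
    s2 <- nullCountSummary(x)
    expect_equal(s2$mean, sum(x) / length(x), tolerance = 1e-12)
    expect_equal(s2$sd, sqrt(sum((x - mean(x))^2) / (length(x) - 1)),
                 tolerance = 1e-12)
})

test_that("one-sample Z-test matches the closed form and normal tail", {
    s <- list(counts = NULL, n = 10000, mean = 65.45, sd = 9.63)
    z <- oneSampleZ(117, s)
    expect_equal(z$z, (117 - 65.45) / 9.63, tolerance = 1e-12)
    expect_equal(z$pOneSided, pnorm((117 - 65.45) / 9.63,
                                    lower.tail = FALSE))
    expect_lt(z$pOneSided, 1e-5)

    at_mean <- oneSampleZ(65.45, s)
    expect_equal(at_mean$z, 0)
    expect_equal(at_mean$pTwoSided, 1)

    # monotone in the observation; two-sided = twice the smaller one-sided
    zs <- vapply(c(60, 70, 90, 120), function(o) oneSampleZ(o, s)$z,
                 numeric(1))
    expect_true(all(diff(zs) > 0))
    for (o in c(50, 64, 80)) {
        r <- oneSampleZ(o, s)
        expect_equal(r$pTwoSided,
                     2 * min(r$pOneSided, 1 - r$pOneSided),
                     tolerance = 1e-12)
    }
    expect_error(oneSampleZ(10, list(n = 5, mean = 1, sd = 0)), "zero")

    # alternative normalisation divides by the SE of the mean
    alt <- oneSampleZ(117, s, normalization = "mean-standard-error")
    expect_equal(alt$z, (117 - 65.45) / (9.63 / sqrt(10000)))
})

test_that("analytic expectation follows the pattern closed form", {
    expect_equal(expectedMotifCount(uniformProfile(), 1005),
                 1000 * 0.25^3)
    expect_equal(expectedMotifCount(
        CompositionProfile(c(A = 1, C = 1, G = 0, T = 1)), 1000), 0)
    # general IUPAC pattern: per-position allowed-set probabilities
    prof <- CompositionProfile(c(A = 0.1, C = 0.2, G = 0.3, T = 0.4))
    expect_equal(expectedMotifCount(prof, 105, pattern = "RGGGYN"),
                 100 * (0.1 + 0.3) * 0.3^3 * (0.2 + 0.4) * 1)
    expect_error(expectedMotifCount(uniformProfile(), 3), "at least")
})

test_that("self-overlap enumeration identifies the G-core clump structure", {
    ov <- motifEnrich:::patternSelfOverlap(gProfile(0.3), "NGGGNN")
    expect_identical(ov$principal, 1:2)
    expect_equal(ov$gamma[1], 0.3)        # one extra G
    expect_equal(ov$gamma[2], 0.09)       # two extra Gs
    expect_equal(ov$gamma[3:5], rep(ov$q, 3))  # disjoint cores
    # union by inclusion-exclusion collapses to p_G
    expect_equal(ov$rho, 0.3)
    # pattern with no self-overlap
    ov2 <- motifEnrich:::patternSelfOverlap(uniformProfile(), "GA")
    expect_length(ov2$principal, 0L)
    expect_equal(ov2$rho, 0)
})

test_that("compound Poisson reduces to plain Poisson without self-overlap", {
    bg <- uniformProfile()
    lam <- expectedMotifCount(bg, 1000, pattern = "GA")
    for (obs in c(0, 40, 62, 80)) {
        cp <- compoundPoissonPValue(obs, bg, 1000, pattern = "GA")
        expect_equal(cp$rho, 0)
        expect_equal(cp$pValue,
                     ppois(obs - 1, cp$lambdaClump, lower.tail = FALSE),
                     tolerance = 1e-9)
    }
    cp <- compoundPoissonPValue(round(lam), bg, 1000, pattern = "GA")
    expect_equal(cp$fold, round(lam) / lam)
    expect_error(compoundPoissonPValue(-1, bg, 1000), "non-negative")
})

test_that("compound-Poisson distribution reproduces exact mean and variance", {
    bg <- gProfile(0.25)
    cp <- compoundPoissonPValue(10, bg, 2000)
    # PMF from the same recursion the tail uses
    rho <- cp$rho
    lc <- cp$lambdaClump
    xmax <- 400
    g <- numeric(xmax)
    g0 <- exp(-lc)
    f <- (1 - rho) * rho^(seq_len(xmax) - 1)
    for (x in seq_len(xmax)) {
        y <- seq_len(x)
        g[x] <- (lc / x) * sum(y * f[y] * c(g0, g)[x - y + 1])
    }
    expect_equal(g0 + sum(g), 1, tolerance = 1e-9)
    mu <- sum(seq_len(xmax) * g)
    v <- sum((seq_len(xmax) - mu)^2 * g) + g0 * mu^2
    expect_equal(mu, cp$lambda, tolerance = 1e-6)
    expect_equal(v, cp$variance, tolerance = 1e-4)
})

test_that("Monte-Carlo count p-value is seeded and add-one corrected", {
    bg <- gProfile(0.25)
    a <- mcCountPValue(0, bg, 800, nSims = 1000, seed = 5)
    expect_equal(a$pValue, 1)
    b <- mcCountPValue(30, bg, 800, nSims = 1000, seed = 5)
    b2 <- mcCountPValue(30, bg, 800, nSims = 1000, seed = 5)
    expect_identical(b$pValue, b2$pValue)
    expect_gt(b$pValue, 0)   # +1 correction: never exactly zero
    huge <- mcCountPValue(10000, bg, 800, nSims = 1000, seed = 5)
    expect_equal(huge$pValue, 1 / 1001)
    expect_error(mcCountPValue(5, bg, 800, nSims = 10, seed = 1), "1000")
})

test_that("KDE of null counts integrates to one and sits on the sample", {
    set.seed(702)
    x <- rnorm(4000, mean = 65, sd = 10)
    k <- kdeCounts(x)
    expect_true(all(k$density >= 0))
    expect_equal(trapz(k$grid, k$density), 1, tolerance = 1e-2)
    expect_lt(abs(k$grid[which.max(k$density)] - mean(x)), 1.5)

    # exactly symmetric sample on a symmetric grid: symmetric density
    sym <- c(x, 130 - x)
    ks <- kdeCounts(sym)
    expect_lt(max(abs(ks$density - rev(ks$density))), 1e-9)

    given <- kdeCounts(x, bandwidth = 1.257)
    expect_equal(given$bandwidth, 1.257)
    expect_error(kdeCounts(rep(3, 10)), "bandwidth")
    expect_error(kdeCounts(3), "at least 2")
})
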