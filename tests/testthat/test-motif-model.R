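test_that("PWM files are normalised with the pseudocount on ingest", {
    f <- tempfile(fileext = ".tsv")
    writeLines(c("A\t0\t1", "C\t0\t1", "G\t10\t1", "T\t0\t1"), f)
    pwm <- readPWM(f)
    # column of counts (0,0,10,0): G freq = (1 + 1e-4) / (1 + 4e-4)
    expect_equal(unname(pwmFreqs(pwm)["G", 1]),
                 (1 + 1e-4) / (1 + 4e-4), tolerance = 1e-12)
    # uniform column is a fixed point of the pseudocount map
    expect_equal(unname(pwmFreqs(pwm)[, 2]), rep(0.25, 4),
                 tolerance = 1e-12)
    expect_equal(unname(colSums(pwmFreqs(pwm))), c(1, 1),
                 tolerance = 1e-9)
})

test_that("malformed PWM files are rejected", {
    f5 <- tempfile(fileext = ".tsv")
    writeLines(c("A\t1", "C\t1", "G\t1", "T\t1", "X\t1"), f5)
    expect_error(readPWM(f5), "4 rows")
    fbad <- tempfile(fileext = ".tsv")
    writeLines(c("A\t1", "C\tfoo", "G\t1", "T\t1"), fbad)
    expect_error(readPWM(fbad), "non-numeric")
    expect_error(PositionWeightMatrix(matrix(0, 4, 2)), "positive total")
})

test_that("logL is zero when the PWM equals the background everywhere", {
    pwm <- PositionWeightMatrix(matrix(c(0.1, 0.2, 0.3, 0.4), 4, 6),
                                pseudocount = 1e-4)
    bg <- CompositionProfile(setNames(pwmFreqs(pwm)[, 1],
                                      c("A", "C", "G", "T")))
    for (site in c("AAAAAA", "ACGTAC", "GGGGGG", "TTTTTT"))
        expect_equal(scoreSite(site, pwm, bg)$logL, 0, tolerance = 1e-12)
})

test_that("logL matches the closed-form product for a G-dominant PWM", {
    eps <- 1e-3
    pwm <- PositionWeightMatrix(
        matrix(c(eps, eps, 1 - 3 * eps, eps), 4, 6), pseudocount = 1e-12)
    bg <- uniformProfile()
    got <- scoreSite("GGGGGG", pwm, bg)$logL
    expect_equal(got, 6 * log((1 - 3 * eps) / 0.25), tolerance = 1e-6)
})

test_that("logL is additive over per-position ratios and permutation-invariant", {
    set.seed(501)
    for (i in 1:10) {
        fr <- matrix(runif(4 * 6, 0.05, 1), 4)
        pwm <- PositionWeightMatrix(fr)
        bg <- randProfile()
        site <- randSeq(6)
        got <- scoreSite(site, pwm, bg)$logL
        # per-position oracle from the stored frequencies
        letters <- strsplit(site, "")[[1]]
        expected <- sum(vapply(1:6, function(j)
            log(pwmFreqs(pwm)[letters[j], j] /
                compositionFreqs(bg)[letters[j]]), numeric(1)))
        expect_equal(got, expected, tolerance = 1e-12)
        # permute columns together with site characters
        perm <- sample(6)
        pwmP <- PositionWeightMatrix(pwmFreqs(pwm)[, perm],
                                     pseudocount = 0.0)
        siteP <- paste(letters[perm], collapse = "")
        expect_equal(scoreSite(siteP, pwmP, bg)$logL, got,
                     tolerance = 1e-9)
    }
})

test_that("sites containing N are unscorable", {
    expect_error(scoreSite("AGGGNN", makeToyPWM(0.9), uniformProfile()),
                 "unscorable")
})

test_that("pwm-expectation threshold equals the enumeration over all sites", {
    set.seed(502)
    pwm <- PositionWeightMatrix(matrix(runif(8, 0.05, 1), 4, 2))
    bg <- randProfile()
    thr <- successThreshold(pwm, bg)
    # enumeration oracle over all 4^2 sites
    bases <- c("A", "C", "G", "T")
    tot <- 0
    for (b1 in bases) for (b2 in bases) {
        p <- pwmFreqs(pwm)[b1, 1] * pwmFreqs(pwm)[b2, 2]
        tot <- tot + p * scoreSite(paste0(b1, b2), pwm, bg)$logL
    }
    expect_equal(thr$value, unname(tot), tolerance = 1e-12)
})

test_that("threshold limits: identical distributions give 0, single-base ~ log 4", {
    bg <- uniformProfile()
    expect_equal(successThreshold(makeToyPWM(0.25), bg)$value, 0,
                 tolerance = 1e-12)
    g1 <- PositionWeightMatrix(matrix(c(0, 0, 1, 0), 4, 1))
    expect_equal(successThreshold(g1, bg)$value, log(4), tolerance = 0.01)
    expect_error(successThreshold(makeToyPWM(0.9), bg, method = "bogus"),
                 "unknown")
    expect_equal(successThreshold(makeToyPWM(0.9), bg, method = "explicit",
                                  value = 2.5)$value, 2.5)
})

test_that("threshold is the mean logL of sites sampled from the PWM", {
    pwm <- makeToyPWM(0.85)
    bg <- gProfile(0.2)
    thr <- successThreshold(pwm, bg)$value
    sites <- samplePWMSites(pwm, 1e5, seed = 13)
    logls <- motifEnrich:::siteLogL(sites, pwm, bg)$logL
    se <- stats::sd(logls) / sqrt(length(logls))
    expect_lt(abs(mean(logls) - thr), 3 * se)
})

test_that("threshold is non-negative, zero only at equality (Gibbs)", {
    set.seed(503)
    for (i in 1:20) {
        pwm <- PositionWeightMatrix(matrix(runif(4 * 3, 0.05, 1), 4, 3))
        bg <- randProfile()
        expect_gte(successThreshold(pwm, bg)$value, 0)
    }
})

test_that("PWM site sampling is seeded and column-faithful", {
    pwm <- makeToyPWM(0.9)
    expect_identical(samplePWMSites(pwm, 50, seed = 5),
                     samplePWMSites(pwm, 50, seed = 5))
    sites <- samplePWMSites(pwm, 2e4, seed = 6)
    gAtCore <- mean(substr(sites, 3, 3) == "G")
    pG <- pwmFreqs(pwm)["G", 3]
    expect_lt(abs(gAtCore - pG), 3 * sqrt(pG * (1 - pG) / 2e4))
    # near-degenerate PWM: consensus dominates
    cons <- samplePWMSites(PositionWeightMatrix(
        matrix(c(0, 0, 1, 0), 4, 6), pseudocount = 1e-6), 100, seed = 7)
    expect_true(all(cons == "GGGGGG"))
})

test_that("normality check behaves on normal, bimodal and degenerate input", {
    set.seed(504)
    rej <- vapply(1:200, function(i)
        logLNormality(rnorm(50))$p < 0.05, logical(1))
    se <- sqrt(0.05 * 0.95 / 200)
    expect_lt(abs(mean(rej) - 0.05), 4 * se)

    bimodal <- c(rep(0, 25), rep(10, 25)) + rnorm(50, sd = 1e-3)
    res <- logLNormality(bimodal)
    expect_lt(res$p, 0.01)
    expect_true(res$W > 0 && res$W <= 1)

    expect_error(logLNormality(rep(1, 10)), "degenerate")
    expect_error(logLNormality(c(1, 2)), "at least 3")
})
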