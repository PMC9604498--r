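test_that("consensus scanning reports all overlapping occurrences", {
    one <- scanMotif(c(s = "AGGGAA"))
    expect_length(one, 1L)
    expect_identical(BiocGenerics::start(one), 1L)
    expect_identical(one$site, "AGGGAA")

    expect_length(scanMotif(c(s = "ATATATCCCATA")), 0L)  # no G anywhere

    # the GGGG run yields two overlapping GGG cores (enumerated by hand)
    two <- scanMotif(c(s = "AGGGGAA"))
    expect_identical(BiocGenerics::start(two), c(1L, 2L))
    expect_identical(two$site, c("AGGGGA", "GGGGAA"))

    expect_length(scanMotif(c(s = "AGGG")), 0L)  # shorter than the motif
})

test_that("a literal N residue is never matched by pattern N", {
    hits <- scanMotif(c(s = "AGGGAANGGGAA"))
    expect_length(hits, 1L)
    expect_identical(BiocGenerics::start(hits), 1L)
    expect_identical(motifCounts(c(s = "AGGGAANGGGAA"))[["s"]], 1L)
})

test_that("scanning agrees with the brute-force window oracle", {
    set.seed(601)
    for (i in 1:50) {
        pg <- runif(1, 0.1, 0.5)
        s <- randSeq(sample(30:300, 1),
                     prob = c((1 - pg) / 3, (1 - pg) / 3, pg,
                              (1 - pg) / 3))
        hits <- scanMotif(c(x = s))
        expect_identical(BiocGenerics::start(hits), bruteScanStarts(s))
        expect_identical(unname(motifCounts(c(x = s))[1]),
                         length(bruteScanStarts(s)))
    }
})

test_that("hit sites equal the sequence residues at the hit coordinates", {
    set.seed(602)
    s <- randSeq(500, prob = c(0.2, 0.2, 0.4, 0.2))
    hits <- scanMotif(c(x = s))
    expect_gt(length(hits), 0L)
    expect_identical(hits$site,
                     substring(s, BiocGenerics::start(hits),
                               BiocGenerics::end(hits)))
    expect_true(all(BiocGenerics::end(hits) -
                    BiocGenerics::start(hits) + 1L == 6L))
})

test_that("reversing sequence and pattern mirrors the hit coordinates", {
    set.seed(603)
    s <- randSeq(300, prob = c(0.2, 0.2, 0.4, 0.2))
    L <- nchar(s)
    fwd <- scanMotif(c(x = s), pattern = "NGGGNN")
    rev <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    bwd <- scanMotif(c(x = rev), pattern = "NNGGGN")  # reversed pattern
    expect_identical(sort(L - BiocGenerics::end(fwd) + 1L),
                     sort(BiocGenerics::start(bwd)))
})

test_that("both-strand scanning maps minus-strand hits correctly", {
    # CCC core on the plus strand is an NGGGNN hit on the minus strand
    s <- c(x = "TTCCCTTTTTTT")
    both <- scanMotif(s, strand = "both")
    plus <- scanMotif(s)
    expect_length(plus, 0L)
    expect_length(both, 1L)
    expect_identical(as.character(BiocGenerics::strand(both)), "-")
    # oracle: scan the reverse complement and map coordinates back
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    oracleStarts <- unname(nchar(s)) - (bruteScanStarts(rc) + 5L) + 1L
    expect_identical(BiocGenerics::start(both), oracleStarts)

    set.seed(604)
    r <- randSeq(400, prob = c(0.3, 0.3, 0.2, 0.2))
    both2 <- scanMotif(c(x = r), strand = "both")
    n_plus <- length(bruteScanStarts(r))
    rc2 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(r)))
    expect_length(both2, n_plus + length(bruteScanStarts(rc2)))
})

test_that("scored hits carry finite logL consistent with scoreSite", {
    pwm <- makeToyPWM(0.9)
    bg <- gProfile(0.3)
    hits <- scanMotif(c(x = "AGGGTTAGGGCA"), pwm = pwm, bg = bg)
    expect_length(hits, 2L)
    expect_true(all(is.finite(hits$logL)))
    expect_equal(hits$logL[1], scoreSite("AGGGTT", pwm, bg)$logL)
})

test_that("window profile counts, expectation and tail are correct", {
    bg <- uniformProfile()
    # closed-form expectation: 145 * 0.25^3 for a 150-nt window
    hits <- scanMotif(c(x = randSeq(400)))
    wp <- windowProfile(hits, seqLength = 400, bg = bg, window = 150)
    expect_equal(wp$expected[1], 145 * 0.015625)
    expect_identical(wp$start, seq_len(400 - 150 + 1))

    # zero hits: all counts 0, all upper-tail p = 1
    none <- scanMotif(c(x = paste(rep("AT", 100), collapse = "")))
    wp0 <- windowProfile(none, seqLength = 200, bg = bg, window = 150)
    expect_true(all(wp0$count == 0L))
    expect_true(all(wp0$pUpper == 1))

    expect_error(windowProfile(hits, 400, bg, window = 5), "pattern width")
    expect_error(windowProfile(hits, 400, bg, window = 500), "exceeds")
})

test_that("non-overlapping tiling partitions the covered hits", {
    set.seed(605)
    s <- randSeq(1000, prob = c(0.2, 0.2, 0.4, 0.2))
    hits <- scanMotif(c(x = s))
    wp <- windowProfile(hits, 1000, uniformProfile(), window = 150,
                        step = 150)
    # a hit belongs to a window iff the whole site fits inside it
    covered <- unlist(lapply(wp$start, function(ws) ws:(ws + 150 - 6)))
    expect_identical(sum(wp$count),
                     sum(BiocGenerics::start(hits) %in% covered))
    # total hit count does not depend on windowing parameters
    wp2 <- windowProfile(hits, 1000, uniformProfile(), window = 97,
                         step = 13)
    expect_length(scanMotif(c(x = s)), length(hits))
})

test_that("window counts localise a planted cluster", {
    sc <- syntheticScenario("pk", c(A = 0.253, C = 0.25, G = 0.247,
                                    T = 0.25),
                            length = 3000L, plantedFold = 3,
                            clusterIntervals = IRanges::IRanges(500, 1399),
                            seed = 21)
    seq <- makeScenarioSequence(sc)
    hits <- scanMotif(seq)
    wp <- windowProfile(hits, 3000, baseComposition(seq), window = 150)
    best <- wp[which.max(wp$count), ]
    expect_true(best$start <= 1399 && best$end >= 500)
})

test_that("BED export is well-formed and round-trips coordinates", {
    pwm <- makeToyPWM(0.9)
    bg <- gProfile(0.3)
    hits <- scanMotif(c(s = "TTTTTTTTTTAGGGTTCGGGCA"), pwm = pwm, bg = bg)
    bed <- tempfile(fileext = ".bed")
    writeBED(hits, bed)
    lines <- readLines(bed)
    expect_match(lines[1], "^track name=")
    fields <- strsplit(lines[-1], "\t")
    expect_true(all(lengths(fields) == 6L))
    tab <- read.table(bed, skip = 1, sep = "\t")
    expect_identical(tab$V2 + 1L, BiocGenerics::start(hits))  # 0-based
    expect_identical(tab$V3, BiocGenerics::end(hits))
    expect_identical(tab$V4, hits$site)
    expect_true(all(tab$V5 >= 0 & tab$V5 <= 1000))

    empty <- tempfile(fileext = ".bed")
    writeBED(hits[0], empty)
    expect_length(readLines(empty), 1L)  # header only
})
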