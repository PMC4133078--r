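# Read simulator: error-rate draws, corruption pass, barcoded/orphaned
# reads, mixtures, and FASTQ round-trips.

test_that("per-read error rates follow the truncated normal", {
    model <- PAPER_MODEL
    expect_identical(drawErrorRates(5, ErrorModel(0.2, 0)), rep(0.2, 5))
    expect_identical(drawErrorRates(3, ErrorModel(0, 0)), rep(0, 3))
    set.seed(1)
    p <- drawErrorRates(10000, model)
    expect_true(all(p >= 0 & p <= 1))
    se <- 0.048 / sqrt(10000)
    expect_lt(abs(mean(p) - 0.122), 3 * se + 1e-3)  # slight truncation shift
    # Kolmogorov-Smirnov against the truncated normal CDF
    ptrunc <- function(q) {
        lo <- stats::pnorm(0, 0.122, 0.048)
        hi <- stats::pnorm(1, 0.122, 0.048)
        pmin(pmax((stats::pnorm(q, 0.122, 0.048) - lo) / (hi - lo), 0), 1)
    }
    ks <- suppressWarnings(stats::ks.test(p, ptrunc))
    expect_gt(ks$p.value, 0.01)
})

test_that("the corruption pass honours p and the operation ratios", {
    tmpl <- strrep("ACGT", 20)
    expect_identical(corruptSequences(tmpl, 0), setNames(tmpl, NULL))
    set.seed(2)
    # forced substitution-only: same length, every position changed
    sub <- corruptSequences(tmpl, 1, c(0, 0, 1))
    expect_identical(nchar(sub), nchar(tmpl))
    expect_true(all(strsplit(sub, "")[[1]] != strsplit(tmpl, "")[[1]]))
    # forced deletion-only removes everything; insertion-only doubles
    expect_identical(corruptSequences(tmpl, 1, c(0, 1, 0)), "")
    expect_identical(nchar(corruptSequences(tmpl, 1, c(1, 0, 0))),
                     2L * nchar(tmpl))
    # mean edit count ~ L * p at small p (50-mer, p = 0.02)
    set.seed(3)
    t50 <- randomSeqs(1, 50)
    cor <- corruptSequences(rep(t50, 10000), 0.02, c(0.55, 0.362, 0.088))
    edits <- slDistance(rep(t50, 10000), cor)
    se <- stats::sd(edits) / sqrt(10000)
    expect_lt(abs(mean(edits) - 1.0), 3 * se + 0.02)
})

test_that("error-type frequencies among introduced edits match the ratios", {
    # classify single edits on a long template via the alignment backtrace
    set.seed(4)
    ref <- fixtureRefs40()
    ratios <- c(ins = 0.55, del = 0.362, sub = 0.088)
    reads <- simulateBarcoded(6000, ref, fixtureInsert(),
                              ErrorModel(0.02, 0, ratios))
    est <- estimateErrorRatios(reads, ref)
    expect_true(all(abs(est - ratios) < 3 * sqrt(0.25 / 1000) + 0.02))
})

test_that("barcoded reads start with their reference at zero error rate", {
    bc <- fixtureBc20()
    set.seed(5)
    rs <- simulateBarcoded(500, bc, fixtureInsert(), ErrorModel(0, 0))
    seqs <- as.character(reads(rs))
    starts <- substr(seqs, 1, 7)
    expect_identical(unname(starts),
                     unname(as.character(bc)[match(truthLabels(rs),
                                                   sampleIds(bc))]))
    # draw frequencies roughly uniform over the set
    set.seed(6)
    big <- simulateBarcoded(20000, bc, fixtureInsert(), ErrorModel(0, 0))
    tab <- table(truthLabels(big))
    expect_gt(stats::chisq.test(tab)$p.value, 0.001)
    expect_identical(length(simulateBarcoded(0, bc, fixtureInsert(),
                                             ErrorModel(0, 0))), 0L)
})

test_that("orphan windows have fixed width and respect the start offset", {
    set.seed(7)
    orph <- simulateOrphaned(200)
    expect_true(all(Biostrings::width(reads(orph)) == 50L))
    expect_true(all(truthLabels(orph) == "ORPHANED"))
    # empirical mode: source reads marked in their first 40 positions
    src <- paste0(strrep("A", 40), randomSeqs(5, 80))
    src <- vapply(src, function(s) chartr("A", "C", substr(s, 41, 120)),
                  character(1), USE.NAMES = FALSE)
    src <- paste0(strrep("A", 40), src)  # A only in positions 1..40
    set.seed(8)
    emp <- simulateOrphaned(500, source = src)
    expect_false(any(grepl("A", as.character(reads(emp)))))
    expect_error(simulateOrphaned(10, source = "ACGTACGT"), "window")
})

test_that("uniform orphans sit near the documented 6% detection rate at delta <= 1", {
    bc <- fixtureBc20()
    set.seed(9)
    orph <- simulateOrphaned(8000)
    prof <- distanceProfile(orph, bc)
    frac <- sum(profileCounts(prof)[c("0", "1")]) / profileTotal(prof)
    expect_lt(abs(frac - 0.06), 0.02)
})

test_that("mixtures honour the rounding rule and are reproducible", {
    bc <- fixtureBc20()
    model <- ErrorModel(0.1, 0.02)
    set.seed(10)
    rs <- simulateMixture(1000, 0.34, bc, fixtureInsert(), model)
    expect_identical(sum(truthLabels(rs) != "ORPHANED"), 340L)
    expect_identical(sum(truthLabels(rs) == "ORPHANED"), 660L)
    set.seed(11)
    all1 <- simulateMixture(50, 1, bc, fixtureInsert(), model)
    expect_true(all(truthLabels(all1) != "ORPHANED"))
    # counts always conserve m under the round-half-to-even rule
    set.seed(12)
    for (i in 1:20) {
        m <- sample(1:500, 1)
        pi1 <- runif(1)
        rs <- simulateMixture(m, pi1, bc, fixtureInsert(), model)
        expect_identical(length(rs), m)
        expect_identical(sum(truthLabels(rs) != "ORPHANED"),
                         as.integer(round(pi1 * m)))
    }
    set.seed(13)
    a <- simulateMixture(200, 0.3, bc, fixtureInsert(), model)
    set.seed(13)
    b <- simulateMixture(200, 0.3, bc, fixtureInsert(), model)
    expect_identical(as.character(reads(a)), as.character(reads(b)))
    expect_identical(truthLabels(a), truthLabels(b))
})

test_that("read sets round-trip through FASTQ with a truth sidecar", {
    bc <- fixtureBc20()
    set.seed(14)
    rs <- simulateMixture(60, 0.5, bc, fixtureInsert(), ErrorModel(0.1, 0))
    fq <- tempfile(fileext = ".fastq")
    writeReadSet(rs, fq)
    back <- readReadSet(fq)
    expect_identical(as.character(reads(back)), as.character(reads(rs)))
    truth <- read.delim(paste0(fq, ".truth.tsv"))
    expect_identical(nrow(truth), 60L)
    expect_identical(sum(truth$label == "barcoded"), 30L)
})
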