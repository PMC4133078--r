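# Distance profiles, CDFs, the two-orientation read universe, and
# background subsequence sampling.

test_that("profiles tally per-read minimal distances over the fixed support", {
    bc <- BarcodeSet(c(S1 = "ACGTACG", S2 = "TTGCAAC"), minDistance = 3)
    reads <- c("ACGTACGAA",   # delta 0 to S1
               "ACCTACGAA",   # one substitution from S1
               "TTGCAACCC")   # delta 0 to S2 -> distances {0, 1, 0}
    prof <- distanceProfile(reads, bc)
    expect_identical(profileTotal(prof), 3L)
    counts <- profileCounts(prof)
    expect_identical(unname(counts[c("0", "1")]), c(2L, 1L))
    expect_identical(names(counts), as.character(0:7))
    # empty read set: empty profile with total 0
    expect_identical(profileTotal(distanceProfile(character(0), bc)), 0L)
    expect_error(distanceProfile(reads, character(0)), "empty")
})

test_that("labeled profiles split additively into orphaned and barcoded parts", {
    bc <- fixtureBc20()
    set.seed(21)
    mix <- simulateMixture(2000, 0.4, bc, fixtureInsert(),
                           ErrorModel(0.12, 0.04))
    prof <- distanceProfile(mix, bc)
    f0 <- profileCounts(prof, "orphaned")
    f1 <- profileCounts(prof, "barcoded")
    expect_identical(unname(f0 + f1), unname(profileCounts(prof)))
    # the split equals profiles of the subsets computed independently
    lab <- truthLabels(mix)
    sub1 <- distanceProfile(as.character(reads(mix))[lab != "ORPHANED"], bc)
    sub0 <- distanceProfile(as.character(reads(mix))[lab == "ORPHANED"], bc)
    expect_identical(unname(f1), unname(profileCounts(sub1)))
    expect_identical(unname(f0), unname(profileCounts(sub0)))
})

test_that("the CDF is the running fraction and ends at one", {
    prof <- new("DistanceProfile",
                counts = setNames(c(1L, 2L, 0L, 0L, 0L, 1L),
                                  as.character(0:5)),
                counts0 = integer(0), counts1 = integer(0))
    cdf <- profileCdf(prof)
    expect_equal(unname(cdf[c("0", "1", "5")]), c(0.25, 0.75, 1))
    expect_true(all(diff(cdf) >= 0))
    set.seed(22)
    rand <- distanceProfile(randomSeqs(300, 50), fixtureBc20())
    rcdf <- profileCdf(rand)
    expect_true(all(diff(rcdf) >= 0))
    expect_equal(unname(rcdf[length(rcdf)]), 1)
})

test_that("the read universe doubles records and keeps provenance", {
    reads <- c(r1 = "ACGGATTT", r2 = "AAATTTCC", pal = "ACGT")
    uni <- readUniverse(reads)
    expect_identical(length(uni), 6L)
    expect_identical(sum(uni@orientation == "fwd"), 3L)
    rc <- as.character(reads(uni))[uni@orientation == "rev"]
    expect_identical(unname(rc), unname(revComp(reads)))
    # palindromic read still contributes two records
    expect_identical(sum(uni@sourceId == "pal"), 2L)
    # orientation metadata round-trips to the source read
    fwd <- as.character(reads(uni))[uni@orientation == "fwd"]
    expect_identical(unname(fwd[match(c("r1", "r2", "pal"),
                                      uni@sourceId[uni@orientation == "fwd"])]),
                     unname(reads))
})

test_that("subsequence sampling is uniform over eligible windows", {
    one <- randomSeqs(1, 50)
    got <- sampleSubsequences(one, 5, width = 50)
    expect_identical(unname(as.character(got)), rep(one, 5))
    set.seed(23)
    bg <- randomSeqs(2, 59)               # 10 eligible offsets per sequence
    win <- sampleSubsequences(bg, 10000, width = 50)
    expect_true(all(Biostrings::width(win) == 50L))
    off <- as.integer(sub(".*:(\\d+)-\\d+$", "\\1", names(win)))
    expect_gt(stats::chisq.test(table(off))$p.value, 0.001)
    expect_error(sampleSubsequences(bg, 5, width = 100), "window")
})

test_that("coincidental similarity grows about linearly with set size", {
    set.seed(24)
    full <- generateBarcodeSet(7, 3, nRestarts = 10)
    stopifnot(length(full) >= 40)
    subs <- randomSeqs(30000, 50)
    frac <- vapply(c(5, 10, 20, 40), function(k) {
        bc <- BarcodeSet(as.character(full)[seq_len(k)], minDistance = 3)
        prof <- distanceProfile(subs, bc)
        sum(profileCounts(prof)[c("0", "1")]) / length(subs)
    }, numeric(1))
    expect_true(all(diff(frac) > 0))
    expect_gt(stats::cor(c(5, 10, 20, 40), frac, method = "spearman"), 0.95)
    # roughly proportional: doubling the set about doubles the rate
    expect_gt(frac[4] / frac[1], 3)
})
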