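# Sequence-Levenshtein distance, minimal distance to a set, and decoding.

test_that("distance follows the prefix rule on the documented cases", {
    expect_identical(slDistance("ACGT", "ACGT"), 0L)
    expect_identical(slDistance("ACGT", "ACGTAACC"), 0L)
    expect_identical(slDistance("AGGT", "ACGTAA"), oracleSL("AGGT", "ACGTAA"))
    expect_identical(slDistance("AGGT", "ACGTAA"), 1L)
    expect_identical(slDistance("AAAA", "CCCCCC"), oracleSL("AAAA", "CCCCCC"))
    expect_identical(slDistance("AAAA", "CCCCCC"), 4L)
    # empty sequences: the empty string is a prefix of everything
    expect_identical(slDistance("", ""), 0L)
    expect_identical(slDistance("", "ACG"), 0L)
})

test_that("distance equals the brute-force oracle on exhaustive and random pairs", {
    alphabet <- c("A", "C", "G", "T")
    short <- ""
    for (l in 1:3) {
        grid <- do.call(expand.grid, c(rep(list(alphabet), l),
                                       stringsAsFactors = FALSE))
        short <- c(short, do.call(paste0, grid))
    }
    got <- outer(seq_along(short), seq_along(short),
                 Vectorize(function(i, j) slDistance(short[i], short[j])))
    want <- outer(seq_along(short), seq_along(short),
                  Vectorize(function(i, j) oracleSL(short[i], short[j])))
    expect_identical(got, want)

    set.seed(61)
    for (i in 1:400) {
        a <- paste(sample(alphabet, sample(0:6, 1), replace = TRUE),
                   collapse = "")
        b <- paste(sample(alphabet, sample(0:6, 1), replace = TRUE),
                   collapse = "")
        expect_identical(slDistance(a, b), oracleSL(a, b))
    }
})

test_that("distance is symmetric, bounded by either length and by Levenshtein", {
    set.seed(7)
    a <- randomSeqs(200, 12)
    b <- randomSeqs(200, 30)
    d1 <- slDistance(a, b)
    expect_identical(d1, slDistance(b, a))
    expect_true(all(d1 <= nchar(a)))
    expect_true(all(d1 <= nchar(b)))
    lev <- mapply(function(x, y) utils::adist(x, y), a, b)
    expect_true(all(d1 <= lev))
})

test_that("prefix-window truncation never changes minimal distances", {
    bc <- fixtureBc20()
    set.seed(17)
    reads <- randomSeqs(2000, 120)
    md <- minBarcodeDistance(reads, bc)                 # default 2x window
    mdFull <- minBarcodeDistance(reads, bc, window = Inf)
    expect_identical(md$delta, mdFull$delta)
    refs <- fixtureRefs40()
    expect_identical(minBarcodeDistance(reads, refs)$delta,
                     minBarcodeDistance(reads, refs, window = Inf)$delta)
})

test_that("minimal distance to a set reports every argmin and rejects empty sets", {
    bc1 <- BarcodeSet(c(S1 = "ACGTACG"), minDistance = 3, check = FALSE)
    md <- minBarcodeDistance("ACGTACGTT", bc1)
    expect_identical(md$delta, 0L)
    expect_identical(md$argmin[[1]], 1L)

    bc2 <- BarcodeSet(c(S1 = "ACGTACG", S2 = "TTGCAAC"), minDistance = 3)
    md2 <- minBarcodeDistance("TTGGAACTT", bc2)
    expect_identical(md2$delta,
                     min(oracleSL("ACGTACG", substr("TTGGAACTT", 1, 14)),
                         oracleSL("TTGCAAC", substr("TTGGAACTT", 1, 14))))
    expect_error(minBarcodeDistance("ACGT", character(0)), "empty")
})

test_that("any single error on any barcode decodes to the right sample at threshold 1", {
    bc <- fixtureBc20()
    seqs <- as.character(bc)
    suffix <- "ACGGATTACAGGATTACAGG"   # arbitrary 20-nt downstream context
    reads <- character(0)
    truth <- character(0)
    for (k in seq_along(seqs)) {
        b <- seqs[k]
        sp <- strsplit(b, "")[[1]]
        variants <- character(0)
        for (pos in 1:7) {  # substitutions
            for (alt in setdiff(c("A", "C", "G", "T"), sp[pos])) {
                v <- sp; v[pos] <- alt
                variants <- c(variants, paste(v, collapse = ""))
            }
        }
        for (pos in 1:7)    # deletions
            variants <- c(variants, paste(sp[-pos], collapse = ""))
        for (pos in 1:8) {  # insertions (before each position and at end)
            for (alt in c("A", "C", "G", "T")) {
                v <- append(sp, alt, after = pos - 1)
                variants <- c(variants, paste(v, collapse = ""))
            }
        }
        reads <- c(reads, paste0(variants, suffix))
        truth <- c(truth, rep(names(bc)[k], length(variants)))
    }
    dec <- decodeReads(reads, bc, threshold = 1)
    expect_true(all(dec$status == "assigned"))
    expect_identical(dec$sample_id, truth)
})

test_that("decoding reports ambiguity and unassigned as first-class statuses", {
    bc <- BarcodeSet(c(S1 = "AACCGGT", S2 = "TTGGCCA"), minDistance = 3,
                     check = FALSE)
    # a read at delta 0 to S1 only
    expect_identical(decodeReads("AACCGGTAAAAAA", bc, 1)$status, "assigned")
    # equidistant to both barcodes at delta <= threshold -> ambiguous
    ties <- BarcodeSet(c(S1 = "AAAA", S2 = "CCCC"), minDistance = 0,
                       check = FALSE)
    md <- minBarcodeDistance("AACC", ties)
    expect_identical(md$n_min, 2L)
    expect_identical(decodeReads("AACC", ties, md$delta)$status, "ambiguous")
    # duplicated barcode under two sample names ties at delta 0
    dup <- BarcodeSet(c(S1 = "AACCGGT", S2 = "AACCGGT"), minDistance = 0,
                      check = FALSE)
    expect_identical(decodeReads("AACCGGTAAAA", dup, 1)$status, "ambiguous")
    # nothing within threshold
    expect_identical(decodeReads("TTTTTTTTTT", bc, 0)$status, "unassigned")
})

test_that("sequence normalization enforces the strict ACGT alphabet", {
    expect_identical(normalizeSequences("acgu"), "ACGT")
    expect_error(normalizeSequences("ACNGT"), "'N' at position 3")
    expect_error(slDistance("ACGT", "AC-T"), "position")
})

test_that("reverse complement is the Watson-Crick involution", {
    expect_identical(revComp("ACGT"), "ACGT")
    expect_identical(revComp("AAAC"), "GTTT")
    set.seed(3)
    x <- randomSeqs(50, 23)
    expect_identical(revComp(revComp(x)), x)
})
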