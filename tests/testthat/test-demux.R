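# Dual-end assignment, conservation, orientation symmetry, trimming and
# per-sample output.

test_that("assignment uses both ends and adjudicates ties per read", {
    bc <- fixtureBc20()
    seqs <- as.character(bc)
    insert <- substr(fixtureInsert(), 1, 60)
    # barcode at the 5' end and the same barcode reverse-complemented at the
    # 3' end: assigned with end = both
    both <- paste0(seqs[1], insert, revComp(seqs[1]))
    # 5' end only
    five <- paste0(seqs[2], insert)
    # 3' end only
    three <- paste0(insert, revComp(seqs[3]))
    # two different barcodes at the two ends, both exact -> ambiguous
    tie <- paste0(seqs[4], insert, revComp(seqs[5]))
    asg <- assignReads(c(a = both, b = five, c = three, d = tie), bc,
                       threshold = 1)
    expect_identical(asg$status, c("assigned", "assigned", "assigned",
                                   "ambiguous"))
    expect_identical(asg$sample_id[1:3], names(bc)[1:3])
    expect_identical(asg$end[1:3], c("both", "5prime", "3prime"))
    expect_identical(asg$delta[1:4], c(0L, 0L, 0L, 0L))
    # nothing within threshold at either end
    far <- assignReads(strrep("A", 60), bc, threshold = 0)
    expect_identical(far$status, "unassigned")
})

test_that("demultiplexing conserves reads and routes them to their samples", {
    bc <- fixtureBc20()
    set.seed(51)
    clean <- simulateBarcoded(60, bc, fixtureInsert(), ErrorModel(0, 0),
                              insertWindow = 80)
    orph <- simulateOrphaned(40)
    reads <- c(setNames(as.character(reads(clean)),
                        paste0("b", seq_len(60))),
               setNames(as.character(reads(orph)), paste0("o", seq_len(40))))
    outDir <- tempfile("demux")
    dm <- demultiplex(reads, bc, threshold = 0, outDir = outDir)
    s <- dm@summary
    expect_identical(s$n_assigned + s$n_ambiguous + s$n_unassigned, 100L)
    expect_identical(nrow(dm@assignments), 100L)
    expect_identical(anyDuplicated(dm@assignments$read_id), 0L)
    # all clean barcoded reads are assigned, and to the right sample
    asg <- dm@assignments
    bcRows <- grepl("^b", asg$read_id)
    expect_true(all(asg$status[bcRows] == "assigned"))
    expect_identical(asg$sample_id[bcRows], truthLabels(clean))
    # the random orphans in this fixture carry no exact barcode
    expect_true(all(asg$status[!bcRows] == "unassigned"))
    # per-sample files exist and hold the assigned read counts
    files <- dm@files
    expect_gt(length(files), 0L)
    nOut <- sum(vapply(files, function(f)
        length(Biostrings::readDNAStringSet(f, format = "fastq")),
        integer(1)))
    expect_identical(nOut, s$n_assigned)
})

test_that("reverse-complementing every read leaves per-sample counts unchanged", {
    bc <- fixtureBc20()
    set.seed(52)
    mix <- simulateMixture(400, 0.5, bc, fixtureInsert(), PAPER_MODEL)
    fwd <- demultiplex(mix, bc, threshold = 1)
    rev <- demultiplex(revComp(as.character(reads(mix))), bc, threshold = 1)
    expect_identical(fwd@summary$reads_per_sample,
                     rev@summary$reads_per_sample)
    expect_identical(fwd@summary$n_assigned, rev@summary$n_assigned)
})

test_that("trimming removes the matched reference prefix cleanly", {
    refs <- fixtureRefs40()
    set.seed(53)
    rs <- simulateBarcoded(80, refs, fixtureInsert(), PAPER_MODEL,
                           insertWindow = 100)
    outDir <- tempfile("trim")
    dm <- demultiplex(reads(rs), refs, threshold = 9, outDir = outDir)
    trimmed <- Biostrings::DNAStringSet()
    for (f in dm@files)
        trimmed <- c(trimmed, Biostrings::readDNAStringSet(f,
                                                           format = "fastq"))
    # no trimmed read still starts with a reference at distance 0
    md <- minBarcodeDistance(as.character(trimmed), refs)
    expect_true(all(md$delta > 0))
    # trimmed reads are shorter than the raw simulated reads
    expect_lt(median(Biostrings::width(trimmed)), 127 - 20)
})

test_that("demultiplexing agrees with the Fdr table's assignment metrics", {
    bc <- fixtureBc20()
    set.seed(54)
    mix <- simulateMixture(3000, 0.34, bc, fixtureInsert(), PAPER_MODEL)
    dt <- 1L
    tab <- fdrTable(mix, bc, useReverseComplement = TRUE)
    dm <- demultiplex(mix, bc, threshold = dt)
    correct <- dm@assignments$status == "assigned" &
        dm@assignments$sample_id == truthLabels(mix)
    correct[is.na(correct)] <- FALSE
    fracCorrect <- sum(correct) / length(mix)
    expect_lt(abs(fracCorrect -
                  tab$assignment_sensitivity[tab$threshold == dt]), 0.02)
})
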