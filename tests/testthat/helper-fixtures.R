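# Shared fixtures and the independent distance oracle.

FWD_PRIMER <- "GGGAGCTGCTCTCTTCTCTT"
REV_PRIMER <- "TATAAACCTTGCCCGCTGTC"
PAPER_MODEL <- ErrorModel(0.122, 0.048, c(0.55, 0.362, 0.088))

# Brute-force prefix-minimising edit distance: the minimum over plain
# Levenshtein distances (base adist) from each sequence to every prefix of
# the other.  Independent of the package's DP implementation.
oracleSL <- function(a, b) {
    pa <- substring(a, 1, 0:nchar(a))
    pb <- substring(b, 1, 0:nchar(b))
    as.integer(min(utils::adist(a, pb), utils::adist(b, pa)))
}

randomSeqs <- function(n, len) {
    vapply(seq_len(n),
           function(i) paste(sample(c("A", "C", "G", "T"), len,
                                    replace = TRUE), collapse = ""),
           character(1))
}

# Deterministic shared fixtures, built once per test run.
.fx <- new.env()

fixtureBc20 <- function() {
    if (is.null(.fx$bc20)) {
        set.seed(20140807)
        full <- generateBarcodeSet(7, 3, nRestarts = 20)
        .fx$bc20 <- BarcodeSet(as.character(full)[1:20], minDistance = 3)
    }
    .fx$bc20
}

fixtureRefs40 <- function() {
    if (is.null(.fx$refs40))
        .fx$refs40 <- barcodedPrimerSet(fixtureBc20(), FWD_PRIMER,
                                        REV_PRIMER)
    .fx$refs40
}

fixtureInsert <- function() {
    if (is.null(.fx$insert)) {
        set.seed(3388)
        .fx$insert <- randomInsert(300)
    }
    .fx$insert
}
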