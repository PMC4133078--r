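# User-facing constructors.

#' Construct a BarcodeSet
#'
#' @param sequences Barcode sequences: a named character vector or a named
#'   [Biostrings::DNAStringSet].  Unnamed inputs are named `BC01`, `BC02`,
#'   ... in order.
#' @param minDistance Declared minimal pairwise Sequence-Levenshtein
#'   distance of the set.
#' @param sample Sample id per member; defaults to the member names.
#' @param check Verify that the actual minimal pairwise distance is at least
#'   `minDistance` (error if not).  Default `TRUE`.
#' @return A [BarcodeSet-class].
#' @examples
#' BarcodeSet(c(S1 = "ACGTACG", S2 = "TTGCAAC"), minDistance = 3)
#' @export
BarcodeSet <- function(sequences, minDistance = 0L, sample = NULL,
                       check = TRUE) {
    if (is(sequences, "DNAStringSet"))
        sequences <- setNames(as.character(sequences), names(sequences))
    seqs <- normalizeSequences(sequences)
    if (is.null(names(seqs)) || !all(nzchar(names(seqs))))
        names(seqs) <- sprintf("BC%02d", seq_along(seqs))
    if (is.null(sample)) sample <- names(seqs)
    obj <- new("BarcodeSet",
               sequences = Biostrings::DNAStringSet(seqs),
               minDistance = as.integer(minDistance),
               sample = as.character(sample))
    if (check && minDistance > 0L && length(obj) > 1L) {
        rep <- verifyBarcodeSet(obj, minDistance)
        if (rep$minDistance < minDistance)
            stop(sprintf(paste0("barcode set violates declared minimal ",
                                "distance %d (observed %d, e.g. %s / %s)"),
                         minDistance, rep$minDistance,
                         rep$offending$id1[1], rep$offending$id2[1]))
    }
    obj
}

#' Construct a ReadSet
#'
#' @param reads Read sequences: character vector or
#'   [Biostrings::DNAStringSet].  Unnamed inputs are named `read00001`, ...
#' @param truth Optional truth labels: the sample id for barcoded reads,
#'   `"ORPHANED"` for orphaned reads, `NA` when unknown.
#' @param errorRate Optional per-read error rates.
#' @param orientation `"fwd"` or `"rev"` per read (default `"fwd"`).
#' @param sourceId Originating read id (defaults to the read names).
#' @return A [ReadSet-class].
#' @export
ReadSet <- function(reads, truth = NA_character_, errorRate = NA_real_,
                    orientation = "fwd", sourceId = NULL) {
    if (!is(reads, "DNAStringSet"))
        reads <- Biostrings::DNAStringSet(normalizeSequences(reads))
    n <- length(reads)
    if (is.null(names(reads)))
        names(reads) <- sprintf("read%05d", seq_len(n))
    if (is.null(sourceId)) sourceId <- names(reads)
    new("ReadSet", reads = reads,
        truth = rep_len(as.character(truth), n),
        errorRate = rep_len(as.numeric(errorRate), n),
        orientation = rep_len(orientation, n),
        sourceId = rep_len(sourceId, n))
}

#' Construct an ErrorModel
#'
#' @param muError Mean per-base error probability (fraction, e.g. 0.122).
#' @param sigmaError Between-read standard deviation of the per-base error
#'   probability (fraction).
#' @param ratios Relative frequencies of insertions, deletions and
#'   substitutions among errors, in that order; normalised to sum to 1.
#' @return An [ErrorModel-class].
#' @examples
#' ErrorModel(0.122, 0.048, c(0.55, 0.362, 0.088))
#' @export
ErrorModel <- function(muError, sigmaError,
                       ratios = c(ins = 1, del = 1, sub = 1) / 3) {
    ratios <- as.numeric(ratios)
    if (length(ratios) != 3L || any(ratios < 0) || sum(ratios) <= 0)
        stop("'ratios' must be three non-negative numbers")
    ratios <- ratios / sum(ratios)
    names(ratios) <- c("ins", "del", "sub")
    new("ErrorModel", muError = as.numeric(muError),
        sigmaError = as.numeric(sigmaError), ratios = ratios)
}

#' Construct MixtureParams
#'
#' @param m Total number of reads to simulate.
#' @param pi1 Fraction of barcoded reads in \[0, 1\].  The barcoded count is
#'   `round(pi1 * m)` (round-half-to-even); the orphaned count is the
#'   remainder, so counts always sum to `m`.
#' @param errorModel An [ErrorModel-class].
#' @param insert Reference insert sequence appended to each barcode.
#' @param barcodes The [BarcodeSet-class] simulated barcoded reads start
#'   with.
#' @return A [MixtureParams-class].
#' @export
MixtureParams <- function(m, pi1, errorModel, insert, barcodes) {
    new("MixtureParams", m = as.integer(m), pi1 = as.numeric(pi1),
        errorModel = errorModel,
        insert = normalizeSequences(as.character(insert)),
        barcodes = barcodes)
}

# Internal: DistanceProfile from a delta vector on support 0..maxDelta.
newDistanceProfile <- function(delta, maxDelta, truth = NULL) {
    counts <- setNames(tabulate(delta + 1L, nbins = maxDelta + 1L),
                       as.character(0:maxDelta))
    counts0 <- integer(0)
    counts1 <- integer(0)
    if (!is.null(truth) && any(!is.na(truth))) {
        orphan <- !is.na(truth) & truth == "ORPHANED"
        counts0 <- tabulate(delta[orphan] + 1L, nbins = maxDelta + 1L)
        counts1 <- tabulate(delta[!orphan] + 1L, nbins = maxDelta + 1L)
    }
    new("DistanceProfile",
        counts = setNames(as.integer(counts), names(counts)),
        counts0 = as.integer(counts0), counts1 = as.integer(counts1))
}
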