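# Sequence-Levenshtein distance, minimal distance to a reference set, and
# nearest-barcode decoding.

#' Normalize DNA sequences
#'
#' Uppercases, converts U to T, and rejects any other non-ACGT symbol
#' (including N: wildcard matching is deliberately not supported because the
#' distance has no defined wildcard semantics).
#'
#' @param x Character vector of sequences (names are kept).
#' @return Character vector over the alphabet ACGT.
#' @examples
#' normalizeSequences("acgu")
#' @export
normalizeSequences <- function(x) {
    nm <- names(x)
    x <- as.character(x)
    out <- setNames(chartr("U", "T", toupper(x)), nm)
    bad <- regexpr("[^ACGT]", out)
    if (any(bad > 0L)) {
        i <- which(bad > 0L)[1L]
        stop(sprintf("invalid base '%s' at position %d of sequence %d",
                     substr(out[i], bad[i], bad[i]), bad[i], i))
    }
    out
}

#' Reverse complement
#'
#' Watson-Crick reverse complement of character sequences (an involution).
#' Thin wrapper over [Biostrings::reverseComplement()] that keeps the
#' character-vector interface used throughout this package.
#'
#' @param x Character vector of ACGT sequences.
#' @return Character vector of reverse complements, names preserved.
#' @examples
#' revComp(c("ACGT", "AAAC"))
#' @export
revComp <- function(x) {
    x <- normalizeSequences(x)
    setNames(as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(x))), names(x))
}

#' Sequence-Levenshtein distance
#'
#' The minimal number of insertions, deletions and substitutions needed to
#' transform one sequence into any prefix of the other, or vice versa:
#' the minimum over the last row and last column of the standard Levenshtein
#' dynamic-programming matrix.  Unlike the plain Levenshtein distance it is
#' suited to barcodes embedded in longer DNA context, because trailing
#' template sequence does not count against a matching barcode:
#' `slDistance("ACGT", "ACGTAACC")` is 0.
#'
#' @param a,b Character vectors of sequences (recycled to equal length).
#' @return Integer vector of pairwise distances.  The distance is symmetric,
#'   never exceeds the plain Levenshtein distance, and is bounded by the
#'   length of either sequence.
#' @examples
#' slDistance("AGGT", "ACGTAA")   # 1
#' slDistance("AAAA", "CCCCCC")   # 4
#' @export
slDistance <- function(a, b) {
    a <- normalizeSequences(a)
    b <- normalizeSequences(b)
    n <- max(length(a), length(b))
    a <- rep_len(a, n)
    b <- rep_len(b, n)
    vapply(seq_len(n), function(i) c_sl_distance(a[i], b[i]), integer(1))
}

#' Sequence-Levenshtein distance matrix
#'
#' Distances between every read (row) and every reference (column).  Reads
#' are truncated to a prefix window of twice the maximal reference length
#' before the dynamic programme; this cannot change any distance because
#' the distance to a reference is bounded by the reference length.
#'
#' @param seqs Character vector or [Biostrings::DNAStringSet] of reads.
#' @param refs Character vector, [Biostrings::DNAStringSet] or
#'   [BarcodeSet-class] of references.
#' @param window Prefix window in nucleotides; default twice the maximal
#'   reference length.  `Inf` disables truncation.
#' @return Integer matrix `length(seqs)` x `length(refs)` with `dimnames`
#'   from the input names.
#' @export
slDistanceMatrix <- function(seqs, refs, window = NULL) {
    seqs <- asSeqChar(seqs)
    refChar <- asSeqChar(refs)
    if (length(refChar) == 0L)
        stop("reference set must not be empty")
    if (is.null(window)) window <- 2L * max(nchar(refChar))
    if (!is.finite(window)) window <- 0L
    m <- c_sl_matrix(unname(seqs), unname(refChar), as.integer(window))
    dimnames(m) <- list(names(seqs), names(refChar))
    m
}

# Internal: coerce reads/references to a plain character vector.
asSeqChar <- function(x) {
    if (is(x, "BarcodeSet")) return(as.character(x))
    if (is(x, "ReadSet")) x <- x@reads
    if (is(x, "DNAStringSet"))
        return(setNames(as.character(x), names(x)))
    normalizeSequences(x)
}

# Internal: sample ids of a reference input.
refSampleIds <- function(refs) {
    if (is(refs, "BarcodeSet")) return(refs@sample)
    refs <- asSeqChar(refs)
    if (!is.null(names(refs))) names(refs) else as.character(seq_along(refs))
}

#' Minimal distance of reads to a reference set
#'
#' For each read, the minimum Sequence-Levenshtein distance \eqn{\delta}
#' over all references, with all references attaining the minimum.
#'
#' @inheritParams slDistanceMatrix
#' @return A data.frame with one row per read: `delta`, `n_min` (number of
#'   references attaining it), `barcode_id` (first of them), `sample_id`
#'   (its sample), and a list column `argmin` with the integer indices of
#'   all of them.
#' @examples
#' bc <- BarcodeSet(c(S1 = "ACGTACG"), minDistance = 3, check = FALSE)
#' minBarcodeDistance("ACGTACGTT", bc)$delta  # 0
#' @export
minBarcodeDistance <- function(seqs, refs, window = NULL) {
    m <- slDistanceMatrix(seqs, refs, window)
    delta <- m[, 1L]
    for (j in seq_len(ncol(m))[-1L]) delta <- pmin(delta, m[, j])
    hits <- m == delta
    nmin <- rowSums(hits)
    first <- max.col(-m, ties.method = "first")
    ids <- names(asSeqChar(refs))
    if (is.null(ids)) ids <- as.character(seq_len(ncol(m)))
    out <- data.frame(delta = unname(delta), n_min = as.integer(nmin),
                      barcode_id = unname(ids[first]),
                      sample_id = unname(refSampleIds(refs)[first]),
                      row.names = NULL)
    out$argmin <- lapply(seq_len(nrow(m)),
                         function(i) unname(which(hits[i, ])))
    out
}

#' Decode reads against a barcode set
#'
#' Classical forward-orientation decoding: a read is assigned to the unique
#' reference attaining the minimal distance \eqn{\delta} when
#' \eqn{\delta \le} `threshold`; when several *samples* attain it the read
#' is `ambiguous` (ties are a first-class status, not an error), and when
#' \eqn{\delta >} `threshold` it is `unassigned`.  Two references of the
#' same sample (e.g. a forward- and a reverse-barcoded primer) do not make
#' a tie.  For dual-end decoding of both the read and its reverse
#' complement see [assignReads()].
#'
#' @inheritParams slDistanceMatrix
#' @param threshold Maximal acceptable distance \eqn{\delta_t} (>= 0).
#' @return A data.frame with one row per read: `delta`, `status`
#'   (`assigned` / `ambiguous` / `unassigned`) and `sample_id` (`NA` unless
#'   assigned).
#' @export
decodeReads <- function(seqs, refs, threshold, window = NULL) {
    stopifnot(threshold >= 0)
    md <- minBarcodeDistance(seqs, refs, window)
    samples <- refSampleIds(refs)
    nsamp <- vapply(md$argmin, function(ix) length(unique(samples[ix])),
                    integer(1))
    status <- ifelse(md$delta > threshold, "unassigned",
                     ifelse(nsamp > 1L, "ambiguous", "assigned"))
    data.frame(delta = md$delta, status = status,
               sample_id = ifelse(status == "assigned", md$sample_id,
                                  NA_character_),
               row.names = NULL)
}
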