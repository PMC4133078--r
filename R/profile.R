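# Frequency functions f(delta) of minimal Sequence-Levenshtein distances,
# their CDFs, the two-orientation read universe, and background subsequence
# sampling.

#' Distance profile of reads against a reference set
#'
#' The frequency function \eqn{f(\delta)}: for each read the minimal
#' Sequence-Levenshtein distance \eqn{\delta} to the reference set, tallied
#' over the fixed support `0..L` (`L` = reference length; distances cannot
#' exceed it, and empty bins are stored explicitly so that histograms of
#' equal `m` are directly comparable in the RMS fit).  When `x` is a
#' truth-labeled [ReadSet-class], the orphaned split \eqn{\hat f_0} and
#' barcoded split \eqn{\hat f_1} are retained; they sum to \eqn{f} bin-wise.
#'
#' @param x Reads: [ReadSet-class], [Biostrings::DNAStringSet] or character.
#' @param refs References: [BarcodeSet-class] or sequence vector.
#' @param window Prefix window (see [slDistanceMatrix()]).
#' @return A [DistanceProfile-class].
#' @examples
#' bc <- BarcodeSet(c(S1 = "ACGTACG", S2 = "TTGCAAC"), minDistance = 3)
#' profileCounts(distanceProfile(c("ACGTACGAA", "ACCTACGAA"), bc))
#' @export
distanceProfile <- function(x, refs, window = NULL) {
    refChar <- asSeqChar(refs)
    if (length(refChar) == 0L) stop("reference set must not be empty")
    maxDelta <- max(nchar(refChar))
    truth <- if (is(x, "ReadSet")) x@truth else NULL
    seqs <- asSeqChar(x)
    if (length(seqs) == 0L)
        return(newDistanceProfile(integer(0), maxDelta, truth))
    if (is.null(window)) window <- 2L * max(nchar(refChar))
    if (!is.finite(window)) window <- 0L
    delta <- c_sl_min_delta(unname(seqs), unname(refChar),
                            as.integer(window))
    newDistanceProfile(delta, maxDelta, truth)
}

#' Cumulative distribution of a distance profile
#'
#' @param profile A [DistanceProfile-class] with at least one read.
#' @param component Which histogram to accumulate (see [profileCounts()]).
#' @return Numeric vector named by delta: non-decreasing cumulative
#'   fractions reaching 1 at the maximal delta.
#' @examples
#' bc <- BarcodeSet(c(S1 = "ACGT"), minDistance = 1, check = FALSE)
#' profileCdf(distanceProfile(c("ACGTAA", "AGGTAA"), bc))[1:3]
#' @export
profileCdf <- function(profile, component = c("all", "orphaned",
                                              "barcoded")) {
    counts <- profileCounts(profile, component)
    tot <- sum(counts)
    if (tot == 0L) stop("empty profile has no CDF")
    cumsum(counts) / tot
}

#' Two-orientation read universe
#'
#' Each read contributes two records: the read itself and its reverse
#' complement.  A complete construct carries the same barcode at the 5' end
#' and (reverse-complemented) at the 3' end, so profiling this universe
#' sees barcodes at either end in forward orientation.  Provenance is kept:
#' `sourceId` holds the original read id and `orientation` marks the
#' strand; a palindromic read still contributes two (identical) records.
#'
#' @param x A [ReadSet-class], [Biostrings::DNAStringSet] or character.
#' @return A [ReadSet-class] of `2n` records.
#' @export
readUniverse <- function(x) {
    truth <- if (is(x, "ReadSet")) x@truth else NA_character_
    rate <- if (is(x, "ReadSet")) x@errorRate else NA_real_
    seqs <- asSeqChar(x)
    if (is.null(names(seqs)))
        names(seqs) <- sprintf("read%05d", seq_along(seqs))
    rc <- revComp(seqs)
    out <- c(setNames(seqs, paste0(names(seqs), "|fwd")),
             setNames(rc, paste0(names(seqs), "|rev")))
    ReadSet(out,
            truth = rep(rep_len(truth, length(seqs)), 2L),
            errorRate = rep(rep_len(rate, length(seqs)), 2L),
            orientation = rep(c("fwd", "rev"), each = length(seqs)),
            sourceId = rep(names(seqs), 2L))
}

#' Sample fixed-length subsequences from a background
#'
#' Uniform sampling over all eligible (sequence, offset) pairs: windows of
#' `width` nt whose start is strictly after `afterPosition` (1-based).
#' Windows containing non-ACGT symbols are excluded (sequences are
#' normalised up front, which rejects them).  Used both for background
#' similarity surveys and for empirical-mode orphan simulation.
#'
#' @param background Sequences: [ReadSet-class],
#'   [Biostrings::DNAStringSet] or character.
#' @param n Number of windows to draw (with replacement).
#' @param width Window length in nt.
#' @param afterPosition Windows start at positions `> afterPosition`
#'   (default 0: anywhere).
#' @return A [Biostrings::DNAStringSet] of `n` windows.
#' @export
sampleSubsequences <- function(background, n, width = 50L,
                               afterPosition = 0L) {
    seqs <- asSeqChar(background)
    nOff <- nchar(seqs) - afterPosition - width + 1L
    nOff[nOff < 0L] <- 0L
    total <- sum(nOff)
    if (total == 0L)
        stop(sprintf(paste0("no background sequence admits a %d-nt window ",
                            "after position %d"), width, afterPosition))
    pos <- sample.int(total, n, replace = TRUE)
    cum <- cumsum(nOff)
    sidx <- findInterval(pos - 1L, cum) + 1L
    off <- pos - c(0L, cum)[sidx]           # 1-based offset within sequence
    start <- afterPosition + off
    out <- substr(seqs[sidx], start, start + width - 1L)
    names(out) <- sprintf("%s:%d-%d",
                          if (is.null(names(seqs))) sidx else names(seqs)[sidx],
                          start, start + width - 1L)
    Biostrings::DNAStringSet(out)
}
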