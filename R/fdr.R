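# Tail area-based Fdr, precision and sensitivity over distance thresholds,
# threshold selection, and the primer-length sensitivity sweep.

#' Tail-area Fdr / precision / sensitivity table
#'
#' For every candidate threshold \eqn{\delta_t} on the support `0..L`,
#' classifies the truth-labeled simulated reads with \eqn{\delta \le
#' \delta_t} as barcoded and reports, per row:
#' \describe{
#'   \item{detection_fdr}{cumulative orphaned count at \eqn{\delta \le
#'     \delta_t} over the cumulative total — the tail-area false discovery
#'     rate of calling reads barcoded.}
#'   \item{detection_precision}{`1 - detection_fdr`, exactly.}
#'   \item{detection_sensitivity}{fraction of truly barcoded reads with
#'     \eqn{\delta \le \delta_t}; non-decreasing in \eqn{\delta_t}.}
#'   \item{assignment_precision}{fraction of the detected reads that decode
#'     to their true sample (unique nearest sample; ties do not decode).}
#'   \item{assignment_sensitivity}{fraction of all reads (or of barcoded
#'     reads, see `assignmentDenominator`) correctly assigned.}
#' }
#' Rows where no read is detected (0/0) report `NA` precision/Fdr.  At the
#' maximal threshold every read is accepted, so `detection_precision`
#' equals the barcoded fraction of the simulation.
#'
#' @param sim A truth-labeled [ReadSet-class] (see [simulateMixture()]).
#' @param refs Reference set: [BarcodeSet-class] or sequence vector.
#' @param useReverseComplement Also score each read's reverse complement
#'   and use the better end, mirroring dual-end empirical decoding
#'   (default `FALSE`: simulated reads are single-orientation).
#' @param assignmentDenominator `"all"` (every simulated read) or
#'   `"barcoded"` (truly barcoded reads only) for
#'   `assignment_sensitivity`.
#' @param window Prefix window (see [slDistanceMatrix()]).
#' @return A data.frame with one row per threshold `0..L`.
#' @export
fdrTable <- function(sim, refs, useReverseComplement = FALSE,
                     assignmentDenominator = c("all", "barcoded"),
                     window = NULL) {
    stopifnot(is(sim, "ReadSet"))
    if (!isLabeled(sim))
        stop("'sim' must carry truth labels (simulate with labels retained)")
    assignmentDenominator <- match.arg(assignmentDenominator)
    refChar <- asSeqChar(refs)
    samples <- refSampleIds(refs)
    maxDelta <- max(nchar(refChar))
    seqs <- asSeqChar(sim)

    dec <- bestEndDecode(seqs, refChar, samples, window,
                         both = useReverseComplement)
    truth <- sim@truth
    orphan <- truth == "ORPHANED"
    correct <- !orphan & !is.na(dec$sample_id) & dec$sample_id == truth

    tab0 <- tabulate(dec$delta[orphan] + 1L, nbins = maxDelta + 1L)
    tab1 <- tabulate(dec$delta[!orphan] + 1L, nbins = maxDelta + 1L)
    tabc <- tabulate(dec$delta[correct] + 1L, nbins = maxDelta + 1L)
    cum0 <- cumsum(tab0)
    cum1 <- cumsum(tab1)
    cumc <- cumsum(tabc)
    det <- cum0 + cum1
    fdr <- ifelse(det > 0L, cum0 / det, NA_real_)
    denom <- if (assignmentDenominator == "all") length(sim) else sum(!orphan)
    data.frame(threshold = 0:maxDelta,
               n_detected = det,
               detection_fdr = fdr,
               detection_precision = 1 - fdr,
               detection_sensitivity = cum1 / sum(tab1),
               assignment_precision = ifelse(det > 0L, cumc / det, NA_real_),
               assignment_sensitivity = cumc / denom,
               row.names = NULL)
}

# Internal: per-read minimal delta and unique-sample decode, optionally over
# both orientations (global argmin across the two ends).
bestEndDecode <- function(seqs, refChar, samples, window = NULL,
                          both = FALSE) {
    mf <- slDistanceMatrix(seqs, refChar, window)
    mats <- list(fwd = mf)
    if (both)
        mats$rev <- slDistanceMatrix(revComp(seqs), refChar, window)
    usamp <- unique(samples)
    # per-sample minimum over that sample's references and both ends
    sampMin <- matrix(NA_integer_, nrow = length(seqs),
                      ncol = length(usamp), dimnames = list(NULL, usamp))
    endOfMin <- sampMin
    for (s in seq_along(usamp)) {
        cols <- which(samples == usamp[s])
        mF <- do.call(pmin, lapply(cols, function(j) mats$fwd[, j]))
        if (both) {
            mR <- do.call(pmin, lapply(cols, function(j) mats$rev[, j]))
            sampMin[, s] <- pmin(mF, mR)
            endOfMin[, s] <- ifelse(mF <= sampMin[, s],
                                    ifelse(mR <= sampMin[, s], 3L, 1L), 2L)
        } else {
            sampMin[, s] <- mF
            endOfMin[, s] <- 1L
        }
    }
    delta <- sampMin[, 1L]
    if (ncol(sampMin) > 1L)
        for (j in 2:ncol(sampMin)) delta <- pmin(delta, sampMin[, j])
    hits <- sampMin == delta
    nSamp <- rowSums(hits)
    first <- max.col(-sampMin, ties.method = "first")
    end <- endOfMin[cbind(seq_along(first), first)]
    data.frame(delta = unname(delta), n_samples = as.integer(nSamp),
               sample_id = ifelse(nSamp == 1L, usamp[first], NA_character_),
               end = c("5prime", "3prime", "both")[end],
               row.names = NULL)
}

#' Choose a detection threshold at a precision floor
#'
#' The largest threshold whose detection precision exceeds `minPrecision`
#' (equivalently, whose tail-area Fdr is below `1 - minPrecision`).
#'
#' @param table A table from [fdrTable()].
#' @param minPrecision Required precision, e.g. 0.95 for a 5% Fdr.
#' @return Integer threshold, or `NA` when no row qualifies.
#' @export
chooseThreshold <- function(table, minPrecision = 0.95) {
    ok <- !is.na(table$detection_precision) &
        table$detection_precision > minPrecision
    if (!any(ok)) return(NA_integer_)
    as.integer(max(table$threshold[ok]))
}

#' Detection sensitivity versus barcoded-primer length
#'
#' Simulated reads (full barcoded primer + insert, plus orphans) are scored
#' against reference sets of increasing length: the bare barcode plus 0,
#' 1, ... nt of primer.  For each reference length and each precision
#' level, the threshold chosen by [chooseThreshold()] and the detection
#' sensitivity at that threshold are reported.  The output is a staircase:
#' thresholds are discrete, so sensitivity moves in steps.
#'
#' @param bc The plain [BarcodeSet-class].
#' @param forward,reverse Primer sequences.
#' @param model An [ErrorModel-class].
#' @param insert Reference insert for the simulation.
#' @param m,pi1 Simulated mixture size and barcoded fraction.
#' @param precisionLevels Precision floors to evaluate (default 0.90 and
#'   0.95).
#' @param primerLengths Primer prefix lengths in nt (default `0:nchar(forward)`).
#' @return A data.frame: `primer_nt`, `reference_nt`, `precision_level`,
#'   `threshold`, `sensitivity` (`NA` when no threshold attains the level).
#' @export
sensitivityVsPrimerLength <- function(bc, forward, reverse, model, insert,
                                      m = 5000L, pi1 = 0.34,
                                      precisionLevels = c(0.90, 0.95),
                                      primerLengths = NULL) {
    stopifnot(is(bc, "BarcodeSet"))
    forward <- normalizeSequences(forward)
    reverse <- normalizeSequences(reverse)
    if (is.null(primerLengths))
        primerLengths <- 0:min(nchar(forward), nchar(reverse))
    full <- barcodedPrimerSet(bc, forward, reverse)
    sim <- simulateMixture(m, pi1, full, insert, model)
    out <- list()
    for (nt in primerLengths) {
        refs <- if (nt == 0L) bc else barcodedPrimerSet(bc, forward,
                                                        reverse, nt = nt)
        tab <- fdrTable(sim, refs)
        for (lev in precisionLevels) {
            dt <- chooseThreshold(tab, lev)
            sens <- if (is.na(dt)) NA_real_ else
                tab$detection_sensitivity[tab$threshold == dt]
            out[[length(out) + 1L]] <-
                data.frame(primer_nt = as.integer(nt),
                           reference_nt = as.integer(barcodeLength(bc) + nt),
                           precision_level = lev, threshold = dt,
                           sensitivity = sens)
        }
    }
    do.call(rbind, out)
}

#' Write an Fdr table as TSV
#'
#' @param table A table from [fdrTable()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFdrTable <- function(table, path) {
    write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
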