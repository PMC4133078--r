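# Dual-end read-to-sample assignment, barcode trimming, and per-sample
# output.

#' Assign reads to samples from either end
#'
#' Scores the start of each read and the start of its reverse complement
#' (i.e. the read's 3' end) against the reference set and takes the global
#' minimal distance \eqn{\delta} across both ends.  A read is `assigned`
#' when a single sample attains that minimum and \eqn{\delta \le}
#' `threshold`; when two different samples tie at the minimum (e.g. one at
#' each end) it is `ambiguous`; when \eqn{\delta >} `threshold` it is
#' `unassigned`.  Ambiguity is adjudicated per read across both ends
#' jointly.
#'
#' @param x Reads: [ReadSet-class], [Biostrings::DNAStringSet] or
#'   character.
#' @param refs Reference set: [BarcodeSet-class] or sequence vector.
#' @param threshold Acceptance threshold \eqn{\delta_t} (>= 0).
#' @param window Prefix window (see [slDistanceMatrix()]).
#' @return A data.frame with one row per read: `read_id`, `status`
#'   (`assigned` / `ambiguous` / `unassigned`), `sample_id`, `end`
#'   (`5prime` / `3prime` / `both`; `NA` unless assigned) and `delta`.
#' @export
assignReads <- function(x, refs, threshold, window = NULL) {
    stopifnot(threshold >= 0)
    seqs <- asSeqChar(x)
    if (any(nchar(seqs) < 1L)) stop("reads must be at least 1 nt long")
    if (is.null(names(seqs)))
        names(seqs) <- sprintf("read%05d", seq_along(seqs))
    refChar <- asSeqChar(refs)
    samples <- refSampleIds(refs)
    dec <- bestEndDecode(seqs, refChar, samples, window, both = TRUE)
    status <- ifelse(dec$delta > threshold, "unassigned",
                     ifelse(dec$n_samples > 1L, "ambiguous", "assigned"))
    data.frame(read_id = names(seqs), status = status,
               sample_id = ifelse(status == "assigned", dec$sample_id,
                                  NA_character_),
               end = ifelse(status == "assigned", dec$end, NA_character_),
               delta = dec$delta, row.names = NULL)
}

#' Demultiplex reads into per-sample files
#'
#' Assigns every read with [assignReads()], optionally trims the matched
#' barcode (or barcoded primer) from the matched end(s), and writes one
#' FASTQ per sample.  Trimming removes the read prefix whose removal
#' corresponds to the endpoint of the optimal Sequence-Levenshtein
#' alignment, so corrupted barcodes of unequal length are removed cleanly;
#' when both ends match the same sample both are trimmed.
#'
#' @inheritParams assignReads
#' @param outDir Output directory for per-sample FASTQ files; `NULL`
#'   suppresses writing.
#' @param trim Trim matched reference prefixes off assigned reads
#'   (default `TRUE`).
#' @return A [DemuxResult-class]; its summary lists status counts and
#'   fractions, per-sample read tallies and per-status median read
#'   lengths.
#' @export
demultiplex <- function(x, refs, threshold, outDir = NULL, trim = TRUE,
                        window = NULL) {
    seqs <- asSeqChar(x)
    if (is.null(names(seqs)))
        names(seqs) <- sprintf("read%05d", seq_along(seqs))
    refChar <- asSeqChar(refs)
    samples <- refSampleIds(refs)
    asg <- assignReads(seqs, refs, threshold, window)
    if (is.null(window)) window <- 2L * max(nchar(refChar))

    outSeqs <- seqs
    if (trim) {
        sel <- which(asg$status == "assigned")
        for (i in sel) {
            sid <- asg$sample_id[i]
            cols <- which(samples == sid)
            # re-derive which end(s) of this read matched this sample
            s5 <- min(c_sl_matrix(seqs[i], refChar[cols], window))
            rc <- revComp(seqs[i])
            s3 <- min(c_sl_matrix(rc, refChar[cols], window))
            d <- min(s5, s3)
            cur <- seqs[[i]]
            if (s5 == d) {
                j <- cols[which.min(c_sl_matrix(seqs[i], refChar[cols],
                                                window))]
                tr <- c_sl_align(cur, refChar[[j]], window)[2L]
                cur <- substr(cur, tr + 1L, nchar(cur))
            }
            if (s3 == d) {
                j <- cols[which.min(c_sl_matrix(rc, refChar[cols], window))]
                tr <- c_sl_align(rc[[1L]], refChar[[j]], window)[2L]
                cur <- substr(cur, 1L, nchar(cur) - tr)
            }
            outSeqs[i] <- cur
        }
    }

    lens <- nchar(seqs)
    statuses <- c("assigned", "ambiguous", "unassigned")
    counts <- vapply(statuses, function(s) sum(asg$status == s), integer(1))
    medLen <- vapply(statuses, function(s) {
        v <- lens[asg$status == s]
        if (length(v)) median(v) else NA_real_
    }, numeric(1))
    perSample <- table(factor(asg$sample_id[asg$status == "assigned"],
                              levels = unique(samples)))
    summary <- list(n_reads = length(seqs),
                    n_assigned = unname(counts[1L]),
                    n_ambiguous = unname(counts[2L]),
                    n_unassigned = unname(counts[3L]),
                    frac_assigned = unname(counts[1L]) / length(seqs),
                    frac_ambiguous = unname(counts[2L]) / length(seqs),
                    frac_unassigned = unname(counts[3L]) / length(seqs),
                    median_length_by_status = setNames(medLen, statuses),
                    reads_per_sample = as.list(perSample))

    files <- character(0)
    if (!is.null(outDir)) {
        if (anyDuplicated(names(seqs)))
            stop("duplicate read ids in input")
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        for (sid in unique(samples)) {
            sel <- which(asg$status == "assigned" & asg$sample_id == sid)
            if (length(sel) == 0L) next
            keep <- outSeqs[sel]
            keep <- keep[nchar(keep) > 0L]
            if (length(keep) == 0L) next
            fp <- file.path(outDir, paste0(sid, ".fastq"))
            dss <- Biostrings::DNAStringSet(keep)
            Biostrings::writeXStringSet(dss, fp, format = "fastq",
                qualities = Biostrings::BStringSet(
                    strrep("I", Biostrings::width(dss))))
            files <- c(files, fp)
        }
    }
    new("DemuxResult", assignments = asg, summary = summary, files = files)
}
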