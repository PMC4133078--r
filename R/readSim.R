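# PacBio-CLR-like read simulator: the synthetic half of the two-component
# mixture (barcoded + orphaned reads).  All randomness uses R's RNG, so
# everything is reproducible under set.seed().

#' Draw per-read error rates
#'
#' One per-base error probability per read, drawn from
#' `Normal(muError, sigmaError)` truncated to \[0, 1\] by resampling
#' rejected draws.  The rate is fixed within a read.
#'
#' @param n Number of reads.
#' @param model An [ErrorModel-class].
#' @return Numeric vector of `n` probabilities.
#' @export
drawErrorRates <- function(n, model) {
    stopifnot(is(model, "ErrorModel"))
    drawErrorRatesRaw(n, model@muError, model@sigmaError)
}

# Internal scalar-parameter version (no S4 dispatch in hot loops).
drawErrorRatesRaw <- function(n, mu, sigma) {
    if (n == 0L) return(numeric(0))
    if (sigma == 0) return(rep(mu, n))
    p <- rnorm(n, mu, sigma)
    bad <- which(p < 0 | p > 1)
    while (length(bad) > 0L) {
        p[bad] <- rnorm(length(bad), mu, sigma)
        bad <- bad[p[bad] < 0 | p[bad] > 1]
    }
    p
}

#' Corrupt sequences under the error model
#'
#' Single left-to-right pass over the template: each base errs with its
#' read's probability `p`; an error is an insertion, deletion or
#' substitution with the given relative ratios.  A substitution always
#' changes the base (uniform over the other three); an insertion places one
#' uniform random base before the template base and keeps the base; a
#' deletion drops the base.  Error positions are uniform over the template.
#'
#' @param seqs Character vector of template sequences.
#' @param p Per-read error probability, recycled over `seqs`.
#' @param ratios Insertion/deletion/substitution ratios (normalised).
#' @return Character vector of corrupted sequences.
#' @examples
#' set.seed(1)
#' corruptSequences("ACGTACGTAC", 0.3, c(0.55, 0.362, 0.088))
#' @export
corruptSequences <- function(seqs, p, ratios = c(1, 1, 1) / 3) {
    seqs <- normalizeSequences(seqs)
    ratios <- as.numeric(ratios)
    stopifnot(length(ratios) == 3L, all(ratios >= 0), sum(ratios) > 0)
    ratios <- ratios / sum(ratios)
    out <- c_corrupt(unname(seqs), as.numeric(p), ratios)
    names(out) <- names(seqs)
    out
}

#' Simulate barcoded reads
#'
#' Each read is a uniformly drawn reference from `bc` followed by a prefix
#' of the reference insert, corrupted under the error model with its own
#' drawn error rate.  Only `insertWindow` nt of insert are simulated by
#' default, because minimal distances to the reference set never consult
#' later bases; set `insertWindow = NULL` to simulate the full insert.
#'
#' @param n Number of reads.
#' @param bc A [BarcodeSet-class].
#' @param insert Reference insert sequence (>= `insertWindow` nt).
#' @param model An [ErrorModel-class].
#' @param insertWindow Insert prefix length in nt (default 50).
#' @return A [ReadSet-class] with truth labels (originating sample) and
#'   per-read error rates.
#' @export
simulateBarcoded <- function(n, bc, insert, model, insertWindow = 50L) {
    stopifnot(is(bc, "BarcodeSet"), is(model, "ErrorModel"))
    insert <- normalizeSequences(as.character(insert))
    if (!nzchar(insert)) stop("'insert' must be non-empty")
    if (is.null(insertWindow)) insertWindow <- nchar(insert)
    if (nchar(insert) < insertWindow)
        stop("'insert' is shorter than the simulation window")
    if (n == 0L)
        return(ReadSet(Biostrings::DNAStringSet(character(0))))
    idx <- sample.int(length(bc), n, replace = TRUE)
    templates <- paste0(as.character(bc)[idx],
                        substr(insert, 1L, insertWindow))
    rate <- drawErrorRates(n, model)
    got <- c_corrupt(templates, rate, model@ratios)
    names(got) <- sprintf("bcread%05d", seq_len(n))
    ReadSet(got, truth = sampleIds(bc)[idx], errorRate = rate)
}

#' Simulate orphaned reads
#'
#' Orphaned reads are the null population: fixed-length fragments that do
#' not start with a barcode.  In empirical mode (`source` given) they are
#' random `width`-nt windows of the source reads starting after
#' `afterPosition` (1-based, i.e. window start >= `afterPosition + 1`),
#' which assumes those windows have lost any barcode context.  In synthetic
#' mode they are windows of a supplied `background` sequence set, or
#' i.i.d. uniform ACGT when neither source is given.
#'
#' @param n Number of orphan reads.
#' @param source Optional [ReadSet-class], [Biostrings::DNAStringSet] or
#'   character vector of empirical reads.
#' @param background Optional background sequences for synthetic windows.
#' @param width Orphan read length in nt (default 50).
#' @param afterPosition Windows must start after this 1-based position of a
#'   source read (default 40; only used in empirical mode).
#' @return A [ReadSet-class] with truth `"ORPHANED"`.
#' @export
simulateOrphaned <- function(n, source = NULL, background = NULL,
                             width = 50L, afterPosition = 40L) {
    if (n == 0L)
        return(ReadSet(Biostrings::DNAStringSet(character(0))))
    if (!is.null(source)) {
        got <- sampleSubsequences(source, n, width = width,
                                  afterPosition = afterPosition)
    } else if (!is.null(background)) {
        got <- sampleSubsequences(background, n, width = width,
                                  afterPosition = 0L)
    } else {
        got <- c_random_seqs(as.integer(n), as.integer(width))
    }
    got <- as.character(got)
    names(got) <- sprintf("orphan%05d", seq_len(n))
    ReadSet(got, truth = "ORPHANED")
}

#' Simulate a barcoded/orphaned read mixture
#'
#' `round(pi1 * m)` barcoded reads (round-half-to-even) and `m` minus that
#' many orphaned reads, shuffled, with truth labels retained.  This is the
#' simulated counterpart of an empirical read set and the engine behind
#' [profileFitness()].
#'
#' @param m Total number of reads (or a [MixtureParams-class], in which
#'   case the remaining arguments are taken from it).
#' @param pi1 Barcoded fraction in \[0, 1\].
#' @param bc A [BarcodeSet-class].
#' @param insert Reference insert sequence.
#' @param model An [ErrorModel-class].
#' @param orphanSource,background,orphanWidth,afterPosition Passed to
#'   [simulateOrphaned()].
#' @param insertWindow Passed to [simulateBarcoded()].
#' @return A labeled [ReadSet-class] of exactly `m` reads.
#' @examples
#' set.seed(1)
#' bc <- generateBarcodeSet(7, 3, nRestarts = 3)
#' model <- ErrorModel(0.122, 0.048, c(0.55, 0.362, 0.088))
#' rs <- simulateMixture(100, 0.34, bc, randomInsert(60), model)
#' table(truthLabels(rs) == "ORPHANED")
#' @export
simulateMixture <- function(m, pi1 = NULL, bc = NULL, insert = NULL,
                            model = NULL, orphanSource = NULL,
                            background = NULL, orphanWidth = 50L,
                            afterPosition = 40L, insertWindow = 50L) {
    if (is(m, "MixtureParams")) {
        params <- m
        m <- params@m; pi1 <- params@pi1; bc <- params@barcodes
        insert <- params@insert; model <- params@errorModel
    }
    stopifnot(m >= 1L, pi1 >= 0, pi1 <= 1)
    n1 <- round(pi1 * m)
    n0 <- m - n1
    s1 <- simulateBarcoded(n1, bc, insert, model, insertWindow = insertWindow)
    s0 <- simulateOrphaned(n0, source = orphanSource,
                           background = background, width = orphanWidth,
                           afterPosition = afterPosition)
    seqs <- c(as.character(s1@reads), as.character(s0@reads))
    truth <- c(s1@truth, s0@truth)
    rate <- c(s1@errorRate, s0@errorRate)
    ord <- sample.int(length(seqs))
    out <- setNames(seqs[ord], sprintf("read%05d", seq_along(seqs)))
    ReadSet(out, truth = truth[ord], errorRate = rate[ord])
}

#' Synthetic random insert
#'
#' Convenience generator for a uniform-ACGT reference insert, used when no
#' real amplicon sequence is supplied to the simulator.
#'
#' @param length Insert length in nt.
#' @return Character scalar.
#' @export
randomInsert <- function(length = 1000L) {
    c_random_seqs(1L, as.integer(length))
}

#' Write a simulated read set to FASTQ plus a truth sidecar
#'
#' The FASTQ carries a constant placeholder quality; the sidecar TSV has
#' columns `read_id`, `label` (`barcoded` / `orphaned` / `NA`),
#' `sample_id` and `error_rate`.
#'
#' @param rs A [ReadSet-class].
#' @param fastq Output FASTQ path.
#' @param truthTsv Optional sidecar path (default: `fastq` with a
#'   `.truth.tsv` suffix; `NA` suppresses it).
#' @return `fastq`, invisibly.
#' @export
writeReadSet <- function(rs, fastq, truthTsv = NULL) {
    stopifnot(is(rs, "ReadSet"))
    if (is.null(truthTsv)) truthTsv <- paste0(fastq, ".truth.tsv")
    quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(rs@reads)))
    Biostrings::writeXStringSet(rs@reads, fastq, format = "fastq",
                                qualities = quals)
    if (!is.na(truthTsv)) {
        lab <- ifelse(is.na(rs@truth), NA_character_,
                      ifelse(rs@truth == "ORPHANED", "orphaned", "barcoded"))
        write.table(data.frame(read_id = names(rs@reads), label = lab,
                               sample_id = ifelse(lab %in% "barcoded",
                                                  rs@truth, NA_character_),
                               error_rate = rs@errorRate),
                    truthTsv, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(fastq)
}

#' Read sequences from FASTA/FASTQ into a ReadSet
#'
#' @param path FASTA or FASTQ file (format inferred from the extension).
#' @return An unlabeled [ReadSet-class].
#' @export
readReadSet <- function(path) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
        "fastq" else "fasta"
    ss <- Biostrings::readDNAStringSet(path, format = fmt)
    names(ss) <- sub("\\s.*$", "", names(ss))
    ReadSet(ss)
}
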