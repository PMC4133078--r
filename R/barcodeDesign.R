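# Design and audit of [l,d] Sequence-Levenshtein barcode sets.

#' Barcode eligibility filters
#'
#' A candidate barcode is eligible when its GC content lies in \[40%, 60%\],
#' it is not its own reverse complement, and it contains no run of three or
#' more identical bases.  These physico-chemical filters are applied before
#' the distance-based greedy construction.
#'
#' @param x Character vector of candidate sequences.
#' @return Logical vector.
#' @examples
#' isEligibleBarcode(c("AAACGTG", "ATATATT", "AGCTGAC"))
#' @export
isEligibleBarcode <- function(x) {
    x <- normalizeSequences(x)
    gc <- vapply(gregexpr("[GC]", x),
                 function(m) sum(m > 0L), integer(1)) / nchar(x)
    runs <- grepl("(.)\\1\\1", x)
    selfrc <- x == revComp(x)
    gc >= 0.40 & gc <= 0.60 & !runs & !selfrc
}

# Internal: all eligible l-mers in lexicographic order (feasible for l <= 10);
# for longer barcodes a random sample of `budget` candidates is screened
# instead.
eligibleCandidates <- function(length, budget = 200000L) {
    if (length <= 10L) {
        grid <- do.call(expand.grid,
                        c(rep(list(c("A", "C", "G", "T")), length),
                          stringsAsFactors = FALSE))
        cand <- do.call(paste0, grid[rev(seq_len(length))])
        cand <- sort(cand)
    } else {
        cand <- sort(unique(c_random_seqs(as.integer(budget),
                                          as.integer(length))))
    }
    cand[isEligibleBarcode(cand)]
}

# Internal: draw a random pairwise-compatible seed of `size` members.
# In tiny candidate spaces (short barcodes at high dmin) a full-size seed
# may not exist; the seed shrinks gracefully down to a single member.
drawSeed <- function(candidates, size, dmin, tries = 200L) {
    for (sz in rev(seq_len(max(size, 1L)))) {
        for (t in seq_len(tries)) {
            ix <- sort(sample.int(length(candidates), sz))
            if (sz == 1L) return(ix)
            m <- c_sl_matrix(candidates[ix], candidates[ix], 0L)
            if (all(m[upper.tri(m)] >= dmin)) return(ix)
        }
    }
    stop(sprintf(paste0("no eligible seed at pairwise distance >= %d ",
                        "found; the barcode length is probably too ",
                        "small"), dmin))
}

#' Generate an [l,d] barcode set
#'
#' Heuristic construction of a set of `length`-nt barcodes with pairwise
#' Sequence-Levenshtein distance at least `dmin`: eligible candidates (see
#' [isEligibleBarcode()]) are scanned in lexicographic order and greedily
#' added to a random 3-member seed whenever the distance to every member
#' already in the set allows it.  The scan is restarted `nRestarts` times
#' from fresh random seeds or random one-member modifications of the best
#' seed so far, and the largest set found is returned.  Deterministic under
#' `set.seed()`.
#'
#' @param length Barcode length `l` in nucleotides (`l >= dmin`).
#' @param dmin Minimal pairwise distance `d` (`>= 1`); `d >= 3` corrects at
#'   least one insertion, deletion or substitution in DNA context.
#' @param nRestarts Number of greedy restarts (default 100).
#' @param seedSize Seed members per restart (default 3; shrinks
#'   automatically when the candidate space admits no such seed).
#' @param candidateBudget For `length > 10`, number of random candidates to
#'   screen instead of the full lexicographic universe.
#' @return A verified [BarcodeSet-class]; members named `BC01`, `BC02`, ...
#' @examples
#' set.seed(1)
#' bc <- generateBarcodeSet(7, 3, nRestarts = 5)
#' length(bc)
#' @export
generateBarcodeSet <- function(length, dmin, nRestarts = 100L, seedSize = 3L,
                               candidateBudget = 200000L) {
    stopifnot(length >= 1L, dmin >= 1L)
    if (dmin > length)
        stop("'dmin' must not exceed the barcode length")
    candidates <- eligibleCandidates(length, candidateBudget)
    if (length(candidates) == 0L)
        stop("no eligible candidate sequences at this length")
    seedSize <- min(seedSize, length(candidates))
    best <- integer(0)
    bestSeed <- NULL
    for (r in seq_len(nRestarts)) {
        seed <- if (is.null(bestSeed) || runif(1) < 0.5) {
            drawSeed(candidates, seedSize, dmin)
        } else {
            mutateSeed(candidates, bestSeed, dmin)
        }
        got <- c_greedy_extend(candidates, seed, as.integer(dmin))
        if (length(got) > length(best)) {
            best <- got
            bestSeed <- seed
        }
    }
    seqs <- candidates[sort(best)]
    names(seqs) <- sprintf("BC%02d", seq_along(seqs))
    BarcodeSet(seqs, minDistance = dmin, check = TRUE)
}

# Internal: replace one random seed member with a fresh eligible candidate
# at distance >= dmin from the remaining members.
mutateSeed <- function(candidates, seed, dmin, tries = 200L) {
    drop <- sample.int(length(seed), 1L)
    keep <- seed[-drop]
    for (t in seq_len(tries)) {
        cand <- sample.int(length(candidates), 1L)
        if (cand %in% keep) next
        d <- c_sl_matrix(candidates[cand], candidates[keep], 0L)
        if (all(d >= dmin)) return(sort(c(keep, cand)))
    }
    seed
}

#' Audit a barcode set
#'
#' Exact pairwise-distance report: observed minimal pairwise distance, the
#' mean pairwise distance `d_mean`, and every pair violating `dmin`.
#'
#' @param bc A [BarcodeSet-class] (or coercible input).
#' @param dmin Distance floor to audit against; default the set's declared
#'   minimal distance.
#' @return A list with `minDistance`, `dMean`, and a data.frame `offending`
#'   of pairs below `dmin` (`id1`, `id2`, `distance`; zero rows when the
#'   set passes).
#' @export
verifyBarcodeSet <- function(bc, dmin = NULL) {
    seqs <- asSeqChar(bc)
    if (length(seqs) == 0L) stop("barcode set must not be empty")
    if (is.null(dmin))
        dmin <- if (is(bc, "BarcodeSet")) declaredMinDistance(bc) else 0L
    if (length(seqs) == 1L)
        return(list(minDistance = nchar(seqs), dMean = NA_real_,
                    offending = data.frame(id1 = character(0),
                                           id2 = character(0),
                                           distance = integer(0))))
    m <- c_sl_matrix(unname(seqs), unname(seqs), 0L)
    up <- upper.tri(m)
    bad <- which(up & m < dmin, arr.ind = TRUE)
    ids <- names(seqs)
    list(minDistance = min(m[up]),
         dMean = mean(m[up]),
         offending = data.frame(id1 = ids[bad[, 1L]], id2 = ids[bad[, 2L]],
                                distance = m[bad], row.names = NULL))
}

#' Extend barcodes with (a prefix of) a primer
#'
#' Concatenates every barcode with the first `nt` bases of `primer`
#' (barcode first), producing the barcoded-primer references used for
#' detection with insert context.  The pairwise distance floor of the
#' extended set is re-verified.
#'
#' @param bc A [BarcodeSet-class].
#' @param primer Primer sequence (ACGT).
#' @param nt Number of primer bases to append; default all.  `nt = 0`
#'   returns the set unchanged.
#' @return A [BarcodeSet-class] of `barcodeLength(bc) + nt`-nt members.
#' @examples
#' bc <- BarcodeSet(c(S1 = "ACGTACG", S2 = "TTGCAAC"), minDistance = 3)
#' barcodeLength(extendWithPrimer(bc, "GGGAGCTGCT"))  # 17
#' @export
extendWithPrimer <- function(bc, primer, nt = NULL) {
    stopifnot(is(bc, "BarcodeSet"))
    primer <- normalizeSequences(primer)
    if (is.null(nt)) nt <- nchar(primer)
    stopifnot(nt >= 0L, nt <= nchar(primer))
    if (nt == 0L) return(bc)
    seqs <- paste0(as.character(bc), substr(primer, 1L, nt))
    names(seqs) <- names(bc)
    BarcodeSet(seqs, minDistance = declaredMinDistance(bc),
               sample = sampleIds(bc), check = TRUE)
}

#' Forward/reverse barcoded-primer reference set
#'
#' Materialises the `2n`-member reference set of barcoded PCR primers: each
#' barcode concatenated with the forward primer and, separately, with the
#' reverse primer.  Both members of a pair share the same sample id, so
#' decoding treats them as one sample.
#'
#' @param bc A [BarcodeSet-class] of `n` barcodes.
#' @param forward,reverse Forward and reverse primer sequences.
#' @param nt Number of primer bases to append (default: all; both primers
#'   must be at least `nt` long).
#' @return A [BarcodeSet-class] with `2n` members named `<id>.fwd` /
#'   `<id>.rev`.
#' @export
barcodedPrimerSet <- function(bc, forward, reverse, nt = NULL) {
    stopifnot(is(bc, "BarcodeSet"))
    forward <- normalizeSequences(forward)
    reverse <- normalizeSequences(reverse)
    if (is.null(nt)) nt <- min(nchar(forward), nchar(reverse))
    fw <- paste0(as.character(bc), substr(forward, 1L, nt))
    rv <- paste0(as.character(bc), substr(reverse, 1L, nt))
    seqs <- c(fw, rv)
    names(seqs) <- c(paste0(names(bc), ".fwd"), paste0(names(bc), ".rev"))
    BarcodeSet(seqs, minDistance = declaredMinDistance(bc),
               sample = c(sampleIds(bc), sampleIds(bc)), check = FALSE)
}

#' Read a barcode set from FASTA or TSV
#'
#' FASTA files use the record id as sample name; TSV files must have two
#' columns, `sample_id` and `sequence` (header optional).
#'
#' @param path File path (`.fa` / `.fasta` or `.tsv` / `.txt`).
#' @param minDistance Declared minimal pairwise distance (default 0: no
#'   verification).
#' @return A [BarcodeSet-class].
#' @export
readBarcodeSet <- function(path, minDistance = 0L) {
    if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) {
        ss <- Biostrings::readDNAStringSet(path)
        seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
    } else {
        df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
        if (identical(tolower(as.character(df[1L, 1L])), "sample_id"))
            df <- df[-1L, , drop = FALSE]
        seqs <- setNames(as.character(df[[2L]]), as.character(df[[1L]]))
    }
    BarcodeSet(seqs, minDistance = minDistance, check = minDistance > 0L)
}

#' Write a barcode set to FASTA or TSV
#'
#' @param bc A [BarcodeSet-class].
#' @param path Output path.
#' @param format `"fasta"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeBarcodeSet <- function(bc, path, format = c("fasta", "tsv")) {
    format <- match.arg(format)
    if (format == "fasta") {
        Biostrings::writeXStringSet(barcodes(bc), path)
    } else {
        write.table(data.frame(sample_id = names(bc),
                               sequence = as.character(bc)),
                    path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}
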