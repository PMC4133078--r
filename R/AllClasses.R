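# S4 classes for the demultiplexing workflow.

setOldClass("data.frame")

#' BarcodeSet: a set of reference barcodes or barcoded primers
#'
#' An ordered collection of equal-length DNA reference sequences with a
#' declared minimal pairwise Sequence-Levenshtein distance `d`.  Members are
#' named by reference id; the `sample` slot maps each member to its sample,
#' so that a forward- and a reverse-barcoded primer of the same sample count
#' as one sample during decoding.
#'
#' @slot sequences A [Biostrings::DNAStringSet] of equal-width members,
#'   uniquely named.
#' @slot minDistance Integer scalar, the declared minimal pairwise
#'   Sequence-Levenshtein distance of the set.
#' @slot sample Character vector parallel to `sequences`: sample id of each
#'   member.
#'
#' @seealso [BarcodeSet()], [generateBarcodeSet()], [verifyBarcodeSet()],
#'   [extendWithPrimer()]
#' @export
setClass("BarcodeSet",
    representation(sequences = "DNAStringSet",
                   minDistance = "integer",
                   sample = "character"))

setValidity("BarcodeSet", function(object) {
    n <- length(object@sequences)
    if (n == 0L)
        return("barcode set must not be empty")
    w <- Biostrings::width(object@sequences)
    if (length(unique(w)) != 1L)
        return("all barcodes must have equal length")
    nm <- names(object@sequences)
    if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
        return("barcodes must carry unique non-empty names")
    if (length(object@sample) != n)
        return("'sample' must be parallel to 'sequences'")
    if (length(object@minDistance) != 1L || is.na(object@minDistance) ||
        object@minDistance < 0L)
        return("'minDistance' must be a single non-negative integer")
    TRUE
})

#' ErrorModel: per-read sequencing error model
#'
#' A read-level error model in which each read draws its own per-base error
#' probability from a normal distribution truncated to \[0, 1\], and each
#' erroneous base becomes an insertion, deletion or substitution according to
#' fixed ratios.
#'
#' @slot muError Numeric scalar, mean per-base error probability.
#' @slot sigmaError Numeric scalar, between-read standard deviation of the
#'   per-base error probability.
#' @slot ratios Named numeric vector `c(ins=, del=, sub=)` summing to 1.
#'
#' @seealso [ErrorModel()], [drawErrorRates()], [corruptSequences()]
#' @export
setClass("ErrorModel",
    representation(muError = "numeric",
                   sigmaError = "numeric",
                   ratios = "numeric"))

setValidity("ErrorModel", function(object) {
    if (length(object@muError) != 1L || object@muError < 0 ||
        object@muError > 1)
        return("'muError' must be a probability in [0, 1]")
    if (length(object@sigmaError) != 1L || object@sigmaError < 0)
        return("'sigmaError' must be a single non-negative number")
    r <- object@ratios
    if (length(r) != 3L || any(r < 0))
        return("'ratios' must be three non-negative numbers (ins, del, sub)")
    if (abs(sum(r) - 1) > 1e-9)
        return("'ratios' must sum to 1")
    TRUE
})

#' ReadSet: reads with optional truth labels
#'
#' A set of reads together with optional simulation truth: the originating
#' sample (or `"ORPHANED"`), the per-read error rate that was drawn, the
#' orientation of the record and the id of the source read (used by
#' [readUniverse()] to keep provenance when reverse complements are added).
#'
#' @slot reads A named [Biostrings::DNAStringSet].
#' @slot truth Character vector: sample id for simulated barcoded reads,
#'   `"ORPHANED"` for simulated orphans, `NA` for unlabeled reads.
#' @slot errorRate Numeric vector of per-read error rates (`NA` if unknown).
#' @slot orientation Character vector, `"fwd"` or `"rev"` per record.
#' @slot sourceId Character vector: id of the originating read.
#'
#' @seealso [ReadSet()], [simulateMixture()], [readUniverse()]
#' @export
setClass("ReadSet",
    representation(reads = "DNAStringSet",
                   truth = "character",
                   errorRate = "numeric",
                   orientation = "character",
                   sourceId = "character"))

setValidity("ReadSet", function(object) {
    n <- length(object@reads)
    if (length(object@truth) != n || length(object@errorRate) != n ||
        length(object@orientation) != n || length(object@sourceId) != n)
        return("all metadata slots must be parallel to 'reads'")
    if (n > 0 && !all(object@orientation %in% c("fwd", "rev")))
        return("'orientation' must be 'fwd' or 'rev'")
    TRUE
})

#' MixtureParams: parameters of a simulated read mixture
#'
#' The full parameterisation of one simulated read set: total read count
#' `m`, barcoded fraction `pi1`, the [ErrorModel-class], the reference
#' insert appended to each barcode, and the [BarcodeSet-class] the barcoded
#' reads start with.
#'
#' @slot m Integer scalar, total number of reads.
#' @slot pi1 Numeric scalar in \[0, 1\], fraction of barcoded reads.
#' @slot errorModel An [ErrorModel-class].
#' @slot insert Character scalar, reference insert sequence.
#' @slot barcodes A [BarcodeSet-class].
#'
#' @seealso [MixtureParams()], [simulateMixture()], [profileFitness()]
#' @export
setClass("MixtureParams",
    representation(m = "integer",
                   pi1 = "numeric",
                   errorModel = "ErrorModel",
                   insert = "character",
                   barcodes = "BarcodeSet"))

setValidity("MixtureParams", function(object) {
    if (length(object@m) != 1L || is.na(object@m) || object@m < 1L)
        return("'m' must be a single integer >= 1")
    if (length(object@pi1) != 1L || object@pi1 < 0 || object@pi1 > 1)
        return("'pi1' must be a fraction in [0, 1]")
    if (length(object@insert) != 1L || !nzchar(object@insert))
        return("'insert' must be a single non-empty sequence")
    TRUE
})

#' DistanceProfile: histogram of minimal Sequence-Levenshtein distances
#'
#' The frequency function \eqn{f(\delta)} of minimal distances between a
#' read set and a reference set, on the fixed support `0..L` where `L` is
#' the reference length (distances cannot exceed it).  For truth-labeled
#' reads the split into the orphaned component \eqn{\hat f_0} and the
#' barcoded component \eqn{\hat f_1} is retained; the split sums to the
#' total counts bin-wise.
#'
#' @slot counts Integer vector named `"0"`, `"1"`, ... with the histogram.
#' @slot counts0 Integer vector, orphaned split (length 0 when unlabeled).
#' @slot counts1 Integer vector, barcoded split (length 0 when unlabeled).
#'
#' @seealso [distanceProfile()], [profileCdf()], [fdrTable()]
#' @export
setClass("DistanceProfile",
    representation(counts = "integer",
                   counts0 = "integer",
                   counts1 = "integer"))

setValidity("DistanceProfile", function(object) {
    if (is.null(names(object@counts)))
        return("'counts' must be named by delta")
    labeled <- length(object@counts0) > 0L
    if (labeled) {
        if (length(object@counts0) != length(object@counts) ||
            length(object@counts1) != length(object@counts))
            return("labeled splits must match the support of 'counts'")
        if (any(object@counts0 + object@counts1 != object@counts))
            return("labeled splits must sum to 'counts' bin-wise")
    }
    TRUE
})

#' FitResult: result of the evolutionary mixture fit
#'
#' Best parameter set found by [fitMixture()] together with its root mean
#' square (RMS) fitness and the per-generation search trace.
#'
#' @slot pi1,muError,sigmaError Numeric scalars, fitted parameters.
#' @slot ratios Named numeric vector of error-type ratios used in the fit.
#' @slot fitness Numeric scalar, RMS distance between the simulated and the
#'   empirical histogram (in read counts).
#' @slot generations Integer, generations run.
#' @slot converged Logical, whether the convergence rule fired before the
#'   generation budget was exhausted.
#' @slot trace A data.frame with one row per generation
#'   (generation, fitness, pi1, mu, sigma).
#'
#' @seealso [fitMixture()]
#' @export
setClass("FitResult",
    representation(pi1 = "numeric",
                   muError = "numeric",
                   sigmaError = "numeric",
                   ratios = "numeric",
                   fitness = "numeric",
                   generations = "integer",
                   converged = "logical",
                   trace = "data.frame"))

#' DemuxResult: per-read assignments and demultiplexing summary
#'
#' @slot assignments A data.frame with columns `read_id`, `status`
#'   (`assigned` / `ambiguous` / `unassigned`), `sample_id`, `end`
#'   (`5prime` / `3prime` / `both`), `delta`.
#' @slot summary Named list of summary statistics (status counts and
#'   fractions, per-sample tallies, per-status median read lengths).
#' @slot files Character vector of per-sample output files (possibly empty).
#'
#' @seealso [demultiplex()], [assignReads()]
#' @export
setClass("DemuxResult",
    representation(assignments = "data.frame",
                   summary = "list",
                   files = "character"))
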