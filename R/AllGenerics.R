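# Generics and accessors.

#' @describeIn BarcodeSet-class number of reference members
#' @param x,object A `BarcodeSet`.
#' @export
setMethod("length", "BarcodeSet", function(x) length(x@sequences))

#' Accessors for BarcodeSet
#'
#' `barcodes()` returns the members as a [Biostrings::DNAStringSet];
#' `barcodeLength()` the common member length in nucleotides;
#' `declaredMinDistance()` the declared minimal pairwise distance `d`;
#' `sampleIds()` the per-member sample ids.
#'
#' @param x A [BarcodeSet-class].
#' @return See the individual descriptions.
#' @examples
#' bc <- BarcodeSet(c(S1 = "ACGTACG", S2 = "TTGCAAC"), minDistance = 3)
#' barcodeLength(bc)
#' sampleIds(bc)
#' @export
setGeneric("barcodes", function(x) standardGeneric("barcodes"))

#' @rdname barcodes
#' @export
setMethod("barcodes", "BarcodeSet", function(x) x@sequences)

#' @rdname barcodes
#' @export
setGeneric("barcodeLength", function(x) standardGeneric("barcodeLength"))

#' @rdname barcodes
#' @export
setMethod("barcodeLength", "BarcodeSet",
    function(x) unique(Biostrings::width(x@sequences)))

#' @rdname barcodes
#' @export
setGeneric("declaredMinDistance",
    function(x) standardGeneric("declaredMinDistance"))

#' @rdname barcodes
#' @export
setMethod("declaredMinDistance", "BarcodeSet", function(x) x@minDistance)

#' @rdname barcodes
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname barcodes
#' @export
setMethod("sampleIds", "BarcodeSet", function(x) x@sample)

setMethod("names", "BarcodeSet", function(x) names(x@sequences))

setMethod("as.character", "BarcodeSet",
    function(x) setNames(as.character(x@sequences), names(x@sequences)))

setMethod("show", "BarcodeSet", function(object) {
    cat(sprintf("BarcodeSet: %d x [%d,%d] references, %d sample(s)\n",
                length(object), barcodeLength(object),
                declaredMinDistance(object),
                length(unique(object@sample))))
    n <- min(length(object), 5L)
    for (i in seq_len(n))
        cat(sprintf("  %-12s %s (%s)\n", names(object)[i],
                    as.character(object@sequences[[i]]), object@sample[i]))
    if (length(object) > n) cat(sprintf("  ... %d more\n", length(object) - n))
})

#' Accessors for ReadSet
#'
#' `reads()` returns the sequences as a [Biostrings::DNAStringSet];
#' `truthLabels()` the per-read truth (sample id, `"ORPHANED"`, or `NA`);
#' `errorRates()` the per-read drawn error rates; `isLabeled()` whether any
#' truth labels are present.
#'
#' @param x A [ReadSet-class].
#' @return See the individual descriptions.
#' @export
setGeneric("reads", function(x) standardGeneric("reads"))

#' @rdname reads
#' @export
setMethod("reads", "ReadSet", function(x) x@reads)

#' @rdname reads
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))

#' @rdname reads
#' @export
setMethod("truthLabels", "ReadSet", function(x) x@truth)

#' @rdname reads
#' @export
setGeneric("errorRates", function(x) standardGeneric("errorRates"))

#' @rdname reads
#' @export
setMethod("errorRates", "ReadSet", function(x) x@errorRate)

#' @rdname reads
#' @export
setGeneric("isLabeled", function(x) standardGeneric("isLabeled"))

#' @rdname reads
#' @export
setMethod("isLabeled", "ReadSet", function(x) any(!is.na(x@truth)))

#' @describeIn ReadSet-class number of reads
#' @param x,object A `ReadSet`.
#' @export
setMethod("length", "ReadSet", function(x) length(x@reads))

setMethod("show", "ReadSet", function(object) {
    n <- length(object)
    cat(sprintf("ReadSet: %d read(s)", n))
    if (isLabeled(object)) {
        n1 <- sum(object@truth != "ORPHANED", na.rm = TRUE)
        n0 <- sum(object@truth == "ORPHANED", na.rm = TRUE)
        cat(sprintf(" [labeled: %d barcoded, %d orphaned]", n1, n0))
    }
    cat("\n")
    if (n > 0)
        cat(sprintf("  width: %d..%d nt\n",
                    min(Biostrings::width(object@reads)),
                    max(Biostrings::width(object@reads))))
})

setMethod("show", "ErrorModel", function(object) {
    cat(sprintf(paste0("ErrorModel: mu = %.4g, sigma = %.4g, ",
                       "ratios (ins/del/sub) = %.3f/%.3f/%.3f\n"),
                object@muError, object@sigmaError,
                object@ratios[1], object@ratios[2], object@ratios[3]))
})

setMethod("show", "MixtureParams", function(object) {
    cat(sprintf("MixtureParams: m = %d, pi1 = %.3f, insert %d nt, %d refs\n",
                object@m, object@pi1, nchar(object@insert),
                length(object@barcodes)))
    show(object@errorModel)
})

#' Total number of reads in a DistanceProfile
#'
#' @param x A [DistanceProfile-class].
#' @return Integer, the sum of all histogram counts.
#' @export
setGeneric("profileTotal", function(x) standardGeneric("profileTotal"))

#' @rdname profileTotal
#' @export
setMethod("profileTotal", "DistanceProfile", function(x) sum(x@counts))

#' Histogram counts of a DistanceProfile
#'
#' @param x A [DistanceProfile-class].
#' @param component `"all"` for the full histogram, `"orphaned"` or
#'   `"barcoded"` for the labeled splits (error if unlabeled).
#' @return Integer vector named by delta.
#' @export
setGeneric("profileCounts",
    function(x, component = c("all", "orphaned", "barcoded"))
        standardGeneric("profileCounts"))

#' @rdname profileCounts
#' @export
setMethod("profileCounts", "DistanceProfile",
    function(x, component = c("all", "orphaned", "barcoded")) {
        component <- match.arg(component)
        if (component == "all") return(x@counts)
        if (length(x@counts0) == 0L)
            stop("profile carries no truth-labeled split")
        if (component == "orphaned")
            setNames(x@counts0, names(x@counts))
        else
            setNames(x@counts1, names(x@counts))
    })

setMethod("show", "DistanceProfile", function(object) {
    cat(sprintf("DistanceProfile: %d read(s), support 0..%d%s\n",
                profileTotal(object), length(object@counts) - 1L,
                if (length(object@counts0) > 0L) " [labeled]" else ""))
    nz <- object@counts != 0L
    print(object@counts[nz])
})

#' @describeIn DistanceProfile-class coerce to a data.frame with columns
#'   `delta`, `count` and, when labeled, `orphaned` and `barcoded`
#' @param x,object A `DistanceProfile`.
#' @param row.names,optional,... Passed on conventions of the generic;
#'   unused.
#' @export
setMethod("as.data.frame", "DistanceProfile",
    function(x, row.names = NULL, optional = FALSE, ...) {
        df <- data.frame(delta = as.integer(names(x@counts)),
                         count = unname(x@counts))
        if (length(x@counts0) > 0L) {
            df$orphaned <- unname(x@counts0)
            df$barcoded <- unname(x@counts1)
        }
        df
    })

setMethod("show", "FitResult", function(object) {
    cat(sprintf(paste0("FitResult: pi1 = %.3f, mu = %.4f, sigma = %.4f ",
                       "(RMS = %.2f, %d generation(s), %s)\n"),
                object@pi1, object@muError, object@sigmaError,
                object@fitness, object@generations,
                if (object@converged) "converged" else "not converged"))
})

setMethod("show", "DemuxResult", function(object) {
    s <- object@summary
    cat(sprintf(paste0("DemuxResult: %d read(s): %d assigned, ",
                       "%d ambiguous, %d unassigned\n"),
                s$n_reads, s$n_assigned, s$n_ambiguous, s$n_unassigned))
    if (length(object@files) > 0)
        cat(sprintf("  %d per-sample file(s) written\n", length(object@files)))
})
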