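# End-to-end workflow: profile -> error ratios -> evolutionary fit ->
# Fdr table -> threshold -> demultiplexing, with machine-readable artifacts.

#' Run the full detection and demultiplexing pipeline
#'
#' Chains all stages on an empirical read set:
#' \enumerate{
#'   \item build the two-orientation read universe and profile it against
#'     the (primer-extended) reference set;
#'   \item estimate insertion/deletion/substitution ratios from
#'     \eqn{\delta = 1} reads (falling back to 1/3 each with a message);
#'   \item fit (`pi1`, `muError`, `sigmaError`) by evolutionary search;
#'   \item simulate a labeled mixture at the fitted parameters and tabulate
#'     tail-area Fdr / precision / sensitivity per threshold;
#'   \item choose the largest threshold with precision above
#'     `1 - targetFdr`;
#'   \item demultiplex the original reads at that threshold.
#' }
#' All intermediate artifacts (profile, ratios, fit, Fdr table, threshold,
#' assignments, summary and a provenance record with the configuration,
#' seed and package version) are written to `outDir` as TSV/JSON.
#'
#' @param reads Empirical reads: a FASTA/FASTQ path or a
#'   [ReadSet-class] / [Biostrings::DNAStringSet].
#' @param bc Barcodes: a FASTA/TSV path or a [BarcodeSet-class].
#' @param insert Reference insert sequence (or FASTA path) used by the
#'   simulator.
#' @param forwardPrimer,reversePrimer Optional primers; when given, the
#'   detection references are the barcoded primers (recommended).
#' @param targetFdr Acceptable tail-area Fdr (default 0.05, i.e. precision
#'   above 95%).
#' @param ratios Optional fixed error-type ratios; default: estimate.
#' @param outDir Output directory (created).
#' @param control A [fitControl()] list for the evolutionary search.
#' @param seed Optional RNG seed recorded in the provenance and applied at
#'   the start.
#' @param trim Passed to [demultiplex()].
#' @return A list with elements `profile`, `ratios`, `fit`, `fdr_table`,
#'   `threshold`, `demux`, `refs`.
#' @export
runPipeline <- function(reads, bc, insert, forwardPrimer = NULL,
                        reversePrimer = NULL, targetFdr = 0.05,
                        ratios = NULL, outDir = tempfile("barcodefdr_run"),
                        control = fitControl(), seed = NULL, trim = TRUE) {
    if (!is.null(seed)) set.seed(seed)
    if (is.character(reads) && length(reads) == 1L && file.exists(reads))
        reads <- readReadSet(reads)
    if (is.character(bc) && length(bc) == 1L && file.exists(bc))
        bc <- readBarcodeSet(bc)
    stopifnot(is(bc, "BarcodeSet"))
    if (is.character(insert) && length(insert) == 1L && file.exists(insert))
        insert <- as.character(Biostrings::readDNAStringSet(insert)[[1L]])
    insert <- normalizeSequences(as.character(insert))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

    refs <- if (!is.null(forwardPrimer) && !is.null(reversePrimer)) {
        barcodedPrimerSet(bc, forwardPrimer, reversePrimer)
    } else if (!is.null(forwardPrimer)) {
        extendWithPrimer(bc, forwardPrimer)
    } else bc

    stageMsg <- function(fmt, ...) message(sprintf(paste0("[%s] ", fmt),
                                                   format(Sys.time(),
                                                          "%H:%M:%S"), ...))
    stageMsg("profiling %d reads (x2 orientations) against %d references",
             length(asSeqChar(reads)), length(refs))
    universe <- readUniverse(reads)
    prof <- distanceProfile(universe, refs)
    write.table(as.data.frame(prof), file.path(outDir, "profile.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    if (is.null(ratios)) {
        ratios <- tryCatch(estimateErrorRatios(universe, refs),
                           error = function(e) {
            message("ratio estimation failed (", conditionMessage(e),
                    "); using default ratios 1/3, 1/3, 1/3")
            c(ins = 1, del = 1, sub = 1) / 3
        })
    }
    jsonlite::write_json(as.list(ratios), file.path(outDir, "ratios.json"),
                         auto_unbox = TRUE, digits = NA)

    stageMsg("fitting mixture parameters (m = %d)", profileTotal(prof))
    fit <- fitMixture(prof, bc = refs, insert = insert, ratios = ratios,
                      refs = refs, orphanSource = universe,
                      control = control)
    writeFitResult(fit, file.path(outDir, "fit.json"))

    stageMsg("tabulating Fdr at pi1 = %.3f, mu = %.4f, sigma = %.4f",
             fit@pi1, fit@muError, fit@sigmaError)
    model <- ErrorModel(fit@muError, fit@sigmaError, fit@ratios)
    sim <- simulateMixture(profileTotal(prof), fit@pi1, refs, insert, model,
                           orphanSource = universe)
    tab <- fdrTable(sim, refs)
    writeFdrTable(tab, file.path(outDir, "fdr_table.tsv"))

    dt <- chooseThreshold(tab, minPrecision = 1 - targetFdr)
    jsonlite::write_json(list(threshold = dt, target_fdr = targetFdr),
                         file.path(outDir, "threshold.json"),
                         auto_unbox = TRUE, digits = NA)
    if (is.na(dt))
        stop(sprintf("no threshold reaches precision > %.3f; inspect %s",
                     1 - targetFdr, file.path(outDir, "fdr_table.tsv")))

    stageMsg("demultiplexing at threshold %d", dt)
    dm <- demultiplex(reads, refs, dt, outDir = file.path(outDir, "samples"),
                      trim = trim)
    write.table(dm@assignments, file.path(outDir, "assignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(dm@summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)

    jsonlite::write_json(list(
        package = "barcodeFdr",
        version = as.character(packageVersion("barcodeFdr")),
        seed = seed,
        target_fdr = targetFdr,
        n_reads = length(asSeqChar(reads)),
        n_references = length(refs),
        reference_nt = barcodeLength(refs),
        ratios = as.list(fit@ratios),
        fitted = list(pi1 = fit@pi1, mu_error = fit@muError,
                      sigma_error = fit@sigmaError),
        threshold = dt), file.path(outDir, "provenance.json"),
        auto_unbox = TRUE, digits = NA)

    invisible(list(profile = prof, ratios = ratios, fit = fit,
                   fdr_table = tab, threshold = dt, demux = dm,
                   refs = refs, outDir = outDir))
}
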