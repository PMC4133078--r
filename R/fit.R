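# Error-type ratio estimation from near-exact reads, RMS histogram fitness,
# and the evolutionary parameter search.

#' Estimate insertion/deletion/substitution ratios from near-exact reads
#'
#' Reads at minimal distance exactly \eqn{\delta = 1} to the reference set
#' are overwhelmingly genuinely barcoded (for primer-extended references,
#' coincidental \eqn{\delta = 1} hits are essentially absent), so the single
#' edit separating each of them from its nearest reference can be read off
#' the alignment backtrace and tallied into error-type ratios.  A terminal
#' edit that is equally explainable as more than one operation (for
#' example, a deletion of the last reference base versus a substitution of
#' it) is dropped from the tally rather than resolved by fiat: ambiguous
#' edits occur at a rate nearly independent of the true operation type, so
#' dropping them leaves the ratios unbiased, whereas any fixed-precedence
#' resolution inflates its preferred type by several percent.
#'
#' @param x Reads: [ReadSet-class], [Biostrings::DNAStringSet] or character.
#' @param refs The reference set (use the primer-extended references; with
#'   short plain barcodes the terminal-edit ambiguity biases the tally).
#' @param window Prefix window (see [slDistanceMatrix()]).
#' @return Named numeric vector `c(ins=, del=, sub=)` summing to 1.
#' @seealso [ErrorModel()]; when this errors for lack of \eqn{\delta = 1}
#'   reads, fall back to the default ratios 1/3, 1/3, 1/3.
#' @export
estimateErrorRatios <- function(x, refs, window = NULL) {
    seqs <- asSeqChar(x)
    refChar <- asSeqChar(refs)
    if (is.null(window)) window <- 2L * max(nchar(refChar))
    md <- minBarcodeDistance(seqs, refChar, window)
    sel <- which(md$delta == 1L)
    if (length(sel) == 0L)
        stop(paste0("no reads at minimal distance 1 to the reference set; ",
                    "supply ratios manually (default: 1/3, 1/3, 1/3)"))
    ops <- c(ins = 0, del = 0, sub = 0)
    for (i in sel) {
        ref <- refChar[[md$argmin[[i]][1L]]]
        al <- c_sl_align(seqs[[i]], ref, as.integer(window))
        if (al[6L] > 1L) next              # ambiguous terminal edit
        ops <- ops + al[3:5]
    }
    if (sum(ops) == 0)
        stop(paste0("all distance-1 edits were ambiguous; supply ratios ",
                    "manually (default: 1/3, 1/3, 1/3)"))
    ops / sum(ops)
}

#' RMS fitness of mixture parameters against an empirical profile
#'
#' Simulates one read mixture under `params`, profiles it against `refs`,
#' and returns the root mean square Euclidean distance between simulated
#' and empirical histogram counts over the full support `0..L`.  Raw counts
#' (not frequencies) are compared, which is meaningful because the
#' simulated `m` equals the empirical total.
#'
#' @param params A [MixtureParams-class] with `m` equal to
#'   `profileTotal(empirical)`.
#' @param empirical The empirical [DistanceProfile-class].
#' @param refs Reference set to profile against (defaults to the simulation
#'   barcodes).
#' @param orphanSource,background Orphan simulation source (see
#'   [simulateOrphaned()]).
#' @param simSeed Optional RNG seed applied immediately before simulating;
#'   passing the seed that generated `empirical` reproduces it exactly and
#'   yields fitness 0.  Used by [fitMixture()] for common random numbers.
#' @return Non-negative RMS value in read counts.
#' @export
profileFitness <- function(params, empirical, refs = NULL,
                           orphanSource = NULL, background = NULL,
                           simSeed = NULL) {
    stopifnot(is(params, "MixtureParams"), is(empirical, "DistanceProfile"))
    if (params@m != profileTotal(empirical))
        stop(sprintf("params@m (%d) must equal the empirical total (%d)",
                     params@m, profileTotal(empirical)))
    if (is.null(refs)) refs <- params@barcodes
    ctx <- fitnessContext(params@barcodes, params@insert, refs,
                          orphanSource, background)
    if (ctx$maxDelta + 1L != length(empirical@counts))
        stop("empirical profile support does not match the reference set")
    fitnessEval(ctx, params@m, params@pi1, params@errorModel@muError,
                params@errorModel@sigmaError, params@errorModel@ratios,
                simSeed, empirical@counts)
}

# Internal: precomputed context for repeated fitness evaluations.  The
# evaluation consumes R's RNG in the same order as
# simulateMixture() + distanceProfile() (the end-of-mixture shuffle is
# skipped: histograms are order-invariant), so a fitness evaluated with the
# seed that generated the empirical profile is exactly 0.
fitnessContext <- function(bc, insert, refs, orphanSource = NULL,
                           background = NULL, insertWindow = 50L,
                           orphanWidth = 50L, afterPosition = 40L) {
    refChar <- unname(asSeqChar(refs))
    insert <- as.character(insert)
    list(bcChar = unname(asSeqChar(bc)),
         bcSamples = refSampleIds(bc),
         insertPrefix = substr(insert, 1L,
                               min(nchar(insert), insertWindow)),
         refChar = refChar,
         maxDelta = max(nchar(refChar)),
         window = 2L * max(nchar(refChar)),
         orphanChar = if (!is.null(orphanSource))
             unname(asSeqChar(orphanSource)) else NULL,
         bgChar = if (!is.null(background))
             unname(asSeqChar(background)) else NULL,
         orphanWidth = orphanWidth,
         afterPosition = afterPosition,
         empty = integer(0))
}

# Internal: one simulate-and-score evaluation on plain character vectors.
# `orphanDeltaBank`: precomputed orphan distances under the common-random-
# numbers seed; the orphan component does not depend on the parameters, so
# under a fixed simulation seed it can be simulated once per fit and the
# first (m - n1) deltas reused for every candidate.
fitnessEval <- function(ctx, m, pi1, mu, sigma, ratios, simSeed,
                        empCounts, orphanDeltaBank = NULL) {
    if (!is.null(simSeed)) set.seed(simSeed)
    n1 <- round(pi1 * m)
    n0 <- m - n1
    delta1 <- integer(0)
    if (n1 > 0L) {
        idx <- sample.int(length(ctx$bcChar), n1, replace = TRUE)
        rate <- drawErrorRatesRaw(n1, mu, sigma)
        barcoded <- c_corrupt(paste0(ctx$bcChar[idx], ctx$insertPrefix),
                              rate, ratios)
        delta1 <- c_sl_min_delta(barcoded, ctx$refChar,
                                 as.integer(ctx$window))
    }
    delta0 <- integer(0)
    if (n0 > 0L) {
        delta0 <- if (!is.null(orphanDeltaBank)) {
            orphanDeltaBank[seq_len(n0)]
        } else {
            c_sl_min_delta(simOrphanSeqs(ctx, n0), ctx$refChar,
                           as.integer(ctx$window))
        }
    }
    counts <- tabulate(c(delta1, delta0) + 1L, nbins = ctx$maxDelta + 1L)
    sqrt(mean((counts - empCounts)^2))
}

# Internal: orphan sequences per the context's source (same draws as
# simulateOrphaned()).
simOrphanSeqs <- function(ctx, n0) {
    if (!is.null(ctx$orphanChar)) {
        as.character(sampleSubsequences(ctx$orphanChar, n0,
                                        width = ctx$orphanWidth,
                                        afterPosition = ctx$afterPosition))
    } else if (!is.null(ctx$bgChar)) {
        as.character(sampleSubsequences(ctx$bgChar, n0,
                                        width = ctx$orphanWidth,
                                        afterPosition = 0L))
    } else {
        c_random_seqs(as.integer(n0), as.integer(ctx$orphanWidth))
    }
}

#' Control parameters for the evolutionary fit
#'
#' A (mu + lambda) evolution strategy: `popSize` parents, `nOffspring`
#' Gaussian mutants per generation, elitist selection over the union, and
#' a multiplicative per-generation decay of the mutation step.  All
#' candidates across the whole run are evaluated under one simulation seed
#' (common random numbers), so fitness differences reflect parameters
#' rather than Monte-Carlo noise, parent fitnesses stay valid across
#' generations, and the best fitness is monotone non-increasing.
#' Convergence is declared when each best parameter moves less than `tol`
#' over `patience` consecutive generations.
#'
#' @param popSize Parents kept per generation.
#' @param nOffspring Mutants generated per generation.
#' @param maxGenerations Generation budget.
#' @param minGenerations Generations that must elapse before the
#'   convergence rule may fire (guards against settling while the
#'   mutation step is still large).
#' @param stepDecay Multiplicative step-size decay per generation.
#' @param initialStepFrac Initial mutation step as a fraction of each
#'   parameter's box width.
#' @param tol,patience Convergence rule (see above).
#' @param bounds Box constraints, a list with elements `pi1`, `mu`,
#'   `sigma`, each `c(lower, upper)`.
#' @return A list of class `"fitControl"`.
#' @export
fitControl <- function(popSize = 20L, nOffspring = 40L,
                       maxGenerations = 60L, minGenerations = 15L,
                       stepDecay = 0.95, initialStepFrac = 0.1,
                       tol = 0.005, patience = 5L,
                       bounds = list(pi1 = c(0, 1), mu = c(0, 0.5),
                                     sigma = c(0, 0.2))) {
    structure(list(popSize = popSize, nOffspring = nOffspring,
                   maxGenerations = maxGenerations,
                   minGenerations = min(minGenerations, maxGenerations),
                   stepDecay = stepDecay,
                   initialStepFrac = initialStepFrac, tol = tol,
                   patience = patience, bounds = bounds),
              class = "fitControl")
}

#' Fit mixture parameters to an empirical distance profile
#'
#' Evolutionary search for the parameter triple (`pi1`, `muError`,
#' `sigmaError`) whose simulated mixture histogram best matches the
#' empirical one by RMS distance ([profileFitness()]).  The error-type
#' ratios are fixed in advance (user-supplied or from
#' [estimateErrorRatios()]); `m` is taken from the empirical profile.
#' Deterministic given the RNG seed.
#'
#' @param empirical The empirical [DistanceProfile-class].
#' @param bc [BarcodeSet-class] the simulated barcoded reads start with
#'   (for primer-extended detection this is the extended set).
#' @param insert Reference insert sequence for barcoded simulation.
#' @param ratios Error-type ratios `c(ins, del, sub)`.
#' @param refs Reference set profiled against (default `bc`).
#' @param orphanSource,background Orphan source (see [simulateOrphaned()]).
#' @param control A [fitControl()] list.
#' @param verbose Print per-generation progress.
#' @return A [FitResult-class].
#' @examples
#' \donttest{
#' set.seed(7)
#' bc <- generateBarcodeSet(7, 3, nRestarts = 10)
#' model <- ErrorModel(0.122, 0.048, c(0.55, 0.362, 0.088))
#' ins <- randomInsert(60)
#' emp <- distanceProfile(simulateMixture(2000, 0.34, bc, ins, model), bc)
#' fit <- fitMixture(emp, bc, ins, model@ratios,
#'                   control = fitControl(maxGenerations = 15))
#' fit
#' }
#' @export
fitMixture <- function(empirical, bc, insert, ratios = c(1, 1, 1) / 3,
                       refs = NULL, orphanSource = NULL, background = NULL,
                       control = fitControl(), verbose = FALSE) {
    stopifnot(is(empirical, "DistanceProfile"))
    m <- profileTotal(empirical)
    if (m < 1L) stop("empirical profile is empty")
    if (is.null(refs)) refs <- bc
    ratios <- as.numeric(ratios) / sum(ratios)
    lo <- vapply(control$bounds, `[`, numeric(1), 1L)
    hi <- vapply(control$bounds, `[`, numeric(1), 2L)
    step0 <- control$initialStepFrac * (hi - lo)

    ctx <- fitnessContext(bc, insert, refs, orphanSource, background)
    if (ctx$maxDelta + 1L != length(empirical@counts))
        stop("empirical profile support does not match the reference set")
    # evaluations reseed the RNG (common random numbers); save/restore the
    # state so the evolutionary search stream is independent of them
    evalCand <- function(par, simSeed) {
        state <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", state, envir = globalenv()))
        fitnessEval(ctx, m, par[1L], par[2L], par[3L], ratios, simSeed,
                    empirical@counts, orphanDeltaBank = orphanBank)
    }

    simSeed <- sample.int(.Machine$integer.max, 1L)
    # orphan deltas are parameter-free: simulate once under the CRN seed
    orphanBank <- local({
        state <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", state, envir = globalenv()))
        set.seed(simSeed)
        c_sl_min_delta(simOrphanSeqs(ctx, m), ctx$refChar,
                       as.integer(ctx$window))
    })
    # Latin-hypercube initialisation: each parameter range covered evenly
    pop <- vapply(seq_len(3L), function(j) {
        lo[j] + (sample.int(control$popSize) -
                 runif(control$popSize)) / control$popSize * (hi[j] - lo[j])
    }, numeric(control$popSize))
    colnames(pop) <- c("pi1", "mu", "sigma")
    popFit <- vapply(seq_len(nrow(pop)),
                     function(i) evalCand(pop[i, ], simSeed), numeric(1))
    trace <- data.frame(generation = integer(0), fitness = numeric(0),
                        pi1 = numeric(0), mu = numeric(0),
                        sigma = numeric(0))
    bestHist <- NULL
    converged <- FALSE
    gen <- 0L
    step <- step0
    while (gen < control$maxGenerations && !converged) {
        gen <- gen + 1L
        parents <- pop[sample.int(nrow(pop), control$nOffspring,
                                  replace = TRUE), , drop = FALSE]
        noise <- matrix(rnorm(length(parents)), nrow = nrow(parents))
        offspring <- parents + noise * rep(step, each = nrow(parents))
        offspring <- pmin(pmax(offspring, rep(lo, each = nrow(offspring))),
                          rep(hi, each = nrow(offspring)))
        offFit <- vapply(seq_len(nrow(offspring)),
                         function(i) evalCand(offspring[i, ], simSeed),
                         numeric(1))
        all <- rbind(pop, offspring)
        fit <- c(popFit, offFit)
        keep <- order(fit)[seq_len(control$popSize)]
        pop <- all[keep, , drop = FALSE]
        popFit <- fit[keep]
        best <- pop[1L, ]
        trace <- rbind(trace, data.frame(generation = gen,
                                         fitness = popFit[1L],
                                         pi1 = best[1L], mu = best[2L],
                                         sigma = best[3L]))
        if (verbose)
            message(sprintf("gen %2d: RMS %.3f  pi1 %.3f mu %.4f sigma %.4f",
                            gen, popFit[1L], best[1L], best[2L], best[3L]))
        bestHist <- rbind(bestHist, best)
        if (gen >= control$minGenerations &&
            nrow(bestHist) > control$patience) {
            recent <- bestHist[(nrow(bestHist) - control$patience):
                               nrow(bestHist), , drop = FALSE]
            drift <- apply(recent, 2L, function(v) max(v) - min(v))
            if (all(drift < control$tol)) converged <- TRUE
        }
        step <- step * control$stepDecay
    }
    best <- pop[1L, ]
    new("FitResult", pi1 = unname(best[1L]), muError = unname(best[2L]),
        sigmaError = unname(best[3L]),
        ratios = setNames(ratios, c("ins", "del", "sub")),
        fitness = trace$fitness[nrow(trace)], generations = gen,
        converged = converged, trace = trace)
}

#' Serialize a FitResult to JSON
#'
#' @param fit A [FitResult-class].
#' @param path Output JSON path; the per-generation trace goes to a `.tsv`
#'   alongside unless `traceTsv = NA`.
#' @param traceTsv Optional trace path.
#' @return `path`, invisibly.
#' @export
writeFitResult <- function(fit, path, traceTsv = NULL) {
    stopifnot(is(fit, "FitResult"))
    if (is.null(traceTsv)) traceTsv <- sub("\\.json$", ".trace.tsv", path)
    jsonlite::write_json(list(pi1 = fit@pi1, mu_error = fit@muError,
                              sigma_error = fit@sigmaError,
                              ratios = as.list(fit@ratios),
                              fitness_rms = fit@fitness,
                              generations = fit@generations,
                              converged = fit@converged),
                         path, auto_unbox = TRUE, digits = NA)
    if (!is.na(traceTsv))
        write.table(fit@trace, traceTsv, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    invisible(path)
}
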