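# Error-ratio estimation, RMS fitness, and the evolutionary mixture fit.

test_that("single-edit reads recover the operation ratios", {
    refs <- fixtureRefs40()
    # substitution-only corruption: every delta=1 edit is a substitution
    set.seed(31)
    rs <- simulateBarcoded(1500, refs, fixtureInsert(),
                           ErrorModel(0.02, 0, c(0, 0, 1)))
    est <- estimateErrorRatios(rs, refs)
    expect_gt(est[["sub"]], 0.95)
    # indel-only corruption recovers a 50/50 split within +-0.05
    set.seed(32)
    rs2 <- simulateBarcoded(6000, refs, fixtureInsert(),
                            ErrorModel(0.02, 0, c(0.5, 0.5, 0)))
    est2 <- estimateErrorRatios(rs2, refs)
    expect_lt(abs(est2[["ins"]] - 0.5), 0.05)
    expect_lt(abs(est2[["del"]] - 0.5), 0.05)
    expect_lt(est2[["sub"]], 0.05)
    # no delta=1 reads: documented error advising the default ratios
    clean <- simulateBarcoded(50, refs, fixtureInsert(), ErrorModel(0, 0))
    expect_error(estimateErrorRatios(clean, refs), "1/3")
})

test_that("fitness is an RMS of count histograms with an exact CRN identity", {
    bc <- fixtureBc20()
    model <- PAPER_MODEL
    set.seed(33)
    emp <- distanceProfile(simulateMixture(2000, 0.34, bc, fixtureInsert(),
                                           model), bc)
    params <- MixtureParams(2000, 0.34, model, fixtureInsert(), bc)
    # same seed -> same simulated histogram -> fitness exactly zero
    set.seed(33)
    expect_identical(profileFitness(params, emp, simSeed = NULL), 0)
    expect_identical(profileFitness(params, emp, simSeed = 33), 0)
    # different seed -> non-negative sampling noise
    f <- profileFitness(params, emp, simSeed = 34)
    expect_gte(f, 0)
    # far-off parameters score clearly worse under the same seed
    bad <- MixtureParams(2000, 0.9, model, fixtureInsert(), bc)
    expect_gt(profileFitness(bad, emp, simSeed = 34), f)
    # m mismatch is a configuration error
    expect_error(profileFitness(MixtureParams(99, 0.3, model,
                                              fixtureInsert(), bc), emp),
                 "must equal")
})

test_that("the evolutionary fit is deterministic and elitist", {
    bc <- fixtureBc20()
    model <- PAPER_MODEL
    set.seed(35)
    emp <- distanceProfile(simulateMixture(1500, 0.34, bc, fixtureInsert(),
                                           model), bc)
    ctl <- fitControl(maxGenerations = 8, minGenerations = 0)
    set.seed(36)
    f1 <- fitMixture(emp, bc, fixtureInsert(), model@ratios, control = ctl)
    set.seed(36)
    f2 <- fitMixture(emp, bc, fixtureInsert(), model@ratios, control = ctl)
    expect_identical(f1@trace, f2@trace)
    expect_identical(c(f1@pi1, f1@muError, f1@sigmaError),
                     c(f2@pi1, f2@muError, f2@sigmaError))
    # elitism under common random numbers: best fitness never worsens
    expect_true(all(diff(f1@trace$fitness) <= 0))
})

test_that("a pure-orphan profile drives the barcoded fraction to zero", {
    bc <- fixtureBc20()
    set.seed(37)
    orph <- simulateOrphaned(2000)
    emp <- distanceProfile(orph, bc)
    fit <- fitMixture(emp, bc, fixtureInsert(), PAPER_MODEL@ratios,
                      control = fitControl(maxGenerations = 20,
                                           minGenerations = 5))
    expect_lt(fit@pi1, 0.05)
})

test_that("fit results serialize to JSON with a trace sidecar", {
    tr <- data.frame(generation = 1:2, fitness = c(5, 4), pi1 = c(0.3, 0.31),
                     mu = c(0.1, 0.12), sigma = c(0.05, 0.04))
    fit <- new("FitResult", pi1 = 0.31, muError = 0.12, sigmaError = 0.04,
               ratios = c(ins = 0.5, del = 0.3, sub = 0.2), fitness = 4,
               generations = 2L, converged = TRUE, trace = tr)
    path <- tempfile(fileext = ".json")
    writeFitResult(fit, path)
    back <- jsonlite::read_json(path)
    expect_equal(back$pi1, 0.31)
    expect_true(back$converged)
    expect_identical(nrow(read.delim(sub("\\.json$", ".trace.tsv", path))),
                     2L)
})
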