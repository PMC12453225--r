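#' Synthetic VAF tables with known generative parameters
#'
#' Emulates the statistical structure of deep-sequenced normal-tissue
#' TP53 data: per 0.33 mm^2 section, the number of detectable mutations
#' is Poisson with an age-bin-specific mean, and detectable VAFs are
#' \code{lod} plus an Exponential(\code{lambda_bin}) excess, truncated at
#' 0.5 (heterozygous convention) by rejection.  Used to test the
#' calibration pipeline against known parameters; it does not emulate
#' donor-level covariates.
#'
#' @param expectedCounts named numeric: age-bin label -> expected
#'   detectable mutations per section.
#' @param lambdas named numeric: age-bin label -> exponential rate of the
#'   recentred VAF distribution.
#' @param samplesPerBin sections per age bin.
#' @param lod detection limit added to every VAF.
#' @param seed integer seed for a deterministic table, or \code{NULL}.
#' @return A \code{\link{VAFTable}} (zero-mutation sections appear in the
#'   manifest).
#' @examples
#' tab <- generateVAFTable(c(young = 1, old = 4),
#'                         c(young = 120, old = 80), samplesPerBin = 5,
#'                         seed = 1)
#' sampleManifest(tab)
#' @export
generateVAFTable <- function(expectedCounts, lambdas, samplesPerBin = 10,
                             lod = 0.011, seed = NULL) {
    stopifnot(!is.null(names(expectedCounts)),
              identical(sort(names(expectedCounts)), sort(names(lambdas))))
    if (any(lambdas <= 0)) stop("lambdas must be positive")
    if (any(expectedCounts < 0)) stop("expected counts must be >= 0")
    if (!is.null(seed)) set.seed(seed)
    bins <- names(expectedCounts)
    mrows <- list(); srows <- list()
    for (b in bins) {
        for (i in seq_len(samplesPerBin)) {
            nm <- rpois(1, expectedCounts[[b]])
            sid <- sprintf("synth_%s_s%03d", b, i)
            srows[[length(srows) + 1L]] <-
                data.frame(sample_id = sid, age_bin = b,
                           has_mutations = nm > 0)
            if (nm > 0) {
                v <- lod + rexp(nm, rate = lambdas[[b]])
                while (any(v > 0.5))   # truncate at 0.5 by rejection
                    v[v > 0.5] <- lod + rexp(sum(v > 0.5),
                                             rate = lambdas[[b]])
                mrows[[length(mrows) + 1L]] <-
                    data.frame(sample_id = sid, age_bin = b, vaf = v)
            }
        }
    }
    muts <- if (length(mrows)) do.call(rbind, mrows) else
        data.frame(sample_id = character(0), age_bin = character(0),
                   vaf = numeric(0))
    VAFTable(muts, do.call(rbind, srows), ageBins = bins)
}

#' Named study scenarios
#'
#' The exact configurations behind the headline simulation results, plus
#' miniature variants for fast checks.  Each entry is a plain list
#' understood by the command-line runner and by
#' \code{\link{runScenario}}.
#'
#' @return named list of scenario configurations.
#' @examples
#' names(goldenScenarios())
#' goldenScenarios()[["fig2_neutral"]]
#' @export
goldenScenarios <- function() {
    fate <- function(pCorr, k = 10, side = 100, reps = 100, horizon = 50)
        list(experiment = "fate", grid_side = side, k = k, D = 2,
             p_corr = pCorr, reps = reps, horizon_years = horizon)
    tp53 <- function(m = 1, r = 1, side = 70, reps = 100, horizon = 46)
        list(experiment = "tp53", grid_side = side, k = 30, D = 2,
             m = m, r = r, p_corr = NULL, p_plus_tp53 = 0.01,
             reps = reps, horizon_years = horizon)
    arr <- function(spacing, side = 400, reps = 10)
        list(experiment = "array", grid_side = side, rows = 4, cols = 4,
             spacing_um = spacing, k_per_needle = 30, D = 2,
             p_corr = 0.1, reps = reps, horizon_years = 10)
    list(
        fig2_neutral = fate(pCorr = 0),
        fig2_p01_k10 = fate(pCorr = 0.1, k = 10),
        fig2_p01_k30 = fate(pCorr = 0.1, k = 30),
        fig2_p1_k10 = fate(pCorr = 1, k = 10),
        fig3_array_175um = arr(175),
        fig3_array_350um = arr(350),
        fig3_array_700um = arr(700),
        fig4_cond1 = tp53(),
        fig4_cond2_m8 = tp53(m = 8),
        fig4_cond3_r4 = tp53(r = 4),
        mini_neutral = fate(pCorr = 0, k = 1, side = 10, reps = 20,
                            horizon = 2),
        mini_tp53 = tp53(side = 20, reps = 5, horizon = 2)
    )
}

#' Run a named or explicit scenario
#'
#' Dispatches a scenario configuration (see
#' \code{\link{goldenScenarios}}) to the matching experiment harness.
#'
#' @param config scenario list (fields as in \code{goldenScenarios}) or
#'   a scenario name.
#' @param seed root seed.
#' @param optimize engine mode.
#' @return the experiment result object.
#' @export
runScenario <- function(config, seed = NULL, optimize = TRUE) {
    if (is.character(config)) {
        config <- goldenScenarios()[[config]]
        if (is.null(config)) stop("unknown scenario name")
    }
    switch(config$experiment,
        fate = runFateExperiment(pCorr = config$p_corr,
                                 gridSide = config$grid_side,
                                 k = config$k, D = config$D,
                                 reps = config$reps,
                                 horizonYears = config$horizon_years,
                                 seed = seed, optimize = optimize),
        array = {
            spec <- ArraySpec(config$rows, config$cols,
                              spacingUm = config$spacing_um,
                              kPerNeedle = config$k_per_needle,
                              D = config$D,
                              center = c(config$grid_side / 2,
                                         config$grid_side / 2))
            runArrayExperiment(spec, gridSide = config$grid_side,
                               pCorr = config$p_corr, reps = config$reps,
                               horizonYears = config$horizon_years,
                               seed = seed, optimize = optimize)
        },
        tp53 = {
            unc <- runTP53Experiment(m = config$m, r = config$r,
                                     pCorr = NULL,
                                     gridSide = config$grid_side,
                                     k = config$k, D = config$D,
                                     reps = config$reps,
                                     horizonYears = config$horizon_years,
                                     pPlusTP53 = config$p_plus_tp53,
                                     seed = seed, optimize = optimize)
            if (is.null(config$p_corr)) unc else
                runTP53Experiment(m = config$m, r = config$r,
                                  pCorr = config$p_corr,
                                  gridSide = config$grid_side,
                                  k = config$k, D = config$D,
                                  reps = config$reps,
                                  horizonYears = config$horizon_years,
                                  pPlusTP53 = config$p_plus_tp53,
                                  uncorrectedPool = unc,
                                  seed = if (is.null(seed)) NULL else
                                      seed + 100000L,
                                  optimize = optimize)
        },
        stop("unknown experiment kind: ", config$experiment))
}
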