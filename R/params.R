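#' Simulation parameters for the basal-layer lattice
#'
#' Holds the kinetic and geometric constants of the basal-layer model.
#' Defaults reproduce oral mucosa: basal cells divide on average 1.8 times
#' per week, the vertical-placement probability is
#' \code{omega = 0.2518617}, cell density is 15,000 basal cells per
#' mm\eqn{^2} (66.7 \eqn{\mu m^2} per cell), and the state is recorded at
#' six-month intervals.
#'
#' Time is stepped in fixed increments of \code{timestepDays} days; in each
#' step every basal cell divides independently with probability
#' \code{divisionRate * timestepDays / 7} and cells are updated in a
#' freshly shuffled sequential order.  With the defaults the per-step
#' division probability is about 0.257.
#'
#' @param omega probability that the second daughter is placed vertically
#'   (suprabasally) rather than targeting a basal neighbour.
#' @param divisionRate mean divisions per cell per week.
#' @param timestepDays length of one update step, in days.
#' @param snapshotInterval interval between recorded snapshots, in years.
#' @param cellDensity basal cells per mm^2.
#' @param cellArea area per basal cell, in um^2.
#' @return A \code{SimParams} object.
#' @examples
#' sp <- SimParams()
#' divisionProb(sp)          # per-step division probability
#' @export
SimParams <- function(omega = 0.2518617, divisionRate = 1.8,
                      timestepDays = 1, snapshotInterval = 0.5,
                      cellDensity = 15000, cellArea = 66.7) {
    new("SimParams", omega = omega, divisionRate = divisionRate,
        timestepDays = timestepDays, snapshotInterval = snapshotInterval,
        cellDensity = cellDensity, cellArea = cellArea)
}

#' @rdname SimParams
#' @export
setClass("SimParams",
    representation(omega = "numeric", divisionRate = "numeric",
                   timestepDays = "numeric", snapshotInterval = "numeric",
                   cellDensity = "numeric", cellArea = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (object@omega < 0 || object@omega > 1)
            msg <- c(msg, "omega must lie in [0, 1]")
        if (object@divisionRate < 0)
            msg <- c(msg, "divisionRate must be non-negative")
        if (object@timestepDays <= 0)
            msg <- c(msg, "timestepDays must be positive")
        if (object@snapshotInterval <= 0)
            msg <- c(msg, "snapshotInterval must be positive")
        p <- object@divisionRate * object@timestepDays / 7
        if (p >= 0.5)
            msg <- c(msg, sprintf(
                "per-step division probability %.3f too large; shrink timestepDays", p))
        dens <- object@cellArea * object@cellDensity
        if (abs(dens - 1e6) / 1e6 > 0.05)
            msg <- c(msg, "cellArea * cellDensity should approximate 1e6 um^2/mm^2")
        if (is.null(msg)) TRUE else msg
    })

#' @rdname SimParams
#' @param params a \code{SimParams} object.
#' @export
divisionProb <- function(params) {
    stopifnot(is(params, "SimParams"))
    params@divisionRate * params@timestepDays / 7
}

#' Genotype-specific persistence coefficients
#'
#' The two-locus genotype (FANC corrected or not; carrying at least one
#' inactivating TP53 mutation or not) maps to a persistence coefficient:
#' the probability that the cell resists displacement when a dividing
#' neighbour targets it.  Uncorrected, TP53-wildtype FA cells never resist
#' (persistence 0).  A TP53 mutation adds \code{pPlusTP53} on a corrected
#' background and \code{ratioR * pPlusTP53} on an uncorrected background;
#' corrected TP53-wildtype cells have persistence \code{pCorr}, and
#' corrected TP53 mutants \code{pCorr + pPlusTP53}.  Additional TP53 hits
#' beyond the first change nothing.
#'
#' @param pCorr persistence of corrected, TP53-wildtype cells.
#' @param pPlusTP53 persistence increment conferred by TP53 loss on a
#'   corrected background; default 0.01, the value selected by the
#'   calibration pipeline against normal-esophagus VAF data.
#' @param ratioR multiplier for TP53 loss on the uncorrected background,
#'   so uncorrected TP53 mutants have persistence
#'   \code{ratioR * pPlusTP53}.
#' @return A \code{GenotypeParams} object.
#' @examples
#' gp <- GenotypeParams(pCorr = 0.1)
#' persistenceOf(fancCorrected = TRUE, tp53Hits = 1, gp)   # 0.11
#' @export
GenotypeParams <- function(pCorr = 0, pPlusTP53 = 0.01, ratioR = 1) {
    new("GenotypeParams", pCorr = pCorr, pPlusTP53 = pPlusTP53,
        ratioR = ratioR)
}

#' @rdname GenotypeParams
#' @export
setClass("GenotypeParams",
    representation(pCorr = "numeric", pPlusTP53 = "numeric",
                   ratioR = "numeric"),
    validity = function(object) {
        msg <- NULL
        ps <- c(hostWT = 0,
                hostMut = object@ratioR * object@pPlusTP53,
                corrWT = object@pCorr,
                corrMut = object@pCorr + object@pPlusTP53)
        if (any(ps < 0) || any(ps > 1))
            msg <- c(msg, "all genotype persistence values must lie in [0, 1]")
        if (object@ratioR < 0)
            msg <- c(msg, "ratioR must be non-negative")
        if (is.null(msg)) TRUE else msg
    })

#' @rdname GenotypeParams
#' @param fancCorrected logical vector: FANC function restored?
#' @param tp53Hits non-negative integer vector of inactivating TP53
#'   mutations carried.
#' @param gp a \code{GenotypeParams} object.
#' @export
persistenceOf <- function(fancCorrected, tp53Hits, gp) {
    stopifnot(is(gp, "GenotypeParams"))
    validObject(gp)
    if (any(tp53Hits < 0)) stop("tp53Hits must be non-negative")
    mut <- tp53Hits >= 1
    ifelse(fancCorrected,
           gp@pCorr + ifelse(mut, gp@pPlusTP53, 0),
           ifelse(mut, gp@ratioR * gp@pPlusTP53, 0))
}

#' TP53 mutation-rate parameters
#'
#' Each cell division draws a Poisson number of new inactivating TP53
#' mutations for the daughter that keeps the parent site.  The expected
#' number per division is \code{muPlus} for corrected cells and
#' \code{multiplierM * muPlus} for uncorrected FA cells (elevated genomic
#' instability).  The default \code{muPlus} of 7.48e-7 per division is the
#' genewide TP53 mutation rate (2.99e-6 per division) times the fraction
#' of mutations that inactivate the gene (~0.25, from deep mutational
#' scanning).
#'
#' @param muPlus expected inactivating TP53 mutations per division in
#'   corrected (FANC+) cells.
#' @param multiplierM fold-elevation of the rate in uncorrected FA cells.
#' @param genewideRate genewide TP53 mutation rate per division.
#' @param inactivatingFraction fraction of TP53 mutations that inactivate.
#' @return A \code{MutationParams} object.
#' @examples
#' mp <- MutationParams(multiplierM = 8)
#' mutationRateFor(fancCorrected = FALSE, mp)    # 8 x 7.48e-7
#' @export
MutationParams <- function(muPlus = 7.48e-7, multiplierM = 1,
                           genewideRate = 2.99e-6,
                           inactivatingFraction = 0.25) {
    new("MutationParams", muPlus = muPlus, multiplierM = multiplierM,
        genewideRate = genewideRate,
        inactivatingFraction = inactivatingFraction)
}

#' @rdname MutationParams
#' @export
setClass("MutationParams",
    representation(muPlus = "numeric", multiplierM = "numeric",
                   genewideRate = "numeric",
                   inactivatingFraction = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (object@muPlus < 0) msg <- c(msg, "muPlus must be non-negative")
        if (object@multiplierM < 1)
            msg <- c(msg, "multiplierM must be >= 1")
        if (object@genewideRate <= 0 || object@genewideRate >= 1)
            msg <- c(msg, "genewideRate must lie in (0, 1)")
        if (object@inactivatingFraction <= 0 || object@inactivatingFraction > 1)
            msg <- c(msg, "inactivatingFraction must lie in (0, 1]")
        if (is.null(msg)) TRUE else msg
    })

#' @rdname MutationParams
#' @param genewideRate,inactivatingFraction see above.
#' @details \code{inactivationRate} returns the product of the genewide
#'   rate and the inactivating fraction, i.e. the expected number of
#'   inactivating TP53 mutations per division.
#' @export
inactivationRate <- function(genewideRate = 2.99e-6,
                             inactivatingFraction = 0.25) {
    if (genewideRate <= 0 || genewideRate >= 1)
        stop("genewideRate must lie in (0, 1)")
    if (inactivatingFraction <= 0 || inactivatingFraction > 1)
        stop("inactivatingFraction must lie in (0, 1]")
    genewideRate * inactivatingFraction
}

#' @rdname MutationParams
#' @param fancCorrected logical vector.
#' @param mp a \code{MutationParams} object.
#' @export
mutationRateFor <- function(fancCorrected, mp) {
    stopifnot(is(mp, "MutationParams"))
    ifelse(fancCorrected, mp@muPlus, mp@multiplierM * mp@muPlus)
}

#' @rdname MutationParams
#' @param n number of divisions to draw for.
#' @param lambda expected inactivating mutations per division.
#' @details \code{drawTP53Hits} is the per-division mutation hook: a
#'   Poisson draw of new inactivating mutations.  Unique mutation-event
#'   ids are attached by the simulation engine when the draw is positive.
#' @export
drawTP53Hits <- function(n, lambda) {
    if (lambda < 0) stop("lambda must be non-negative")
    rpois(n, lambda)
}

setMethod("show", "SimParams", function(object) {
    cat("SimParams: omega =", object@omega,
        "| divisions/week =", object@divisionRate,
        "| step =", object@timestepDays, "d",
        "| density =", object@cellDensity, "cells/mm^2\n")
})

setMethod("show", "GenotypeParams", function(object) {
    cat("GenotypeParams:\n",
        sprintf("  host  TP53+ : 0\n  host  TP53- : %g\n", object@ratioR * object@pPlusTP53),
        sprintf("  corr  TP53+ : %g\n  corr  TP53- : %g\n", object@pCorr, object@pCorr + object@pPlusTP53))
})

setMethod("show", "MutationParams", function(object) {
    cat("MutationParams: mu(FANC+) =", object@muPlus,
        "| mu(FANC-) =", object@multiplierM * object@muPlus, "per division\n")
})
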