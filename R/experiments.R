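#' Corrected-patch fate experiment
#'
#' Replicated simulation of a single delivery into an all-FA tissue, each
#' replicate run until loss of all corrected cells, confluence (corrected
#' fraction >= 0.8) or the horizon.  Mirrors the single-needle design:
#' a fresh \code{gridSide x gridSide} host grid per replicate, delivery at
#' t = 0, up to 50 years of follow-up with six-month snapshots.
#'
#' Each replicate gets the deterministic seed \code{seed + replicate}, so
#' any replicate can be reproduced in isolation.
#'
#' @param pCorr persistence coefficient of corrected cells.
#' @param gridSide tissue side length in cells (default 100, i.e. a
#'   0.67 mm^2 section at 15,000 cells/mm^2).
#' @param k,D cells corrected and Gaussian variance of the single central
#'   needle (ignored when \code{plan} is given).
#' @param reps number of replicates.
#' @param horizonYears follow-up horizon.
#' @param plan optional \code{\link{DeliveryPlan}} overriding the central
#'   single-needle default.
#' @param simParams a \code{\link{SimParams}}.
#' @param genoParams optional \code{\link{GenotypeParams}}; default has
#'   the requested \code{pCorr} and no TP53 dynamics.
#' @param seed integer root seed, or \code{NULL} to use the current RNG
#'   state.
#' @param optimize engine mode, see \code{\link{advanceGrid}}.
#' @return list of class \code{"fateExperiment"}: \code{fates}
#'   (data.frame \code{replicate}, \code{outcome}, \code{eventTime},
#'   \code{seed}), \code{trajectories} (snapshot rows with a
#'   \code{replicate} column), and \code{summary} (outcome probabilities
#'   with binomial standard errors).
#' @examples
#' \donttest{
#' fe <- runFateExperiment(pCorr = 0, gridSide = 30, k = 3, reps = 10,
#'                         horizonYears = 2, seed = 1)
#' fe$summary
#' }
#' @export
runFateExperiment <- function(pCorr, gridSide = 100, k = 10, D = 2,
                              reps = 100, horizonYears = 50, plan = NULL,
                              simParams = SimParams(), genoParams = NULL,
                              seed = NULL, optimize = TRUE) {
    if (reps < 1) stop("reps must be >= 1")
    if (is.null(plan)) plan <- centralDelivery(gridSide, gridSide, k = k, D = D)
    # fate experiments have no TP53 dynamics, so the TP53 increment is 0
    # (this also keeps pCorr = 1 a valid configuration)
    if (is.null(genoParams))
        genoParams <- GenotypeParams(pCorr = pCorr, pPlusTP53 = 0)
    fates <- vector("list", reps)
    trajs <- vector("list", reps)
    for (i in seq_len(reps)) {
        repSeed <- NA_integer_
        if (!is.null(seed)) { repSeed <- seed + i; set.seed(repSeed) }
        g <- BasalGrid(gridSide, gridSide)
        g <- applyCorrection(g, plan)
        tr <- advanceGrid(g, years = horizonYears, simParams = simParams,
                          genoParams = genoParams, optimize = optimize)
        fates[[i]] <- data.frame(replicate = i, outcome = outcomeOf(tr),
                                 eventTime = eventTimeOf(tr),
                                 seed = repSeed)
        sn <- snapshots(tr)
        sn$replicate <- i
        trajs[[i]] <- sn
    }
    fates <- do.call(rbind, fates)
    trajs <- do.call(rbind, trajs)
    structure(list(fates = fates, trajectories = trajs,
                   gridSide = gridSide, plan = plan,
                   genoParams = genoParams, simParams = simParams,
                   summary = fateSummary(fates)),
              class = "fateExperiment")
}

#' @rdname runFateExperiment
#' @param fates data.frame with an \code{outcome} column.
#' @export
fateSummary <- function(fates) {
    n <- nrow(fates)
    out <- lapply(c(loss = "loss", confluence = "confluence",
                    ongoing = "ongoing"), function(o) {
        p <- mean(fates$outcome == o)
        c(prob = p, se = sqrt(p * (1 - p) / n))
    })
    data.frame(outcome = names(out),
               prob = vapply(out, `[[`, numeric(1), "prob"),
               se = vapply(out, `[[`, numeric(1), "se"),
               n = n, row.names = NULL)
}

#' Areal expansion rate of confluent corrected patches
#'
#' For every replicate that reached confluence, corrected cell counts at
#' the six-month snapshots are converted to area (\code{cellArea} um^2
#' per cell) and the least-squares slope of area versus time from
#' delivery to confluence is taken as that replicate's expansion rate.
#' The ensemble mean and its standard error are returned.
#'
#' @param experiment a \code{"fateExperiment"} result.
#' @param simParams a \code{\link{SimParams}} (for \code{cellArea}).
#' @return list: \code{meanRate} and \code{se} (mm^2/year), \code{n}
#'   confluent replicates, and \code{perReplicate} slopes.  With no
#'   confluent replicates, \code{n = 0} and the rates are \code{NA}.
#' @export
estimateExpansionRate <- function(experiment, simParams = SimParams()) {
    conf <- experiment$fates$replicate[experiment$fates$outcome == "confluence"]
    if (length(conf) == 0)
        return(list(meanRate = NA_real_, se = NA_real_, n = 0L,
                    perReplicate = numeric(0)))
    areaPerCell <- simParams@cellArea * 1e-6  # um^2 -> mm^2
    slopes <- vapply(conf, function(r) {
        sn <- experiment$trajectories[experiment$trajectories$replicate == r, ]
        if (nrow(sn) < 2) return(NA_real_)
        unname(coef(lm(I(sn$corrected * areaPerCell) ~ sn$time))[2])
    }, numeric(1))
    slopes <- slopes[!is.na(slopes)]
    list(meanRate = mean(slopes),
         se = if (length(slopes) > 1) sd(slopes) / sqrt(length(slopes)) else NA_real_,
         n = length(slopes), perReplicate = slopes)
}

#' Clone areas in a grid snapshot
#'
#' Cell counts and areas per lineage label.  \code{by = "clone_id"}
#' groups corrected cells by founder cell, \code{by = "needle_id"} by
#' microneedle of origin, and \code{by = "mutation_event_id"} counts the
#' cells carrying each independent TP53 mutation event (nested double
#' hits are counted under each event id they carry).
#'
#' @param grid a \code{\link{BasalGrid}}.
#' @param by grouping label.
#' @param simParams a \code{\link{SimParams}} (for \code{cellArea}).
#' @return data.frame: \code{label}, \code{cells}, \code{areaMm2}.
#' @export
cloneAreas <- function(grid, by = c("clone_id", "needle_id", "mutation_event_id"),
                       simParams = SimParams()) {
    by <- match.arg(by)
    areaPerCell <- simParams@cellArea * 1e-6
    if (by == "mutation_event_id") {
        cnt <- gridEventCounts(grid)
    } else {
        lab <- if (by == "clone_id") grid@cloneId else grid@needleId
        lab <- lab[lab > 0L]
        cnt <- table(factor(lab))
        cnt <- setNames(as.integer(cnt), names(cnt))
    }
    data.frame(label = as.integer(names(cnt)), cells = unname(cnt),
               areaMm2 = unname(cnt) * areaPerCell)
}

# cells carrying each TP53 mutation-event id (named integer vector;
# events with zero surviving cells are dropped)
gridEventCounts <- function(grid) {
    nEv <- grid@nextEventId - 1L
    if (nEv == 0L) return(setNames(integer(0), character(0)))
    cnt <- integer(nEv)
    pid <- grid@profileId[grid@profileId > 0L]
    for (p in pid) {
        ev <- grid@profiles[[p]]
        cnt[ev] <- cnt[ev] + 1L
    }
    keep <- cnt > 0L
    setNames(cnt[keep], which(keep))
}

#' Spatially connected corrected patches
#'
#' Sizes of the 4-connected components of corrected cells (under the
#' grid's boundary mode) — the spatial-patch alternative to grouping by
#' lineage label.
#'
#' @param grid a \code{\link{BasalGrid}}.
#' @return integer vector of component sizes (cells), decreasing.
#' @export
correctedPatches <- function(grid) {
    w <- grid@width; h <- grid@height
    corr <- grid@corrected == 1L
    seen <- matrix(FALSE, w, h)
    sizes <- integer(0)
    periodic <- grid@boundaryMode == "periodic"
    for (start in which(corr)) {
        if (seen[start]) next
        queue <- start
        seen[start] <- TRUE
        size <- 0L
        while (length(queue)) {
            s <- queue[length(queue)]
            queue <- queue[-length(queue)]
            size <- size + 1L
            x <- (s - 1L) %% w; y <- (s - 1L) %/% w
            for (d in 1:4) {
                xx <- x + c(-1L, 1L, 0L, 0L)[d]
                yy <- y + c(0L, 0L, -1L, 1L)[d]
                if (periodic) {
                    xx <- xx %% w; yy <- yy %% h
                } else if (xx < 0L || xx >= w || yy < 0L || yy >= h) next
                t <- xx + yy * w + 1L
                if (corr[t] && !seen[t]) { seen[t] <- TRUE; queue <- c(queue, t) }
            }
        }
        sizes <- c(sizes, size)
    }
    sort(sizes, decreasing = TRUE)
}

#' Microneedle array experiment
#'
#' Replicated simulation of arrayed delivery on a large tissue section
#' (default 400 x 400 cells, 10.67 mm^2), following the per-needle
#' descendant areas to the horizon (default 10 years).  There is no
#' confluence stop; replicates only stop early if every corrected cell is
#' lost.
#'
#' @param spec an \code{\link{ArraySpec}} (its centre should be the grid
#'   centre).
#' @param gridSide tissue side in cells.
#' @param pCorr persistence coefficient of corrected cells.
#' @param reps replicates.
#' @param horizonYears follow-up.
#' @param simParams,seed,optimize as in \code{\link{runFateExperiment}}.
#' @return list of class \code{"arrayExperiment"}: \code{needleAreas}
#'   (data.frame \code{replicate}, \code{needle}, \code{cells},
#'   \code{areaMm2} at the horizon), \code{totals} (per-replicate total
#'   corrected area), and \code{meanTotalArea}.
#' @export
runArrayExperiment <- function(spec, gridSide = 400, pCorr = 0.1,
                               reps = 10, horizonYears = 10,
                               simParams = SimParams(), seed = NULL,
                               optimize = TRUE) {
    stopifnot(is(spec, "ArraySpec"))
    plan <- arraySites(spec, cellDensity = simParams@cellDensity,
                       gridDims = c(gridSide, gridSide))
    genoParams <- GenotypeParams(pCorr = pCorr)
    areaPerCell <- simParams@cellArea * 1e-6
    perNeedle <- vector("list", reps)
    totals <- numeric(reps)
    for (i in seq_len(reps)) {
        if (!is.null(seed)) set.seed(seed + i)
        g <- BasalGrid(gridSide, gridSide)
        g <- applyCorrection(g, plan)
        tr <- advanceGrid(g, years = horizonYears, simParams = simParams,
                          genoParams = genoParams,
                          confluenceFraction = NA, optimize = optimize)
        fg <- finalGrid(tr)
        cnt <- tabulate(fg@needleId[fg@needleId > 0L],
                        nbins = nrow(plan@sites))
        perNeedle[[i]] <- data.frame(replicate = i,
                                     needle = seq_along(cnt),
                                     cells = cnt,
                                     areaMm2 = cnt * areaPerCell)
        totals[i] <- sum(cnt) * areaPerCell
    }
    structure(list(needleAreas = do.call(rbind, perNeedle),
                   totals = totals, meanTotalArea = mean(totals),
                   spec = spec, plan = plan, gridSide = gridSide,
                   pCorr = pCorr),
              class = "arrayExperiment")
}

#' TP53 burden experiment
#'
#' Replicated simulation of TP53 mutation accumulation in 0.33 mm^2
#' (70 x 70 cell) tissue sections, with or without gene correction,
#' following the fraction of basal cells carrying at least one
#' inactivating TP53 mutation at six-month intervals up to 46 years.
#'
#' The three experimental conditions are expressed through \code{m} and
#' \code{r}: condition 1 (\code{m = 1, r = 1}) has identical TP53
#' mutation rates and persistence on both FANC backgrounds; condition 2
#' (\code{m > 1, r = 1}) elevates the FA-cell mutation rate; condition 3
#' (\code{m = 1, r > 1}) elevates the FA-cell TP53 persistence.
#'
#' Corrected arms (\code{pCorr} non-\code{NULL}) stop a replicate when
#' every corrected cell is lost; from that time on, its timepoints are
#' substituted with values sampled, independently at each timepoint, from
#' a random replicate of the supplied uncorrected pool (such a tissue
#' behaves like one never corrected).  The 46-year clone statistics of a
#' stopped replicate are likewise drawn from a random uncorrected
#' replicate.
#'
#' @param m fold-elevation of the FA-cell TP53 mutation rate.
#' @param r fold-elevation of the FA-cell TP53 persistence coefficient.
#' @param pCorr persistence of corrected cells, or \code{NULL} for the
#'   uncorrected arm.
#' @param gridSide,k,D tissue side and single-needle delivery dose.
#' @param reps replicates.
#' @param horizonYears quantification horizon (default 46).
#' @param pPlusTP53 TP53 persistence increment on the corrected
#'   background (default 0.01, the calibrated value).
#' @param mutParams base \code{\link{MutationParams}}; its
#'   \code{multiplierM} is replaced by \code{m}.
#' @param uncorrectedPool a \code{"tp53Experiment"} result from the
#'   matching uncorrected arm; required when \code{pCorr} is given.
#' @param simParams,seed,optimize as in \code{\link{runFateExperiment}}.
#' @return list of class \code{"tp53Experiment"}: \code{times},
#'   \code{coverage} (reps x times matrix of TP53-mutant fractions, with
#'   substituted values where a corrected replicate was stopped),
#'   \code{lossTimes}, \code{cloneStats} (per-replicate distinct TP53
#'   clone count and median clone size at the horizon), and
#'   \code{finalGrids} is not kept (grids are summarised on the fly).
#' @export
runTP53Experiment <- function(m = 1, r = 1, pCorr = NULL, gridSide = 70,
                              k = 30, D = 2, reps = 100,
                              horizonYears = 46, pPlusTP53 = 0.01,
                              mutParams = MutationParams(),
                              uncorrectedPool = NULL,
                              simParams = SimParams(), seed = NULL,
                              optimize = TRUE) {
    if (reps < 1) stop("reps must be >= 1")
    correctedArm <- !is.null(pCorr)
    if (correctedArm && is.null(uncorrectedPool))
        stop("aggregation error: corrected arm needs an uncorrected pool")
    mp <- MutationParams(muPlus = mutParams@muPlus, multiplierM = m,
                         genewideRate = mutParams@genewideRate,
                         inactivatingFraction = mutParams@inactivatingFraction)
    gp <- GenotypeParams(pCorr = if (correctedArm) pCorr else 0,
                         pPlusTP53 = pPlusTP53, ratioR = r)
    N <- gridSide * gridSide

    times <- NULL
    coverage <- NULL
    lossTimes <- rep(NA_real_, reps)
    cloneStats <- vector("list", reps)
    for (i in seq_len(reps)) {
        if (!is.null(seed)) set.seed(seed + i)
        g <- BasalGrid(gridSide, gridSide)
        if (correctedArm)
            g <- applyCorrection(g, centralDelivery(gridSide, gridSide,
                                                    k = k, D = D))
        tr <- advanceGrid(g, years = horizonYears, simParams = simParams,
                          genoParams = gp, mutParams = mp,
                          checkLoss = correctedArm,
                          confluenceFraction = NA, optimize = optimize)
        sn <- snapshots(tr)
        if (is.null(times)) {
            # canonical snapshot schedule: the first full-horizon replicate
            fullTimes <- snapshotTimes(horizonYears, simParams)
            times <- fullTimes
            coverage <- matrix(NA_real_, nrow = reps, ncol = length(times))
        }
        idx <- match(round(sn$time, 9), round(times, 9))
        ok <- !is.na(idx)
        coverage[i, idx[ok]] <- sn$tp53Mutant[ok] / N
        if (outcomeOf(tr) == "loss") lossTimes[i] <- eventTimeOf(tr)
        ev <- gridEventCounts(finalGrid(tr))
        cloneStats[[i]] <- data.frame(
            replicate = i, nClones = length(ev),
            medianCloneCells = if (length(ev)) median(ev) else NA_real_,
            substituted = FALSE)
    }

    if (correctedArm) {
        poolCov <- uncorrectedPool$coverage
        if (ncol(poolCov) != length(times))
            stop("aggregation error: pool snapshot schedule does not match")
        for (i in seq_len(reps)) {
            missing <- which(is.na(coverage[i, ]))
            for (jj in missing) {
                donor <- sample.int(nrow(poolCov), 1L)
                coverage[i, jj] <- poolCov[donor, jj]
            }
            if (!is.na(lossTimes[i])) {
                donor <- sample.int(nrow(poolCov), 1L)
                cs <- uncorrectedPool$cloneStats[
                    uncorrectedPool$cloneStats$replicate == donor, ]
                cloneStats[[i]] <- data.frame(
                    replicate = i, nClones = cs$nClones,
                    medianCloneCells = cs$medianCloneCells,
                    substituted = TRUE)
            }
        }
    }

    structure(list(m = m, r = r, pCorr = pCorr, times = times,
                   coverage = coverage, lossTimes = lossTimes,
                   cloneStats = do.call(rbind, cloneStats),
                   gridSide = gridSide),
              class = "tp53Experiment")
}

# snapshot schedule (absolute times in years) of a full-horizon run;
# rounding must match the engine (half away from zero, as C lround)
snapshotTimes <- function(horizonYears, simParams = SimParams()) {
    dt <- simParams@timestepDays
    nSteps <- ceiling(horizonYears * 365 / dt - 1e-9)
    snapEvery <- max(1L, floor(simParams@snapshotInterval * 365 / dt + 0.5))
    steps <- unique(c(0L,
                      if (snapEvery <= nSteps)
                          seq(snapEvery, nSteps, by = snapEvery),
                      nSteps))
    steps * dt / 365
}

#' @rdname runTP53Experiment
#' @param experiment a \code{"tp53Experiment"} result.
#' @details \code{coverageSummary} gives the per-timepoint ensemble mean
#'   TP53-mutant tissue fraction and its standard error.
#' @export
coverageSummary <- function(experiment) {
    cov <- experiment$coverage
    data.frame(time = experiment$times,
               mean = colMeans(cov, na.rm = TRUE),
               se = apply(cov, 2, function(v)
                   sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))))
}

#' @rdname runTP53Experiment
#' @param atTime evaluation time (default: last common timepoint).
#' @details \code{meanCoverageAt} is the headline summary: mean fraction
#'   of basal cells with at least one TP53 hit at \code{atTime}.
#' @export
meanCoverageAt <- function(experiment, atTime = max(experiment$times)) {
    j <- which.min(abs(experiment$times - atTime))
    v <- experiment$coverage[, j]
    list(time = experiment$times[j], mean = mean(v, na.rm = TRUE),
         se = sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
}
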