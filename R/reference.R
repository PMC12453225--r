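#' Resolve a single cell division
#'
#' The division primitive, exposed for inspection and testing.  With
#' probability \code{omega} the second daughter is placed vertically and
#' the basal state is unchanged.  Otherwise a uniform Von Neumann
#' neighbour is targeted; it resists with probability
#' \code{persistenceFn(record)}, forcing vertical placement, and is
#' otherwise replaced by a copy of the parent record (the displaced record
#' leaves the basal layer permanently).
#'
#' @param grid a \code{\link{BasalGrid}}.
#' @param parent \code{c(x, y)} of the dividing cell, 0-based.
#' @param persistenceFn maps a cell record (list with
#'   \code{fancCorrected}, \code{tp53Hits}, \code{cloneId},
#'   \code{needleId}) to a persistence probability in \code{[0, 1]}.
#' @param omega vertical-placement probability.
#' @return list with \code{outcome} (\code{"vertical"} or
#'   \code{"displaced"}), \code{target} (coordinates or \code{NULL}) and
#'   the updated \code{grid}.
#' @export
resolveDivision <- function(grid, parent, persistenceFn,
                            omega = 0.2518617) {
    stopifnot(is(grid, "BasalGrid"), is.function(persistenceFn))
    px <- as.integer(parent[1]); py <- as.integer(parent[2])
    if (px < 0L || px >= grid@width || py < 0L || py >= grid@height)
        stop("parent out of bounds")
    if (runif(1) < omega)
        return(list(outcome = "vertical", target = NULL, grid = grid))
    nb <- neighborSites(grid, parent)
    tgt <- nb[sample.int(nrow(nb), 1L), ]
    i <- tgt[1] + 1L; j <- tgt[2] + 1L
    hits <- if (grid@profileId[i, j] > 0L)
        length(grid@profiles[[grid@profileId[i, j]]]) else 0L
    rec <- list(fancCorrected = grid@corrected[i, j] == 1L,
                tp53Hits = hits, cloneId = grid@cloneId[i, j],
                needleId = grid@needleId[i, j])
    p <- persistenceFn(rec)
    if (is.na(p) || p < 0 || p > 1)
        stop("persistenceFn must return a probability in [0, 1]")
    if (runif(1) < p)
        return(list(outcome = "vertical", target = NULL, grid = grid))
    pi_ <- px + 1L; pj <- py + 1L
    grid@corrected[i, j] <- grid@corrected[pi_, pj]
    grid@cloneId[i, j] <- grid@cloneId[pi_, pj]
    grid@needleId[i, j] <- grid@needleId[pi_, pj]
    grid@profileId[i, j] <- grid@profileId[pi_, pj]
    list(outcome = "displaced", target = unname(tgt), grid = grid)
}

#' Naive full-sweep reference stepper
#'
#' A plain-R implementation of the basal-layer dynamics, visiting every
#' site of the lattice every step.  It exists as the readable reference
#' against which the compiled engine (both its naive and active-region
#' modes) is checked for distributional equivalence; use it only on small
#' grids.
#'
#' @inheritParams advanceGrid
#' @return list with \code{outcome}, \code{eventTime}, \code{finalGrid}
#'   and a \code{snapshots} data.frame (\code{time}, \code{corrected},
#'   \code{tp53Mutant}).
#' @seealso \code{\link{advanceGrid}}
#' @export
advanceGridR <- function(grid, years, simParams = SimParams(),
                         genoParams = GenotypeParams(), mutParams = NULL,
                         checkLoss = TRUE, confluenceFraction = 0.8,
                         startYears = 0) {
    stopifnot(is(grid, "BasalGrid"))
    w <- grid@width; h <- grid@height; N <- w * h
    divP <- divisionProb(simParams)
    omega <- simParams@omega
    lamCorr <- if (is.null(mutParams)) 0 else mutationRateFor(TRUE, mutParams)
    lamHost <- if (is.null(mutParams)) 0 else mutationRateFor(FALSE, mutParams)
    pers <- c(0, genoParams@ratioR * genoParams@pPlusTP53,
              genoParams@pCorr, genoParams@pCorr + genoParams@pPlusTP53)

    # flat state vectors, 1-based site index s = x + y*w + 1
    corr <- as.integer(grid@corrected)
    clid <- as.integer(grid@cloneId)
    ndid <- as.integer(grid@needleId)
    pid <- as.integer(grid@profileId)
    profiles <- grid@profiles
    nextEv <- grid@nextEventId

    nbrs <- lapply(seq_len(N) - 1L, function(s) {
        xy <- c(s %% w, s %/% w)
        nb <- neighborSites(grid, xy)
        nb[, 1] + nb[, 2] * w + 1L
    })

    nSteps <- ceiling(years * 365 / simParams@timestepDays - 1e-9)
    snapEvery <- max(1L, floor(simParams@snapshotInterval * 365 /
                               simParams@timestepDays + 0.5))
    confCells <- confluenceFraction * N - 1e-9
    checkConf <- !is.na(confluenceFraction)

    outcome <- "ongoing"; eventTime <- NA_real_
    snaps <- list(data.frame(time = startYears, corrected = sum(corr),
                             tp53Mutant = sum(pid > 0L)))
    if (checkLoss && sum(corr) == 0L) {
        outcome <- "loss"; eventTime <- startYears
    } else if (checkConf && sum(corr) >= confCells) {
        outcome <- "confluence"; eventTime <- startYears
    }

    step <- 0L
    while (outcome == "ongoing" && step < nSteps) {
        step <- step + 1L
        tNow <- startYears + step * simParams@timestepDays / 365
        # each site divides with probability divP this step, in a freshly
        # shuffled order, with whatever record occupies it at its turn
        dividing <- which(runif(N) < divP)
        for (s in dividing[sample.int(length(dividing))]) {
            if (runif(1) >= omega) {
                nb <- nbrs[[s]]
                tgt <- nb[sample.int(length(nb), 1L)]
                cls <- 1L + (pid[tgt] > 0L) + 2L * corr[tgt]
                p <- pers[cls]
                if (p <= 0 || runif(1) >= p) {
                    corr[tgt] <- corr[s]; clid[tgt] <- clid[s]
                    ndid[tgt] <- ndid[s]; pid[tgt] <- pid[s]
                }
            }
            lam <- if (corr[s] == 1L) lamCorr else lamHost
            if (lam > 0) {
                nh <- rpois(1, lam)
                if (nh > 0) {
                    prof <- if (pid[s] > 0L) profiles[[pid[s]]] else integer(0)
                    profiles[[length(profiles) + 1L]] <-
                        c(prof, seq.int(nextEv, length.out = nh))
                    nextEv <- nextEv + nh
                    pid[s] <- length(profiles)
                }
            }
        }
        if (checkLoss && sum(corr) == 0L) {
            outcome <- "loss"; eventTime <- tNow
        } else if (checkConf && step %% max(1L, round(1 / simParams@timestepDays)) == 0L &&
                   sum(corr) >= confCells) {
            outcome <- "confluence"; eventTime <- tNow
        }
        if (step %% snapEvery == 0L || outcome != "ongoing" || step == nSteps)
            snaps[[length(snaps) + 1L]] <-
                data.frame(time = tNow, corrected = sum(corr),
                           tp53Mutant = sum(pid > 0L))
    }

    out <- grid
    out@corrected <- matrix(corr, w, h)
    out@cloneId <- matrix(clid, w, h)
    out@needleId <- matrix(ndid, w, h)
    out@profileId <- matrix(pid, w, h)
    out@profiles <- profiles
    out@nextEventId <- as.integer(nextEv)
    list(outcome = outcome, eventTime = eventTime, finalGrid = out,
         snapshots = do.call(rbind, snaps))
}
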