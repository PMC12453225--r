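#' Simulation trajectory
#'
#' Time-stamped record of a simulated tissue: snapshots at the configured
#' interval (default six months) with corrected and TP53-mutant cell
#' counts, per-genotype-class counts, per-needle and per-clone corrected
#' cell counts, and per-mutation-event cell counts; plus the endpoint
#' classification (\code{"loss"}, \code{"confluence"} or \code{"ongoing"})
#' and the final grid state.
#'
#' @slot snapshots data.frame: \code{time} (years), \code{corrected},
#'   \code{tp53Mutant}, \code{hostWT}, \code{hostMut}, \code{corrWT},
#'   \code{corrMut} cell counts.
#' @slot needleCounts data.frame of corrected cells per needle label per
#'   snapshot.
#' @slot cloneCounts data.frame of corrected cells per clone label per
#'   snapshot.
#' @slot eventCounts data.frame of cells carrying each TP53
#'   mutation-event id per snapshot.
#' @slot outcome one of \code{"loss"}, \code{"confluence"},
#'   \code{"ongoing"}.
#' @slot eventTime years at which the endpoint was reached (\code{NA} for
#'   ongoing).
#' @slot finalGrid the \code{\link{BasalGrid}} at the last recorded time.
#' @include grid.R params.R AllGenerics.R
#' @export
setClass("Trajectory",
    representation(snapshots = "data.frame", needleCounts = "data.frame",
                   cloneCounts = "data.frame", eventCounts = "data.frame",
                   outcome = "character", eventTime = "numeric",
                   finalGrid = "BasalGrid"),
    validity = function(object) {
        msg <- NULL
        if (!object@outcome %in% c("loss", "confluence", "ongoing"))
            msg <- c(msg, "outcome must be loss, confluence or ongoing")
        tms <- object@snapshots$time
        if (length(tms) && any(diff(tms) <= 0))
            msg <- c(msg, "snapshot times must be strictly increasing")
        if (is.null(msg)) TRUE else msg
    })

setMethod("show", "Trajectory", function(object) {
    n <- nrow(object@snapshots)
    cat(sprintf("Trajectory: %d snapshots over %.2f years; outcome '%s'",
                n, if (n) max(object@snapshots$time) else 0, object@outcome))
    if (!is.na(object@eventTime))
        cat(sprintf(" at %.3f years", object@eventTime))
    cat("\n")
})

#' @describeIn Trajectory snapshot table.
#' @param x a \code{Trajectory}.
#' @export
setMethod("snapshots", "Trajectory", function(x) x@snapshots)

#' @describeIn Trajectory final \code{BasalGrid}.
#' @export
setMethod("finalGrid", "Trajectory", function(x) x@finalGrid)

#' @describeIn Trajectory endpoint classification.
#' @export
setMethod("outcomeOf", "Trajectory", function(x) x@outcome)

#' @describeIn Trajectory endpoint time in years (NA if ongoing).
#' @export
setMethod("eventTimeOf", "Trajectory", function(x) x@eventTime)

#' @describeIn Trajectory corrected fraction over time, from the
#'   snapshot table.
#' @export
setMethod("correctedFraction", "Trajectory", function(x) {
    N <- x@finalGrid@width * x@finalGrid@height
    setNames(x@snapshots$corrected / N, x@snapshots$time)
})

#' @describeIn Trajectory TP53-mutant fraction over time.
#' @export
setMethod("tp53Fraction", "Trajectory", function(x) {
    N <- x@finalGrid@width * x@finalGrid@height
    setNames(x@snapshots$tp53Mutant / N, x@snapshots$time)
})

#' Advance the basal-layer dynamics
#'
#' Runs the stochastic lattice dynamics for up to \code{years} simulated
#' years or until an endpoint is reached.  Per timestep each basal cell
#' divides independently with probability
#' \code{divisionRate * timestepDays / 7}, in shuffled sequential order
#' over sites.  A division places the second daughter vertically with
#' probability \code{omega}; otherwise a uniform Von Neumann neighbour is
#' targeted and resists displacement with its genotype persistence
#' coefficient, in which case the daughter is placed vertically instead.
#' Displacement copies the parent record (genotype, clone, needle,
#' mutation profile) over the target; the displaced record stratifies and
#' never returns.  When \code{mutParams} is supplied, the daughter
#' retaining the parent site draws a Poisson number of new inactivating
#' TP53 mutations each division.
#'
#' \code{optimize = TRUE} resolves explicitly only divisions at sites that
#' are, or neighbour, a non-background cell; all-background regions are
#' exchangeable and their mutation influx is injected by Poisson thinning
#' of the aggregate division flux.  Distributional equivalence with the
#' naive full sweep is part of the test suite.
#'
#' @param grid a \code{\link{BasalGrid}}.
#' @param years horizon in simulated years (endpoints may stop earlier).
#' @param simParams a \code{\link{SimParams}}.
#' @param genoParams a \code{\link{GenotypeParams}}.
#' @param mutParams a \code{\link{MutationParams}}, or \code{NULL} to
#'   disable TP53 mutation.
#' @param checkLoss stop (outcome \code{"loss"}) when no corrected cells
#'   remain; checked every timestep.
#' @param confluenceFraction stop (outcome \code{"confluence"}) when the
#'   corrected fraction reaches this value (default 0.8); checked once per
#'   simulated day.  \code{NA} disables the check.
#' @param optimize use the active-region engine (default) or the naive
#'   full sweep.
#' @param startYears time label of the initial state (snapshots are
#'   stamped with absolute time).
#' @return A \code{\link{Trajectory}}.
#' @examples
#' g <- BasalGrid(10, 10)
#' tr <- advanceGrid(g, years = 1, genoParams = GenotypeParams(pCorr = 0),
#'                   checkLoss = FALSE)
#' outcomeOf(tr)
#' @export
advanceGrid <- function(grid, years, simParams = SimParams(),
                        genoParams = GenotypeParams(),
                        mutParams = NULL, checkLoss = TRUE,
                        confluenceFraction = 0.8, optimize = TRUE,
                        startYears = 0) {
    stopifnot(is(grid, "BasalGrid"), is(simParams, "SimParams"),
              is(genoParams, "GenotypeParams"))
    validObject(simParams); validObject(genoParams)
    if (years < 0) stop("years must be non-negative")
    lamCorr <- 0; lamHost <- 0
    if (!is.null(mutParams)) {
        stopifnot(is(mutParams, "MutationParams"))
        validObject(mutParams)
        lamCorr <- mutationRateFor(TRUE, mutParams)
        lamHost <- mutationRateFor(FALSE, mutParams)
    }
    checkConf <- !is.na(confluenceFraction)
    res <- cpp_advance(
        as.integer(grid@corrected), as.integer(grid@cloneId),
        as.integer(grid@needleId), as.integer(grid@profileId),
        grid@profiles, grid@width, grid@height,
        grid@boundaryMode == "periodic",
        simParams@omega, divisionProb(simParams), simParams@timestepDays,
        startYears, years, simParams@snapshotInterval,
        0, genoParams@ratioR * genoParams@pPlusTP53,
        genoParams@pCorr, genoParams@pCorr + genoParams@pPlusTP53,
        lamCorr, lamHost,
        checkLoss, checkConf,
        if (checkConf) confluenceFraction else 2,
        optimize, grid@nextEventId)

    out <- grid
    dims <- c(grid@width, grid@height)
    out@corrected <- matrix(res$corrected, dims[1], dims[2])
    out@cloneId <- matrix(res$cloneId, dims[1], dims[2])
    out@needleId <- matrix(res$needleId, dims[1], dims[2])
    out@profileId <- matrix(res$profileId, dims[1], dims[2])
    out@profiles <- res$profiles
    out@nextEventId <- as.integer(res$nextEventId)

    snaps <- data.frame(time = res$snapTimes,
                        corrected = res$snapCorrected,
                        tp53Mutant = res$snapTP53,
                        corrMut = res$snapCorrMut,
                        hostMut = res$snapHostMut)
    snaps$corrWT <- snaps$corrected - snaps$corrMut
    snaps$hostWT <- prod(dims) - snaps$corrected - snaps$hostMut
    snaps <- snaps[, c("time", "corrected", "tp53Mutant",
                       "hostWT", "hostMut", "corrWT", "corrMut")]
    # snapshots can repeat the final time if the endpoint fell on a
    # snapshot step; drop duplicates
    snaps <- snaps[!duplicated(snaps$time), , drop = FALSE]
    keep <- !duplicated(res$snapTimes)

    longify <- function(lst, label) {
        rows <- lapply(which(keep), function(i) {
            v <- lst[[i]]
            if (length(v) == 0L) return(NULL)
            data.frame(time = res$snapTimes[i], id = seq_along(v), cells = v)
        })
        df <- do.call(rbind, rows)
        if (is.null(df))
            df <- data.frame(time = numeric(0), id = integer(0),
                             cells = numeric(0))
        names(df)[2] <- label
        df
    }

    new("Trajectory",
        snapshots = snaps,
        needleCounts = longify(res$snapNeedleCounts, "needle"),
        cloneCounts = longify(res$snapCloneCounts, "clone"),
        eventCounts = longify(res$snapEventCounts, "event"),
        outcome = c("ongoing", "loss", "confluence")[res$outcome + 1L],
        eventTime = res$eventTime,
        finalGrid = out)
}

#' @rdname advanceGrid
#' @param trajectory a \code{Trajectory}.
#' @details \code{needleCounts}, \code{cloneCounts} and
#'   \code{eventCounts} extract the respective long-format tables.
#' @export
needleCounts <- function(trajectory) trajectory@needleCounts

#' @rdname advanceGrid
#' @export
cloneCounts <- function(trajectory) trajectory@cloneCounts

#' @rdname advanceGrid
#' @export
eventCounts <- function(trajectory) trajectory@eventCounts
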