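#' Per-sample VAF tables
#'
#' Container for deep-sequencing style TP53 variant allele frequency
#' (VAF) data: one row per detected mutation (\code{sample_id},
#' \code{age_bin}, \code{vaf}) plus a sample manifest (\code{sample_id},
#' \code{age_bin}, \code{has_mutations}) so that sections with no
#' detectable mutation still enter the count statistics.  All mutations
#' are treated as heterozygous single-copy, so a VAF is half the mutant
#' cell fraction and cannot exceed 0.5.
#'
#' @param mutations data.frame with columns \code{sample_id},
#'   \code{age_bin}, \code{vaf}.
#' @param samples optional manifest data.frame (\code{sample_id},
#'   \code{age_bin}, \code{has_mutations}); derived from \code{mutations}
#'   when omitted (then no zero-mutation sections are represented).
#' @param ageBins ordered character vector of age-bin labels; defaults to
#'   the sorted unique bins present.
#' @return A \code{VAFTable}.
#' @export
VAFTable <- function(mutations, samples = NULL, ageBins = NULL) {
    mutations <- as.data.frame(mutations)
    if (is.null(samples)) {
        u <- unique(mutations[, c("sample_id", "age_bin")])
        samples <- data.frame(sample_id = u$sample_id, age_bin = u$age_bin,
                              has_mutations = TRUE)
    }
    samples <- as.data.frame(samples)
    if (is.null(ageBins))
        ageBins <- sort(unique(as.character(samples$age_bin)))
    new("VAFTable", mutations = mutations, samples = samples,
        ageBins = as.character(ageBins))
}

#' @rdname VAFTable
#' @export
setClass("VAFTable",
    representation(mutations = "data.frame", samples = "data.frame",
                   ageBins = "character"),
    validity = function(object) {
        msg <- NULL
        m <- object@mutations
        if (!all(c("sample_id", "age_bin", "vaf") %in% names(m)))
            msg <- c(msg, "mutations needs columns sample_id, age_bin, vaf")
        else if (nrow(m) && (any(m$vaf <= 0) || any(m$vaf > 0.5)))
            msg <- c(msg, "VAFs must lie in (0, 0.5]")
        s <- object@samples
        if (!all(c("sample_id", "age_bin", "has_mutations") %in% names(s)))
            msg <- c(msg, "samples needs columns sample_id, age_bin, has_mutations")
        else {
            if (!all(as.character(s$age_bin) %in% object@ageBins))
                msg <- c(msg, "sample age_bin values must be declared in ageBins")
            if (nrow(m) && !all(m$sample_id %in% s$sample_id))
                msg <- c(msg, "all mutation sample_ids must appear in the manifest")
        }
        if (is.null(msg)) TRUE else msg
    })

setMethod("show", "VAFTable", function(object) {
    cat(sprintf("VAFTable: %d mutations in %d samples across %d age bins\n",
                nrow(object@mutations), nrow(object@samples),
                length(object@ageBins)))
})

#' @describeIn VAFTable mutation rows.
#' @param x a \code{VAFTable}.
#' @export
setMethod("vafData", "VAFTable", function(x) x@mutations)

#' @describeIn VAFTable sample manifest.
#' @export
setMethod("sampleManifest", "VAFTable", function(x) x@samples)

#' @rdname VAFTable
#' @param table a \code{VAFTable}.
#' @param mutationsFile,samplesFile CSV paths.
#' @export
writeVAFTable <- function(table, mutationsFile, samplesFile) {
    write.csv(table@mutations, mutationsFile, row.names = FALSE, quote = FALSE)
    write.csv(table@samples, samplesFile, row.names = FALSE, quote = FALSE)
    invisible(c(mutationsFile, samplesFile))
}

#' @rdname VAFTable
#' @export
readVAFTable <- function(mutationsFile, samplesFile = NULL,
                         ageBins = NULL) {
    m <- read.csv(mutationsFile)
    s <- if (!is.null(samplesFile)) read.csv(samplesFile) else NULL
    VAFTable(m, s, ageBins)
}

#' Calibration constants
#'
#' The limit of detection of a square section is set by the 108-copy
#' rule: 108 genomic copies over \code{2 * side^2} total copies, i.e.
#' 0.0018 for a full 173 x 173 (2 mm^2) section and 0.011 for a 70 x 70
#' (0.33 mm^2) subsection.
#'
#' @param side section side in cells.
#' @return \code{lodForSide}: the minimum reportable VAF.
#' @export
lodForSide <- function(side) 108 / (2 * side^2)

#' @rdname lodForSide
#' @details \code{calibDefaults} collects the default calibration
#'   settings: section geometries, detection limits, the likelihood
#'   interval half-width \code{epsilon}, and the candidate persistence
#'   values.
#' @export
calibDefaults <- function() {
    list(fullSide = 173L, subSide = 70L,
         lodFull = lodForSide(173), lodSub = lodForSide(70),
         epsilon = 2e-4,
         candidates = c(0, 0.007, 0.01, 0.0125, 0.015))
}

roundHalfUp <- function(x) floor(x + 0.5)

#' Spatial reconstruction of a sequenced tissue section
#'
#' Builds a possible \code{side x side} cellular section consistent with
#' an observed VAF list: mutation \code{i} occupies
#' \code{round(2 * side^2 * f_i)} cells (heterozygous single-copy
#' convention) as a 4-connected patch.  Patches are placed serially in
#' descending frequency, each grown from a uniformly random start by
#' repeatedly mutating a random unmutated neighbour of the current patch.
#' When the cumulative mutant cell count would exceed the section
#' (cumulative VAF reaching 0.5), the overflowing mutation is instead
#' grown inside a previously placed (hence at least as frequent) clone
#' with enough cells not already shared with another nested mutation,
#' producing doubly mutated cells.
#'
#' @param vafs numeric VAFs in (0, 0.5].
#' @param side section side in cells (173 for a 2 mm^2 section).
#' @param growth \code{"frontier"} (default): the next cell is uniform
#'   among the distinct unmutated neighbours of the patch;
#'   \code{"boundary"}: a patch cell with unmutated neighbours is chosen
#'   uniformly, then one of its unmutated neighbours.
#' @param maxRestarts growth restarts allowed when a patch gets walled
#'   in before reaching its target size.
#' @return list of class \code{"reconstructedSection"}: \code{side},
#'   \code{vafs}, \code{targetCells}, \code{cells} (integer site indices
#'   per mutation), \code{nestedIn} (host mutation index or \code{NA}).
#' @export
reconstructSection <- function(vafs, side = 173,
                               growth = c("frontier", "boundary"),
                               maxRestarts = 100) {
    growth <- match.arg(growth)
    if (any(vafs > 0.5) || any(vafs <= 0))
        stop("data error: VAFs must lie in (0, 0.5]")
    ord <- order(vafs, decreasing = TRUE)
    vafs <- vafs[ord]
    N <- side * side
    n <- roundHalfUp(2 * N * vafs)
    if (any(n == 0)) {
        warning("dropping ", sum(n == 0), " mutation(s) rounding to 0 cells")
        keep <- n > 0
        vafs <- vafs[keep]; n <- n[keep]
    }
    k <- length(vafs)
    cells <- vector("list", k)
    nestedIn <- rep(NA_integer_, k)
    occ <- integer(N)        # top-level clone index per site (0 = none)
    nestTag <- integer(N)    # nested mutation index per site (0 = none)
    placedTop <- 0L

    growPatch <- function(allowed, target) {
        # allowed: logical over sites where the patch may grow
        for (try in seq_len(maxRestarts)) {
            avail <- which(allowed)
            patch <- integer(target)
            start <- avail[sample.int(length(avail), 1L)]
            patch[1L] <- start
            free <- allowed
            free[start] <- FALSE
            npat <- 1L
            frontier <- integer(0)
            addFrontier <- function(s, frontier) {
                x <- (s - 1L) %% side; y <- (s - 1L) %/% side
                for (d in 1:4) {
                    xx <- x + c(-1L, 1L, 0L, 0L)[d]
                    yy <- y + c(0L, 0L, -1L, 1L)[d]
                    if (xx < 0L || xx >= side || yy < 0L || yy >= side) next
                    t <- xx + yy * side + 1L
                    if (free[t]) { frontier <- c(frontier, t); free[t] <<- FALSE }
                }
                frontier
            }
            if (growth == "frontier") {
                # frontier holds distinct free neighbours of the patch;
                # 'free' marks sites neither in patch nor frontier
                frontier <- addFrontier(start, frontier)
                while (npat < target && length(frontier)) {
                    j <- sample.int(length(frontier), 1L)
                    s <- frontier[j]
                    frontier <- frontier[-j]
                    npat <- npat + 1L
                    patch[npat] <- s
                    frontier <- addFrontier(s, frontier)
                }
            } else {
                inPatch <- logical(N); inPatch[start] <- TRUE
                freeB <- allowed; freeB[start] <- FALSE
                nbrsOf <- function(s) {
                    x <- (s - 1L) %% side; y <- (s - 1L) %/% side
                    out <- integer(0)
                    if (x > 0L) out <- c(out, s - 1L)
                    if (x < side - 1L) out <- c(out, s + 1L)
                    if (y > 0L) out <- c(out, s - side)
                    if (y < side - 1L) out <- c(out, s + side)
                    out
                }
                while (npat < target) {
                    bcells <- patch[seq_len(npat)]
                    bcells <- bcells[vapply(bcells, function(s)
                        any(freeB[nbrsOf(s)]), logical(1))]
                    if (!length(bcells)) break
                    b <- bcells[sample.int(length(bcells), 1L)]
                    cand <- nbrsOf(b); cand <- cand[freeB[cand]]
                    s <- cand[sample.int(length(cand), 1L)]
                    freeB[s] <- FALSE
                    npat <- npat + 1L
                    patch[npat] <- s
                }
            }
            if (npat == target) return(patch)
        }
        NULL
    }

    topCells <- 0L
    for (i in seq_len(k)) {
        if (topCells + n[i] <= N) {
            patch <- growPatch(occ == 0L, n[i])
            if (is.null(patch))
                stop("reconstruction error: could not grow mutation ", i,
                     " to ", n[i], " cells")
            occ[patch] <- i
            cells[[i]] <- patch
            topCells <- topCells + n[i]
            placedTop <- i
        } else {
            # overflow: nest inside an earlier clone with unshared room
            hosts <- which(!is.na(vapply(seq_len(k), function(j) {
                if (j >= i || !is.na(nestedIn[j])) return(NA_real_)
                room <- sum(occ == j & nestTag == 0L)
                if (room >= n[i]) room else NA_real_
            }, numeric(1))))
            if (!length(hosts))
                stop("reconstruction error: no qualifying host clone for ",
                     "nested mutation ", i)
            host <- hosts[sample.int(length(hosts), 1L)]
            patch <- growPatch(occ == host & nestTag == 0L, n[i])
            if (is.null(patch))
                stop("reconstruction error: could not grow nested mutation ",
                     i, " inside clone ", host)
            nestTag[patch] <- i
            cells[[i]] <- patch
            nestedIn[i] <- host
        }
    }
    structure(list(side = side, vafs = vafs, targetCells = n,
                   cells = cells, nestedIn = nestedIn),
              class = "reconstructedSection")
}

#' Downsample a reconstructed section
#'
#' Samples a square \code{subSide x subSide} window, uniformly over all
#' fully contained placements, and reports the mutations detected in it:
#' each mutation's window VAF is its cell count in the window over
#' \code{2 * subSide^2}; mutations below the window's detection limit are
#' dropped.
#'
#' @param recon a \code{"reconstructedSection"}.
#' @param subSide window side in cells.
#' @param lod detection limit applied to window VAFs (default: the
#'   108-copy rule for \code{subSide}).
#' @return list: \code{count} (detected mutations) and \code{vafs}.
#' @export
downsampleSection <- function(recon, subSide = 70, lod = lodForSide(subSide)) {
    side <- recon$side
    if (subSide > side) stop("subSide must not exceed the section side")
    x0 <- sample.int(side - subSide + 1L, 1L) - 1L
    y0 <- sample.int(side - subSide + 1L, 1L) - 1L
    inWin <- function(s) {
        x <- (s - 1L) %% side; y <- (s - 1L) %/% side
        x >= x0 & x < x0 + subSide & y >= y0 & y < y0 + subSide
    }
    vafs <- vapply(recon$cells, function(cs) sum(inWin(cs)), numeric(1)) /
        (2 * subSide^2)
    keep <- vafs >= lod
    list(count = sum(keep), vafs = vafs[keep])
}

#' Mean-squared error of mutation counts across age bins
#'
#' For each candidate persistence value, the squared difference between
#' the simulated and empirical mean mutation count is averaged over the
#' included age bins.
#'
#' @param simMeans matrix of simulated mean counts, rows named by
#'   candidate persistence, columns by age bin.
#' @param empMeans named vector of empirical mean counts per age bin.
#' @param excludeBins age bins to drop (e.g. a known outlier donor bin).
#' @return list: \code{mse} (named per candidate) and \code{best} (the
#'   argmin candidate, numeric).
#' @export
countMSE <- function(simMeans, empMeans, excludeBins = character(0)) {
    bins <- intersect(colnames(simMeans), names(empMeans))
    bins <- setdiff(bins, excludeBins)
    if (!length(bins)) stop("data error: no overlapping age bins")
    mse <- apply(simMeans[, bins, drop = FALSE], 1, function(s)
        mean((s - empMeans[bins])^2))
    list(mse = mse, best = as.numeric(names(which.min(mse))))
}

#' Exponential fit to recentred VAFs
#'
#' Maximum-likelihood exponential fit to VAFs recentred by the detection
#' limit (\code{x = vaf - lod}), via \code{fitdistrplus::fitdist}; the
#' MLE rate equals \code{1/mean(x)}.
#'
#' @param vafs VAFs, all at or above \code{lod}.
#' @param lod detection limit used for recentring.
#' @return list of class \code{"expFit"}: \code{lambda}, \code{n},
#'   \code{lod}.
#' @export
fitExponential <- function(vafs, lod = 0.011) {
    if (length(vafs) < 2) stop("fit error: need at least 2 VAFs")
    if (any(vafs < lod - 1e-12)) stop("all VAFs must be >= lod")
    x <- pmax(vafs - lod, 0)
    if (mean(x) <= 0) stop("fit error: degenerate data (all VAFs at lod)")
    fit <- fitdistrplus::fitdist(x, "exp", method = "mle")
    structure(list(lambda = unname(fit$estimate["rate"]), n = length(x),
                   lod = lod),
              class = "expFit")
}

#' Interval log-likelihood of an observed VAF
#'
#' Probability that an interval of half-width \code{eps} around the
#' recentred observation \code{f - lod} is drawn from an
#' Exponential(\code{lambda}):
#' \deqn{p(f \mid \lambda) = \int_{f'-\epsilon}^{f'+\epsilon}
#'       \lambda e^{-\lambda x}\,dx}
#' with the lower limit clamped at 0 near the detection boundary.
#' Vectorised over \code{f}; returns log probabilities.
#'
#' @param f observed VAF(s), at or above \code{lod}.
#' @param lambda exponential rate.
#' @param eps interval half-width (default 2e-4).
#' @param lod detection limit used for recentring.
#' @return log probabilities.
#' @export
intervalLoglik <- function(f, lambda, eps = 2e-4, lod = 0.011) {
    if (eps <= 0) stop("eps must be positive")
    fp <- f - lod
    if (any(fp < -1e-12)) stop("observed VAFs must be >= lod")
    lower <- pmax(fp - eps, 0)
    upper <- fp + eps
    log(exp(-lambda * lower) - exp(-lambda * upper))
}

#' Select the TP53 persistence coefficient
#'
#' Given simulated VAF-table ensembles for a set of candidate persistence
#' values and an empirical (downsampled) table, selects the candidate by
#' two criteria: (i) minimum mean-squared error of the per-age-bin mean
#' mutation counts, and (ii) minimum summed negative interval
#' log-likelihood of the empirical VAFs under per-bin exponential fits to
#' the simulated VAFs.  The likelihood criterion skips candidate 0
#' (too few simulated mutations to fit a size distribution).
#'
#' @param simEnsembles named list (names = candidate persistence values)
#'   of simulated \code{\link{VAFTable}}s.
#' @param empTable empirical \code{\link{VAFTable}}.
#' @param lod detection limit used throughout.
#' @param eps interval half-width for the likelihood.
#' @param excludeCountBins age bins dropped from the count MSE.
#' @param excludeVAFBins age bins dropped from the likelihood.
#' @return list: \code{bestPMSE}, \code{bestPNLL}, \code{mse},
#'   \code{nll}, \code{lambdaTable} (per candidate and bin), and
#'   \code{countTable}.
#' @export
selectPersistence <- function(simEnsembles, empTable, lod = 0.011,
                              eps = 2e-4,
                              excludeCountBins = character(0),
                              excludeVAFBins = character(0)) {
    if (is.null(names(simEnsembles)) || any(names(simEnsembles) == ""))
        stop("selection error: simEnsembles must be named by candidate value")
    cands <- names(simEnsembles)
    bins <- empTable@ageBins

    meanCounts <- function(tab) {
        s <- tab@samples
        m <- tab@mutations
        cnt <- table(factor(m$sample_id, levels = s$sample_id))
        vapply(bins, function(b)
            mean(cnt[s$age_bin == b]), numeric(1))
    }
    simMeans <- do.call(rbind, lapply(simEnsembles, meanCounts))
    colnames(simMeans) <- bins
    empMeans <- meanCounts(empTable)
    cm <- countMSE(simMeans, empMeans, excludeBins = excludeCountBins)

    nllBins <- setdiff(bins, excludeVAFBins)
    # likelihoods are only comparable across candidates when summed over
    # the same age bins, so restrict to bins every non-zero candidate can
    # fit (>= 2 simulated VAFs)
    nzCands <- cands[vapply(cands, function(p) as.numeric(p) > 0, logical(1))]
    simVAFs <- function(p, b) {
        m <- simEnsembles[[p]]@mutations
        m$vaf[as.character(m$age_bin) == b]
    }
    fittable <- vapply(nllBins, function(b)
        all(vapply(nzCands, function(p) length(simVAFs(p, b)) >= 2,
                   logical(1))), logical(1))
    if (any(!fittable) && length(nllBins))
        message("dropping age bin(s) from the likelihood: ",
                paste(nllBins[!fittable], collapse = ", "))
    nllBins <- nllBins[fittable]
    lamRows <- list()
    nll <- setNames(rep(NA_real_, length(cands)), cands)
    for (p in nzCands) {
        tot <- 0
        for (b in nllBins) {
            fit <- fitExponential(simVAFs(p, b), lod = lod)
            lamRows[[length(lamRows) + 1L]] <-
                data.frame(candidate = as.numeric(p), age_bin = b,
                           lambda = fit$lambda, n = fit$n)
            ev <- empTable@mutations$vaf[
                as.character(empTable@mutations$age_bin) == b]
            if (length(ev))
                tot <- tot + sum(intervalLoglik(ev, fit$lambda,
                                                eps = eps, lod = lod))
        }
        nll[p] <- if (length(nllBins)) -tot else NA_real_
    }
    bestPNLL <- if (all(is.na(nll))) NA_real_ else
        as.numeric(names(which.min(nll)))
    list(bestPMSE = cm$best, bestPNLL = bestPNLL, mse = cm$mse, nll = nll,
         lambdaTable = if (length(lamRows)) do.call(rbind, lamRows) else
             data.frame(candidate = numeric(0), age_bin = character(0),
                        lambda = numeric(0), n = integer(0)),
         countTable = list(sim = simMeans, emp = empMeans))
}

#' Simulated VAF-table ensemble for calibration
#'
#' Runs replicate uncorrected tissue simulations (condition 1: no gene
#' correction, equal rates) with a given TP53 persistence value and
#' extracts, at each requested age, the detectable mutation VAF list
#' (cells carrying each mutation event over \code{2 * gridSide^2},
#' thresholded at the section's detection limit).  Each replicate
#' contributes one sample per age bin.
#'
#' @param p candidate TP53 persistence value.
#' @param ages named numeric vector: age-bin label -> evaluation age in
#'   years.
#' @param reps replicate tissues.
#' @param gridSide section side in cells.
#' @param mutParams a \code{\link{MutationParams}}.
#' @param lod detection limit (default: 108-copy rule for
#'   \code{gridSide}).
#' @param simParams,seed,optimize as in \code{\link{runFateExperiment}}.
#' @return A \code{\link{VAFTable}}.
#' @export
simulateVAFEnsemble <- function(p, ages, reps = 100, gridSide = 70,
                                mutParams = MutationParams(),
                                lod = lodForSide(gridSide),
                                simParams = SimParams(), seed = NULL,
                                optimize = TRUE) {
    stopifnot(!is.null(names(ages)), all(ages >= 0))
    ages <- ages[order(ages)]
    gp <- GenotypeParams(pCorr = 0, pPlusTP53 = p, ratioR = 1)
    N2 <- 2 * gridSide^2
    mrows <- list()
    srows <- list()
    for (i in seq_len(reps)) {
        if (!is.null(seed)) set.seed(seed + i)
        g <- BasalGrid(gridSide, gridSide)
        tPrev <- 0
        for (b in seq_along(ages)) {
            tr <- advanceGrid(g, years = ages[b] - tPrev,
                              simParams = simParams, genoParams = gp,
                              mutParams = mutParams, checkLoss = FALSE,
                              confluenceFraction = NA,
                              optimize = optimize, startYears = tPrev)
            g <- finalGrid(tr)
            tPrev <- ages[b]
            vafs <- gridEventCounts(g) / N2
            vafs <- vafs[vafs >= lod]
            sid <- sprintf("sim_p%s_rep%03d_%s", format(p), i,
                           names(ages)[b])
            srows[[length(srows) + 1L]] <-
                data.frame(sample_id = sid, age_bin = names(ages)[b],
                           has_mutations = length(vafs) > 0)
            if (length(vafs))
                mrows[[length(mrows) + 1L]] <-
                    data.frame(sample_id = sid, age_bin = names(ages)[b],
                               vaf = unname(vafs))
        }
    }
    muts <- if (length(mrows)) do.call(rbind, mrows) else
        data.frame(sample_id = character(0), age_bin = character(0),
                   vaf = numeric(0))
    VAFTable(muts, do.call(rbind, srows), ageBins = names(ages))
}
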