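#' The basal-layer lattice
#'
#' A \code{BasalGrid} is a fully occupied \code{width} x \code{height}
#' lattice of cell records, the competitive arena of the model.  Each site
#' carries: a corrected flag (FANC function restored), a clone label
#' (0 = uncorrected host background; corrected founders get fresh labels),
#' an optional needle-of-origin label, and a mutation profile — the set of
#' independent TP53 mutation-event ids the cell carries.  The population is
#' constant: displaced cells leave the basal layer permanently and are
#' replaced by the displacing daughter.
#'
#' Sites are addressed by 0-based coordinates: cell \code{(x, y)} occupies
#' the unit square \code{[x, x+1) x [y, y+1)}, with
#' \code{x in 0..width-1}, \code{y in 0..height-1}.
#'
#' @param width,height lattice dimensions in cells (both >= 3).
#' @param boundaryMode \code{"periodic"} (default; preserves neutrality
#'   symmetry) or \code{"reflecting"}.
#' @return A \code{BasalGrid} with every site an uncorrected,
#'   TP53-wildtype host cell.
#' @examples
#' g <- BasalGrid(10, 10)
#' correctedFraction(g)   # 0
#' neighborSites(g, c(0, 0))
#' @export
BasalGrid <- function(width, height = width, boundaryMode = c("periodic", "reflecting")) {
    boundaryMode <- match.arg(boundaryMode)
    width <- as.integer(width); height <- as.integer(height)
    z <- matrix(0L, nrow = width, ncol = height)
    new("BasalGrid", width = width, height = height, corrected = z,
        cloneId = z, needleId = z, profileId = z, profiles = list(),
        boundaryMode = boundaryMode, nextCloneId = 1L, nextEventId = 1L)
}

#' @rdname BasalGrid
#' @include AllGenerics.R params.R
#' @export
setClass("BasalGrid",
    representation(width = "integer", height = "integer",
                   corrected = "matrix", cloneId = "matrix",
                   needleId = "matrix", profileId = "matrix",
                   profiles = "list", boundaryMode = "character",
                   nextCloneId = "integer", nextEventId = "integer"),
    validity = function(object) {
        msg <- NULL
        if (object@width < 3L || object@height < 3L)
            msg <- c(msg, "width and height must both be >= 3")
        dims <- c(object@width, object@height)
        for (sl in c("corrected", "cloneId", "needleId", "profileId")) {
            m <- slot(object, sl)
            if (!all(dim(m) == dims))
                msg <- c(msg, sprintf("slot '%s' must be %d x %d", sl, dims[1], dims[2]))
        }
        if (!object@boundaryMode %in% c("periodic", "reflecting"))
            msg <- c(msg, "boundaryMode must be 'periodic' or 'reflecting'")
        if (any(object@profileId < 0) ||
            any(object@profileId > length(object@profiles)))
            msg <- c(msg, "profileId values must index into profiles (or be 0)")
        if (any(!object@corrected %in% c(0L, 1L)))
            msg <- c(msg, "corrected must be 0/1")
        if (is.null(msg)) TRUE else msg
    })

setMethod("show", "BasalGrid", function(object) {
    cat(sprintf("BasalGrid %d x %d (%s), N = %d cells\n", object@width,
                object@height, object@boundaryMode,
                object@width * object@height))
    cat(sprintf("  corrected: %.4f  TP53-mutant: %.4f  mutation events: %d\n",
                correctedFraction(object), tp53Fraction(object),
                object@nextEventId - 1L))
})

#' @rdname BasalGrid
#' @param x a \code{BasalGrid}.
#' @aliases dim,BasalGrid-method
#' @export
setMethod("dim", "BasalGrid", function(x) c(x@width, x@height))

#' @describeIn BasalGrid fraction of basal sites occupied by corrected
#'   cells.
#' @export
setMethod("correctedFraction", "BasalGrid", function(x)
    sum(x@corrected) / (x@width * x@height))

#' @describeIn BasalGrid fraction of basal sites carrying at least one
#'   inactivating TP53 mutation.
#' @export
setMethod("tp53Fraction", "BasalGrid", function(x)
    sum(x@profileId > 0L) / (x@width * x@height))

#' @describeIn BasalGrid integer matrix of TP53 hit counts per site.
#' @export
setMethod("tp53Hits", "BasalGrid", function(x) {
    nh <- c(0L, vapply(x@profiles, length, integer(1)))
    matrix(nh[x@profileId + 1L], nrow = x@width, ncol = x@height)
})

#' @describeIn BasalGrid boundary mode of the lattice.
#' @export
setMethod("boundaryMode", "BasalGrid", function(x) x@boundaryMode)

#' @describeIn BasalGrid one row per site: \code{x}, \code{y},
#'   \code{fanc_corrected}, \code{tp53_hits}, \code{clone_id},
#'   \code{needle_id}, plus \code{mutation_event_ids}
#'   (semicolon-separated) so clone statistics can be re-derived from an
#'   export bit-exactly.
#' @export
setMethod("cellRecords", "BasalGrid", function(x) {
    hits <- tp53Hits(x)
    evs <- character(length(x@profileId))
    pid <- as.vector(x@profileId)
    nz <- pid > 0L
    evs[nz] <- vapply(pid[nz], function(p)
        paste(x@profiles[[p]], collapse = ";"), character(1))
    data.frame(
        x = rep(0:(x@width - 1L), times = x@height),
        y = rep(0:(x@height - 1L), each = x@width),
        fanc_corrected = as.vector(x@corrected) == 1L,
        tp53_hits = as.vector(hits),
        clone_id = as.vector(x@cloneId),
        needle_id = as.vector(x@needleId),
        mutation_event_ids = evs)
})

#' Orthogonal neighbours of a lattice site
#'
#' Returns the Von Neumann (4-)neighbourhood of \code{site} under the
#' grid's boundary mode.  Periodic boundaries always yield 4 neighbours;
#' reflecting boundaries yield 2 (corner), 3 (edge) or 4 (interior).
#'
#' @param grid a \code{BasalGrid}.
#' @param site integer vector \code{c(x, y)}, 0-based.
#' @return An n x 2 integer matrix of neighbour coordinates.
#' @export
neighborSites <- function(grid, site) {
    stopifnot(is(grid, "BasalGrid"), length(site) == 2)
    x <- as.integer(site[1]); y <- as.integer(site[2])
    if (x < 0L || x >= grid@width || y < 0L || y >= grid@height)
        stop("site out of bounds")
    cand <- rbind(c(x - 1L, y), c(x + 1L, y), c(x, y - 1L), c(x, y + 1L))
    if (grid@boundaryMode == "periodic") {
        cand[, 1] <- cand[, 1] %% grid@width
        cand[, 2] <- cand[, 2] %% grid@height
    } else {
        keep <- cand[, 1] >= 0L & cand[, 1] < grid@width &
                cand[, 2] >= 0L & cand[, 2] < grid@height
        cand <- cand[keep, , drop = FALSE]
    }
    colnames(cand) <- c("x", "y")
    cand
}

#' Export a grid snapshot
#'
#' \code{writeGridCSV} writes one row per site (columns \code{x, y,
#' fanc_corrected, tp53_hits, clone_id, needle_id}); \code{readGridCSV}
#' rebuilds a \code{BasalGrid} from such a file.  \code{writeGridPNG}
#' writes a raster coloured by genotype class: host grey, host TP53-mutant
#' magenta, corrected green, corrected TP53-mutant cyan.
#'
#' @param grid a \code{BasalGrid}.
#' @param file output path.
#' @return \code{writeGridCSV}/\code{writeGridPNG} return \code{file}
#'   invisibly; \code{readGridCSV} returns a \code{BasalGrid}.
#' @export
writeGridCSV <- function(grid, file) {
    write.csv(cellRecords(grid), file, row.names = FALSE, quote = FALSE)
    invisible(file)
}

#' @rdname writeGridCSV
#' @param boundaryMode boundary mode for the rebuilt grid.
#' @export
readGridCSV <- function(file, boundaryMode = "periodic") {
    df <- read.csv(file)
    needed <- c("x", "y", "fanc_corrected", "tp53_hits", "clone_id", "needle_id")
    if (!all(needed %in% names(df)))
        stop("grid CSV must have columns: ", paste(needed, collapse = ", "))
    w <- max(df$x) + 1L; h <- max(df$y) + 1L
    g <- BasalGrid(w, h, boundaryMode)
    idx <- cbind(df$x + 1L, df$y + 1L)
    g@corrected[idx] <- as.integer(df$fanc_corrected)
    g@cloneId[idx] <- as.integer(df$clone_id)
    g@needleId[idx] <- as.integer(df$needle_id)
    pid <- integer(nrow(df))
    profiles <- list()
    nextEv <- 1L
    if ("mutation_event_ids" %in% names(df)) {
        # event identities preserved: cells sharing a mutation event keep
        # sharing it after the round trip
        evs <- as.character(df$mutation_event_ids)
        evs[is.na(evs)] <- ""
        seenProf <- new.env()
        for (i in which(nzchar(evs))) {
            key <- evs[i]
            if (is.null(seenProf[[key]])) {
                profiles[[length(profiles) + 1L]] <-
                    as.integer(strsplit(key, ";", fixed = TRUE)[[1]])
                seenProf[[key]] <- length(profiles)
            }
            pid[i] <- seenProf[[key]]
        }
        if (length(profiles)) nextEv <- max(unlist(profiles)) + 1L
    } else {
        # hit multiplicity only: each mutant cell gets a fresh profile of
        # synthetic event ids
        hcounts <- as.integer(df$tp53_hits)
        for (i in which(hcounts > 0L)) {
            profiles[[length(profiles) + 1L]] <-
                seq.int(nextEv, length.out = hcounts[i])
            nextEv <- nextEv + hcounts[i]
            pid[i] <- length(profiles)
        }
    }
    g@profileId[idx] <- pid
    g@profiles <- profiles
    g@nextEventId <- nextEv
    g@nextCloneId <- max(1L, max(g@cloneId) + 1L)
    validObject(g)
    g
}

#' @rdname writeGridCSV
#' @export
writeGridPNG <- function(grid, file) {
    corr <- grid@corrected == 1L
    mut <- grid@profileId > 0L
    # genotype palette: host grey, host TP53- magenta, corrected green,
    # corrected TP53- cyan
    cols <- c("#BFBFBF", "#C542F5", "#2CA02C", "#17BECF")
    cls <- 1L + mut + 2L * corr
    rgbmat <- grDevices::col2rgb(cols) / 255
    img <- array(0, dim = c(grid@height, grid@width, 3))
    for (ch in 1:3)
        img[, , ch] <- t(matrix(rgbmat[ch, cls], nrow = grid@width))[grid@height:1, , drop = FALSE]
    png::writePNG(img, target = file)
    invisible(file)
}
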