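#' Microneedle delivery plans
#'
#' A \code{DeliveryPlan} is a list of injection sites applied at
#' \code{deliveryTime}.  Each site corrects \code{k} cells sampled without
#' replacement from a bivariate Gaussian footprint of variance \code{D}
#' (cell-length^2 units) centred on the continuous lattice coordinates
#' \code{(x, y)} — the simulated spread of transgene away from a
#' microneedle tip.
#'
#' @param x,y continuous injection coordinates in cell units (the tissue
#'   centre of a \code{w x h} grid is \code{(w/2, h/2)}).
#' @param k number of cells corrected per site.
#' @param D isotropic Gaussian variance per site.
#' @param deliveryTime years at which the plan is applied.
#' @return A \code{DeliveryPlan}.
#' @examples
#' centralDelivery(100, 100, k = 10, D = 2)
#' @export
DeliveryPlan <- function(x, y, k, D, deliveryTime = 0) {
    sites <- data.frame(x = as.numeric(x), y = as.numeric(y),
                        k = as.integer(k), D = as.numeric(D))
    new("DeliveryPlan", sites = sites, deliveryTime = deliveryTime)
}

#' @rdname DeliveryPlan
#' @include grid.R AllGenerics.R
#' @export
setClass("DeliveryPlan",
    representation(sites = "data.frame", deliveryTime = "numeric"),
    validity = function(object) {
        msg <- NULL
        s <- object@sites
        if (nrow(s) == 0) msg <- c(msg, "sites must be non-empty")
        if (!all(c("x", "y", "k", "D") %in% names(s)))
            msg <- c(msg, "sites needs columns x, y, k, D")
        else {
            if (any(s$D <= 0)) msg <- c(msg, "D must be positive")
            if (any(s$k < 1)) msg <- c(msg, "k must be >= 1")
        }
        if (is.null(msg)) TRUE else msg
    })

setMethod("show", "DeliveryPlan", function(object) {
    cat(sprintf("DeliveryPlan: %d site(s), total k = %d, at t = %g y\n",
                nrow(object@sites), sum(object@sites$k),
                object@deliveryTime))
})

#' @rdname DeliveryPlan
#' @param width,height grid dimensions; the single site is placed at the
#'   tissue centre.
#' @details \code{centralDelivery} builds the single-needle plan used
#'   throughout the fate experiments: one site at the tissue centre.
#' @export
centralDelivery <- function(width, height = width, k = 10, D = 2,
                            deliveryTime = 0) {
    DeliveryPlan(width / 2, height / 2, k = k, D = D,
                 deliveryTime = deliveryTime)
}

#' Gaussian per-cell correction weights
#'
#' Integrates the bivariate Gaussian transgene footprint over each cell's
#' unit square: cell \code{(i, j)} (0-based, occupying
#' \code{[i, i+1) x [j, j+1)}) receives weight
#' \deqn{[\Phi((i+1-x)/\sqrt D) - \Phi((i-x)/\sqrt D)] \cdot
#'       [\Phi((j+1-y)/\sqrt D) - \Phi((j-y)/\sqrt D)]}
#' Gaussian mass falling outside the grid is ignored; with
#' \code{normalize = TRUE} (the default) weights are renormalised to sum
#' to 1 over the grid before sampling.
#'
#' @param width,height grid dimensions in cells.
#' @param x,y injection coordinates (continuous, cell units).
#' @param D Gaussian variance (> 0).
#' @param normalize renormalise over the finite grid.
#' @return \code{width x height} matrix of weights.
#' @export
gaussianCellWeights <- function(width, height, x, y, D,
                                normalize = TRUE) {
    if (D <= 0) stop("D must be positive")
    sdv <- sqrt(D)
    wx <- diff(pnorm((0:width - x) / sdv))
    wy <- diff(pnorm((0:height - y) / sdv))
    w <- outer(wx, wy)
    if (normalize) {
        tot <- sum(w)
        if (tot <= 0) stop("weight mass on the grid is zero")
        w <- w / tot
    }
    w
}

#' Weighted sampling of cells without replacement
#'
#' Draws \code{k} distinct cells sequentially, each proportional to the
#' remaining weights (successive weighted sampling without replacement).
#'
#' @param weights non-negative weight matrix or vector.
#' @param k number of draws; must not exceed the number of
#'   positive-weight cells.
#' @return integer vector of \code{k} distinct (1-based) cell indices
#'   into \code{weights}.
#' @export
sampleCorrectedCells <- function(weights, k) {
    w <- as.vector(weights)
    npos <- sum(w > 0)
    if (k > npos)
        stop("delivery error: k exceeds the number of positive-weight cells")
    sample.int(length(w), size = k, replace = FALSE, prob = w)
}

#' @describeIn DeliveryPlan apply a plan to a grid: per site (in order),
#'   the Gaussian weights are computed, cells already corrected are
#'   excluded, and \code{k} cells are sampled without replacement and
#'   corrected.  Each newly corrected cell gets a fresh clone label and
#'   the site's needle label; existing TP53 hits are retained, and
#'   re-correcting a corrected cell is impossible by construction (the
#'   exclusion guarantees the advertised total dose).
#' @param grid a \code{\link{BasalGrid}}.
#' @param plan a \code{DeliveryPlan}.
#' @param ... unused.
#' @export
setMethod("applyCorrection", signature(grid = "BasalGrid", plan = "DeliveryPlan"),
    function(grid, plan, ...) {
        validObject(plan)
        s <- plan@sites
        if (any(s$x < 0 | s$x > grid@width | s$y < 0 | s$y > grid@height))
            stop("injection site outside grid bounds")
        if (sum(s$k) > grid@width * grid@height)
            stop("total k exceeds grid size")
        for (i in seq_len(nrow(s))) {
            w <- gaussianCellWeights(grid@width, grid@height,
                                     s$x[i], s$y[i], s$D[i],
                                     normalize = FALSE)
            w[grid@corrected == 1L] <- 0
            tot <- sum(w)
            if (tot <= 0) stop("no uncorrected cells available for site ", i)
            idx <- sampleCorrectedCells(w / tot, s$k[i])
            grid@corrected[idx] <- 1L
            grid@cloneId[idx] <- seq.int(grid@nextCloneId,
                                         length.out = length(idx))
            grid@nextCloneId <- grid@nextCloneId + length(idx)
            grid@needleId[idx] <- i
        }
        grid
    })

#' Microneedle array geometry
#'
#' A rectangular \code{rows x cols} array of identical microneedles on a
#' square spacing, centred at \code{center}.  Physical spacing in microns
#' is converted to cell units using the basal cell side length
#' \code{1000 / sqrt(cellDensity)} um (about 8.165 um at 15,000 cells per
#' mm^2); continuous coordinates are retained without rounding.
#'
#' @param rows,cols array dimensions.
#' @param spacingUm inter-needle spacing in microns.
#' @param kPerNeedle cells corrected per needle.
#' @param D Gaussian variance per needle.
#' @param center array centre \code{c(x, y)} in cell units.
#' @return An \code{ArraySpec}.
#' @examples
#' spec <- ArraySpec(4, 4, spacingUm = 700, kPerNeedle = 30, D = 2,
#'                   center = c(200, 200))
#' arraySites(spec)
#' @export
ArraySpec <- function(rows, cols = rows, spacingUm, kPerNeedle = 30,
                      D = 2, center) {
    new("ArraySpec", rows = as.integer(rows), cols = as.integer(cols),
        spacingUm = spacingUm, kPerNeedle = as.integer(kPerNeedle),
        D = D, center = as.numeric(center))
}

#' @rdname ArraySpec
#' @export
setClass("ArraySpec",
    representation(rows = "integer", cols = "integer",
                   spacingUm = "numeric", kPerNeedle = "integer",
                   D = "numeric", center = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (object@rows < 1L || object@cols < 1L)
            msg <- c(msg, "rows and cols must be >= 1")
        if (object@spacingUm <= 0) msg <- c(msg, "spacingUm must be positive")
        if (object@kPerNeedle < 1L) msg <- c(msg, "kPerNeedle must be >= 1")
        if (object@D <= 0) msg <- c(msg, "D must be positive")
        if (length(object@center) != 2)
            msg <- c(msg, "center must be c(x, y)")
        if (is.null(msg)) TRUE else msg
    })

#' @rdname ArraySpec
#' @param spec an \code{ArraySpec}.
#' @param cellDensity basal cells per mm^2 (sets the um-to-cell
#'   conversion).
#' @param gridDims optional \code{c(width, height)}; if supplied, an
#'   array extending beyond the grid is a geometry error.
#' @return \code{arraySites} returns a \code{\link{DeliveryPlan}} with
#'   one site per needle (row-major order).
#' @export
arraySites <- function(spec, cellDensity = 15000, gridDims = NULL) {
    stopifnot(is(spec, "ArraySpec"))
    validObject(spec)
    cellSideUm <- 1000 / sqrt(cellDensity)
    sp <- spec@spacingUm / cellSideUm
    xs <- spec@center[1] + (seq_len(spec@cols) - (spec@cols + 1) / 2) * sp
    ys <- spec@center[2] + (seq_len(spec@rows) - (spec@rows + 1) / 2) * sp
    g <- expand.grid(x = xs, y = ys)
    if (!is.null(gridDims)) {
        if (any(g$x < 0 | g$x > gridDims[1] | g$y < 0 | g$y > gridDims[2]))
            stop("geometry error: array exceeds grid bounds")
    }
    DeliveryPlan(g$x, g$y, k = spec@kPerNeedle, D = spec@D)
}

#' @rdname ArraySpec
#' @param backingMm2 backing patch area in mm^2; needles are evenly
#'   spaced on a square of side \code{sqrt(backingMm2)} mm so that an
#'   \code{n x n} array spans the backing edge-to-edge
#'   (spacing \code{side/(n-1)}).
#' @param rowsCols array dimension \code{n} for an \code{n x n} array
#'   (n >= 2).
#' @details \code{arrayOnBacking} builds the fixed-backing density
#'   variants (for example 2x2, 4x4, 8x8 needles on 4.43 mm^2).
#' @export
arrayOnBacking <- function(rowsCols, backingMm2 = 4.43, kPerNeedle = 30,
                           D = 2, center, cellDensity = 15000) {
    if (rowsCols < 2) stop("arrayOnBacking needs at least a 2x2 array")
    sideUm <- sqrt(backingMm2) * 1000
    ArraySpec(rowsCols, rowsCols, spacingUm = sideUm / (rowsCols - 1),
              kPerNeedle = kPerNeedle, D = D, center = center)
}
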