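test_that("Gaussian cell weights integrate the footprint over unit cells", {
    # near-degenerate variance concentrates all mass in the containing cell
    w <- gaussianCellWeights(9, 9, 3.5, 4.5, D = 1e-6)
    expect_equal(w[4, 5], 1, tolerance = 1e-9)
    expect_lt(max(w[-(4 + 4 * 9)]), 1e-9)
    # a site on a cell-corner junction spreads equally over the 4 cells
    w4 <- gaussianCellWeights(10, 10, 5, 5, D = 3, normalize = FALSE)
    expect_equal(w4[5, 5], w4[6, 6])
    expect_equal(w4[5, 6], w4[6, 5])
    expect_equal(w4[5, 5], w4[6, 5])
    expect_error(gaussianCellWeights(5, 5, 2, 2, D = 0), "positive")
})

test_that("raw weight mass grows toward 1 with grid size; quadrature oracle agrees", {
    raw <- function(n) sum(gaussianCellWeights(n, n, n / 2, n / 2, D = 4,
                                               normalize = FALSE))
    expect_lt(raw(6), 1)
    expect_lt(raw(6), raw(12))
    expect_gt(raw(30), 1 - 1e-8)
    expect_equal(sum(gaussianCellWeights(7, 7, 3.2, 3.2, D = 2)), 1)
    # independent numerical quadrature of the bivariate normal density
    x0 <- 3.7; y0 <- 2.2; D <- 2.5
    w <- gaussianCellWeights(8, 8, x0, y0, D, normalize = FALSE)
    for (cell in list(c(3, 2), c(4, 3), c(1, 6))) {
        i <- cell[1]; j <- cell[2]
        fx <- integrate(function(x) dnorm(x, x0, sqrt(D)), i, i + 1)$value
        fy <- integrate(function(y) dnorm(y, y0, sqrt(D)), j, j + 1)$value
        expect_equal(w[i + 1, j + 1], fx * fy, tolerance = 1e-6)
    }
})

test_that("weighted sampling without replacement matches a sequential oracle", {
    # exhaustive cases
    w <- matrix(0, 5, 5); w[1:10] <- 1
    expect_setequal(sampleCorrectedCells(w, 10), 1:10)
    expect_setequal(sampleCorrectedCells(matrix(1, 4, 4), 16), 1:16)
    expect_error(sampleCorrectedCells(w, 11), "delivery error")
    # inclusion frequency of the modal cell vs a hand-rolled sequential
    # sampler on a 4x4 grid
    set.seed(11)
    wts <- gaussianCellWeights(4, 4, 1.3, 2.1, D = 1.5)
    modal <- which.max(wts)
    k <- 3; n <- 20000
    oracleDraw <- function() {
        rem <- as.vector(wts); out <- integer(k)
        for (i in seq_len(k)) {
            u <- runif(1) * sum(rem)
            s <- findInterval(u, cumsum(rem)) + 1L
            out[i] <- s; rem[s] <- 0
        }
        out
    }
    hitsOracle <- mean(replicate(n, modal %in% oracleDraw()))
    hitsImpl <- mean(replicate(n, modal %in% sampleCorrectedCells(wts, k)))
    se <- sqrt(hitsOracle * (1 - hitsOracle) * 2 / n)
    expect_lt(abs(hitsImpl - hitsOracle), 4 * se)
})

test_that("applying a delivery plan corrects exactly the advertised dose", {
    set.seed(3)
    g <- BasalGrid(100, 100)
    g <- applyCorrection(g, centralDelivery(100, 100, k = 10, D = 2))
    expect_equal(correctedFraction(g), 10 / 1e4)
    expect_equal(sort(unique(g@cloneId[g@corrected == 1L])), 1:10)
    # two distant sites keep distinct needle labels, no double counting
    g2 <- BasalGrid(60, 60)
    plan <- DeliveryPlan(x = c(12, 48), y = c(12, 48), k = c(30, 30),
                         D = c(0.5, 0.5))
    g2 <- applyCorrection(g2, plan)
    expect_equal(sum(g2@corrected), 60)
    expect_setequal(unique(g2@needleId[g2@corrected == 1L]), c(1L, 2L))
    expect_equal(length(unique(g2@cloneId[g2@corrected == 1L])), 60)
    # overlapping sites still deliver the exact total dose (cross-site
    # exclusion), and re-correction cannot strip TP53 hits
    g3 <- BasalGrid(10, 10)
    g3@profiles <- list(1L); g3@profileId[5, 5] <- 1L; g3@nextEventId <- 2L
    plan3 <- DeliveryPlan(x = c(5, 5), y = c(5, 5), k = c(40, 40),
                          D = c(1, 1))
    g3 <- applyCorrection(g3, plan3)
    expect_equal(sum(g3@corrected), 80)
    expect_equal(tp53Hits(g3)[5, 5], 1L)
    expect_error(applyCorrection(BasalGrid(5, 5),
                                 DeliveryPlan(2, 2, k = 26, D = 1)),
                 "exceeds grid size")
    expect_error(applyCorrection(BasalGrid(5, 5),
                                 DeliveryPlan(9, 2, k = 2, D = 1)),
                 "outside grid")
})

test_that("weight field respects grid symmetries fixing the site", {
    w <- gaussianCellWeights(9, 9, 4.5, 4.5, D = 4)
    expect_equal(w, w[9:1, ])          # reflection in x
    expect_equal(w, w[, 9:1])          # reflection in y
    expect_equal(w, t(w))              # diagonal (x/y swap)
})

test_that("greater diffusion spreads sampled cells further apart", {
    set.seed(21)
    meanDist <- function(D) {
        d <- replicate(150, {
            idx <- sampleCorrectedCells(
                gaussianCellWeights(100, 100, 50, 50, D), 10)
        x <- (idx - 1) %% 100; y <- (idx - 1) %/% 100
            mean(dist(cbind(x, y)))
        })
        mean(d)
    }
    m <- vapply(c(2, 10, 20), meanDist, numeric(1))
    expect_lt(m[1], m[2])
    expect_lt(m[2], m[3])
})

test_that("array geometry converts microns to cell units at the basal density", {
    s1 <- ArraySpec(1, 1, spacingUm = 175, kPerNeedle = 5, D = 2,
                    center = c(50, 50))
    p1 <- arraySites(s1)
    expect_equal(nrow(p1@sites), 1)
    expect_equal(unlist(p1@sites[1, c("x", "y")]), c(x = 50, y = 50))
    # 175 um at 15,000 cells/mm^2 is 175/8.1650 = 21.43 cell units
    s2 <- ArraySpec(2, 2, spacingUm = 175, kPerNeedle = 5, D = 2,
                    center = c(50, 50))
    p2 <- arraySites(s2)
    xs <- sort(unique(p2@sites$x))
    expect_equal(diff(xs), 175 / (1000 / sqrt(15000)), tolerance = 1e-9)
    expect_equal(diff(xs), 21.43, tolerance = 1e-3)
    # a 4x4 at 700 um spans 2100 um = 257.2 cell units and fits 400x400
    s3 <- ArraySpec(4, 4, spacingUm = 700, kPerNeedle = 30, D = 2,
                    center = c(200, 200))
    p3 <- arraySites(s3, gridDims = c(400, 400))
    expect_equal(max(p3@sites$x) - min(p3@sites$x), 2100 / 8.164966,
                 tolerance = 1e-4)
    expect_error(arraySites(s3, gridDims = c(200, 200)), "geometry error")
    # fixed 4.43 mm^2 backing: a 4x4 spans it edge-to-edge at ~700 um
    sb <- arrayOnBacking(4, center = c(200, 200))
    expect_equal(sb@spacingUm, sqrt(4.43) * 1000 / 3, tolerance = 1e-9)
    expect_equal(sb@spacingUm, 700, tolerance = 0.01)
})
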