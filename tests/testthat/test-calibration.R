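test_that("detection limits follow the 108-copy rule", {
    expect_equal(lodForSide(70), 108 / 9800)
    expect_equal(round(lodForSide(70), 3), 0.011)
    expect_equal(round(lodForSide(173), 4), 0.0018)
    d <- calibDefaults()
    expect_equal(d$lodSub, lodForSide(d$subSide))
    expect_equal(d$lodFull, lodForSide(d$fullSide))
    expect_equal(d$candidates, c(0, 0.007, 0.01, 0.0125, 0.015))
    expect_equal(d$epsilon, 2e-4)
})

test_that("reconstruction places each mutation as a contiguous patch at its frequency", {
    set.seed(51)
    side <- 40
    # a single fully clonal mutation fills the section
    r1 <- reconstructSection(0.5, side = side)
    expect_equal(length(r1$cells[[1]]), side^2)
    # a quarter-frequency mutation occupies half the cells, 4-connected
    r2 <- reconstructSection(0.25, side = side)
    expect_equal(length(r2$cells[[1]]), round(0.5 * side^2))
    expect_true(isConnected4(r2$cells[[1]], side))
    # conservation with several mutations
    vafs <- c(0.2, 0.12, 0.05, 0.011)
    r3 <- reconstructSection(vafs, side = side)
    expect_equal(vapply(r3$cells, length, numeric(1)),
                 floor(2 * side^2 * sort(vafs, decreasing = TRUE) + 0.5))
    for (cs in r3$cells) expect_true(isConnected4(cs, side))
    # top-level patches are disjoint
    expect_false(anyDuplicated(unlist(r3$cells[is.na(r3$nestedIn)])) > 0)
    expect_error(reconstructSection(0.6), "data error")
    expect_warning(reconstructSection(c(0.3, 1e-6), side = 40), "dropping")
})

test_that("cumulative overflow beyond 0.5 nests the mutation inside a larger clone", {
    set.seed(52)
    r <- reconstructSection(c(0.3, 0.3), side = 30)
    expect_true(is.na(r$nestedIn[1]))
    expect_equal(r$nestedIn[2], 1L)
    # doubly mutated cells exist: the nested patch lies inside the host
    expect_true(all(r$cells[[2]] %in% r$cells[[1]]))
    expect_true(isConnected4(r$cells[[2]], 30))
    # boundary-growth variant obeys the same constraints
    rb <- reconstructSection(c(0.3, 0.3), side = 30, growth = "boundary")
    expect_true(all(rb$cells[[2]] %in% rb$cells[[1]]))
})

test_that("window downsampling applies the window detection limit", {
    # hand-built section: window position is forced when subSide == side
    side <- 70
    mk <- function(n) seq_len(n)   # n cells packed from the corner
    recon <- structure(list(side = side, vafs = c(0.3, 0.2, 0.1),
                            targetCells = c(108, 107, 4900),
                            cells = list(mk(108), 200000, mk(4900)),
                            nestedIn = rep(NA_integer_, 3)),
                       class = "reconstructedSection")
    recon$cells[[2]] <- integer(0)      # absent from the section/window
    ds <- downsampleSection(recon, subSide = 70)
    # 108 mutant cells -> VAF 108/9800 = 0.011020, retained at the LOD
    expect_true(any(abs(ds$vafs - 108 / 9800) < 1e-12))
    # the full-window mutation reports VAF 0.5
    expect_true(any(ds$vafs == 0.5))
    expect_equal(ds$count, 2)
    # 107 cells falls below the LOD and is dropped
    recon$cells[[1]] <- mk(107)
    ds2 <- downsampleSection(recon, subSide = 70)
    expect_equal(ds2$count, 1)
    expect_error(downsampleSection(recon, subSide = 71), "exceed")
})

test_that("window sampling is unbiased for clone cell fractions", {
    # unbiasedness holds over the joint randomness of patch placement and
    # window position (conditionally on one placement, fully contained
    # windows over-weight central cells); a toroidally translated fixed
    # patch shape makes the placement distribution exactly uniform
    set.seed(53)
    side <- 60; sub <- 20
    base <- reconstructSection(c(0.15, 0.08), side = side)
    shapes <- lapply(base$cells, function(cs)
        cbind((cs - 1L) %% side, (cs - 1L) %/% side))
    fr <- replicate(1500, {
        dx <- sample.int(side, 1L) - 1L; dy <- sample.int(side, 1L) - 1L
        cells <- lapply(shapes, function(m)
            ((m[, 1] + dx) %% side) + ((m[, 2] + dy) %% side) * side + 1L)
        r <- base; r$cells <- cells
        ds <- downsampleSection(r, subSide = sub, lod = 0)
        unname(ds$vafs) * 2          # cell fraction = 2 * VAF
    })
    fracSection <- vapply(base$cells, length, numeric(1)) / side^2
    est <- rowMeans(fr)
    se <- apply(fr, 1, sd) / sqrt(ncol(fr))
    expect_true(all(abs(est - fracSection) < 3.5 * se))
})

test_that("count MSE selects the candidate closest in mean mutation counts", {
    sim <- rbind(`0.007` = c(a = 1, b = 2, c = 3),
                 `0.01` = c(a = 2, b = 3, c = 5),
                 `0.015` = c(a = 4, b = 6, c = 9))
    emp <- c(a = 2, b = 3, c = 5)
    res <- countMSE(sim, emp)
    expect_equal(res$best, 0.01)
    expect_equal(unname(res$mse["0.01"]), 0)
    # constant offset gives the squared offset
    expect_equal(unname(countMSE(sim, emp + 2)$mse["0.01"]), 4)
    # exclusions change the comparison set
    res2 <- countMSE(sim, c(a = 1, b = 2, c = 9), excludeBins = "c")
    expect_equal(res2$best, 0.007)
    expect_error(countMSE(sim, c(z = 1)), "no overlapping")
})

test_that("exponential fits equal the closed-form MLE on recentred VAFs", {
    lod <- 0.011
    f1 <- fitExponential(lod + c(0.01, 0.03), lod = lod)   # mean 0.02
    expect_equal(f1$lambda, 50, tolerance = 1e-6)
    f2 <- fitExponential(lod + c(0.004, 0.006), lod = lod) # mean 0.005
    expect_equal(f2$lambda, 200, tolerance = 1e-6)
    # recovery at scale: 1e4 draws from Exponential(80) + lod
    set.seed(54)
    x <- lod + rexp(1e4, 80)
    f3 <- fitExponential(x, lod = lod)
    expect_gt(f3$lambda, 78.4)
    expect_lt(f3$lambda, 81.6)
    expect_equal(f3$lambda, 1 / mean(x - lod), tolerance = 1e-6)
    expect_error(fitExponential(lod + 0.01, lod = lod), "at least 2")
    expect_error(fitExponential(rep(lod, 5), lod = lod), "degenerate")
})

test_that("interval likelihood matches quadrature and is stable in epsilon", {
    lam <- 50; eps <- 2e-4; lod <- 0.011
    f <- lod + 0.02
    ll <- intervalLoglik(f, lam, eps = eps, lod = lod)
    expect_equal(exp(ll), exp(-0.99) - exp(-1.01), tolerance = 1e-12)
    quad <- integrate(function(x) lam * exp(-lam * x), 0.02 - eps,
                      0.02 + eps)$value
    expect_equal(exp(ll), quad, tolerance = 1e-8)
    # halving eps halves the probability to first order
    llHalf <- intervalLoglik(f, lam, eps = eps / 2, lod = lod)
    expect_equal(exp(llHalf) / eps, exp(ll) / (2 * eps), tolerance = 1e-3)
    # near the detection boundary the lower limit clamps at zero
    llEdge <- intervalLoglik(lod + 1e-5, lam, eps = eps, lod = lod)
    expect_true(is.finite(llEdge))
    expect_equal(exp(llEdge), 1 - exp(-lam * (1e-5 + eps)),
                 tolerance = 1e-10)
    expect_error(intervalLoglik(0.005, lam, lod = lod), ">= lod")
})

test_that("a single-candidate selection is returned trivially", {
    set.seed(55)
    tab <- generateVAFTable(c(young = 2, old = 4), c(young = 90, old = 70),
                            samplesPerBin = 15, seed = 550)
    sel <- selectPersistence(list(`0.01` = tab), tab)
    expect_equal(sel$bestPMSE, 0.01)
    expect_equal(sel$bestPNLL, 0.01)
    expect_equal(unname(sel$mse["0.01"]), 0)
    expect_error(selectPersistence(list(tab), tab), "selection error")
})

test_that("persistence selection recovers the generating value in closed loop", {
    # simulator-generated 'empirical' data at p = 0.01, compared against
    # simulated ensembles for well-separated candidates; scaled down via
    # an elevated mutation rate and small sections to keep power at
    # manageable cost
    mp <- MutationParams(muPlus = 2e-5)
    ages <- c(young = 6, mid = 12, old = 18)
    ens <- list()
    for (p in c(0.004, 0.01, 0.025)) {
        ens[[format(p)]] <- simulateVAFEnsemble(
            p, ages = ages, reps = 40, gridSide = 40, mutParams = mp,
            seed = 100 + round(1e5 * p))
    }
    emp <- simulateVAFEnsemble(0.01, ages = ages, reps = 40, gridSide = 40,
                               mutParams = mp, seed = 877)
    sel <- suppressMessages(selectPersistence(ens, emp, lod = lodForSide(40)))
    expect_equal(sel$bestPMSE, 0.01)
    expect_equal(sel$bestPNLL, 0.01)
    expect_true(all(c("0.004", "0.01", "0.025") %in% names(sel$mse)))
    expect_equal(nrow(sel$lambdaTable), 3 * length(unique(sel$lambdaTable$age_bin)))
})
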