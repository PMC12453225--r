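test_that("whole-grid delivery reaches confluence immediately", {
    set.seed(41)
    fe <- runFateExperiment(pCorr = 0, gridSide = 10, k = 100, D = 5,
                            reps = 5, horizonYears = 1, seed = 410)
    expect_true(all(fe$fates$outcome == "confluence"))
    expect_true(all(fe$fates$eventTime == 0))
    expect_equal(fe$summary$prob[fe$summary$outcome == "confluence"], 1)
})

test_that("endpoints are exclusive and verified by the final state", {
    set.seed(42)
    fe <- runFateExperiment(pCorr = 0.2, gridSide = 15, k = 3, D = 2,
                            reps = 30, horizonYears = 20, seed = 420)
    expect_true(all(fe$fates$outcome %in% c("loss", "confluence", "ongoing")))
    for (i in seq_len(nrow(fe$fates))) {
        sn <- fe$trajectories[fe$trajectories$replicate == i, ]
        last <- tail(sn, 1)
        if (fe$fates$outcome[i] == "loss") {
            expect_equal(last$corrected, 0)
            expect_lte(fe$fates$eventTime[i], 20)
        } else if (fe$fates$outcome[i] == "confluence") {
            expect_gte(last$corrected, 0.8 * 225)
        }
    }
    # outcome probabilities sum to one with binomial SEs attached
    expect_equal(sum(fe$summary$prob), 1)
    expect_true(all(fe$summary$se >= 0))
})

test_that("expansion-rate estimator recovers exact slopes and signals no data", {
    # hand-built experiment: area grows linearly at 2 cells per year
    cellArea <- SimParams()@cellArea * 1e-6
    fake <- list(fates = data.frame(replicate = 1:2,
                                    outcome = c("confluence", "loss"),
                                    eventTime = c(4, 1), seed = NA),
                 trajectories = data.frame(
                     replicate = rep(1:2, each = 5),
                     time = rep(0:4, 2),
                     corrected = c(10 + 2 * (0:4), rep(7, 5))))
    er <- estimateExpansionRate(fake)
    expect_equal(er$n, 1L)
    expect_equal(er$meanRate, 2 * cellArea, tolerance = 1e-10)
    # constant corrected count gives slope 0
    fake$fates$outcome <- c("confluence", "confluence")
    fake$trajectories$corrected <- 7
    er0 <- estimateExpansionRate(fake)
    expect_equal(er0$meanRate, 0, tolerance = 1e-12)
    # no confluent replicates: empty-result signal
    fake$fates$outcome <- c("loss", "ongoing")
    erNA <- estimateExpansionRate(fake)
    expect_equal(erNA$n, 0L)
    expect_true(is.na(erNA$meanRate))
})

test_that("clone areas convert counts at 66.7 um^2 per cell and partition corrected tissue", {
    g <- BasalGrid(20, 20)
    g@corrected[1:10] <- 1L
    g@cloneId[1:10] <- 1L
    g@needleId[1:10] <- 1L
    ca <- cloneAreas(g, by = "clone_id")
    expect_equal(ca$cells, 10)
    expect_equal(ca$areaMm2, 10 * 66.7e-6, tolerance = 1e-12)
    # 0.15 mm^2 corresponds to 2249 cells at this areal density
    expect_equal(round(0.15 / 66.7e-6), 2249)
    # labels partition the corrected cells
    set.seed(43)
    g2 <- applyCorrection(BasalGrid(40, 40),
                          DeliveryPlan(x = c(10, 30), y = c(10, 30),
                                       k = c(12, 8), D = c(2, 2)))
    byClone <- cloneAreas(g2, by = "clone_id")
    byNeedle <- cloneAreas(g2, by = "needle_id")
    expect_equal(sum(byClone$cells), 20)
    expect_equal(sum(byNeedle$cells), 20)
    expect_equal(sort(byNeedle$cells), c(8, 12))
    expect_equal(sum(byClone$areaMm2),
                 correctedFraction(g2) * 1600 * 66.7e-6)
})

test_that("spatial patches and lineage labels are both available", {
    g <- BasalGrid(12, 12)
    g@corrected[2:4, 2] <- 1L; g@cloneId[2:4, 2] <- 1:3
    g@corrected[9, 9] <- 1L; g@cloneId[9, 9] <- 4L
    expect_equal(correctedPatches(g), c(3L, 1L))
    expect_equal(nrow(cloneAreas(g, by = "clone_id")), 4)
})

test_that("loss probability is non-increasing in delivered dose", {
    loss <- vapply(c(3, 10, 30), function(k) {
        fe <- runFateExperiment(pCorr = 0.1, gridSide = 40, k = k, D = 2,
                                reps = 100, horizonYears = 4, seed = 440)
        mean(fe$fates$outcome == "loss")
    }, numeric(1))
    expect_gte(loss[1], loss[2])
    expect_gte(loss[2], loss[3])
})

test_that("TP53 coverage statistics are pure functions of the exported snapshot", {
    set.seed(45)
    g <- BasalGrid(25, 25)
    tr <- advanceGrid(g, years = 3, mutParams = MutationParams(muPlus = 2e-4),
                      genoParams = GenotypeParams(pCorr = 0, pPlusTP53 = 0.05),
                      checkLoss = FALSE, confluenceFraction = NA)
    fg <- finalGrid(tr)
    f <- tempfile(fileext = ".csv")
    writeGridCSV(fg, f)
    g2 <- readGridCSV(f)
    expect_identical(tp53Fraction(g2), tp53Fraction(fg))
    ev1 <- cloneAreas(fg, by = "mutation_event_id")
    ev2 <- cloneAreas(g2, by = "mutation_event_id")
    expect_identical(sort(ev1$cells), sort(ev2$cells))
    unlink(f)
})

test_that("corrected-arm aggregation substitutes uncorrected replicates after loss", {
    unc <- runTP53Experiment(m = 1, r = 1, pCorr = NULL, gridSide = 12,
                             k = 2, reps = 6, horizonYears = 2,
                             mutParams = MutationParams(muPlus = 1e-4),
                             seed = 460)
    expect_false(any(is.na(unc$coverage)))
    expect_equal(dim(unc$coverage), c(6, length(unc$times)))
    # pCorr = 0 with k = 2 loses correction quickly in most replicates
    corr <- runTP53Experiment(m = 1, r = 1, pCorr = 0, gridSide = 12,
                              k = 2, reps = 6, horizonYears = 2,
                              mutParams = MutationParams(muPlus = 1e-4),
                              uncorrectedPool = unc, seed = 461)
    expect_false(any(is.na(corr$coverage)))
    expect_true(any(!is.na(corr$lossTimes)))
    expect_true(any(corr$cloneStats$substituted))
    expect_error(runTP53Experiment(pCorr = 0.1, gridSide = 12, reps = 2,
                                   horizonYears = 1),
                 "aggregation error")
    cs <- coverageSummary(unc)
    expect_equal(nrow(cs), length(unc$times))
    expect_true(all(cs$mean >= 0 & cs$mean <= 1))
})

test_that("46-year TP53 burden is insensitive to correction when rates and fitness are equal", {
    # condition-1 symmetry at reduced scale: elevated mutation rate and a
    # shorter horizon keep the comparison well powered
    mp <- MutationParams(muPlus = 2e-5)
    unc <- runTP53Experiment(m = 1, r = 1, pCorr = NULL, gridSide = 30,
                             k = 10, reps = 60, horizonYears = 12,
                             mutParams = mp, seed = 470)
    corr <- runTP53Experiment(m = 1, r = 1, pCorr = 0.1, gridSide = 30,
                              k = 10, reps = 60, horizonYears = 12,
                              mutParams = mp, uncorrectedPool = unc,
                              seed = 471)
    mu <- meanCoverageAt(unc); mc <- meanCoverageAt(corr)
    se <- sqrt(mu$se^2 + mc$se^2)
    expect_lt(abs(mu$mean - mc$mean), 3 * se)
})

test_that("array experiments report per-needle descendant areas", {
    spec <- ArraySpec(2, 2, spacingUm = 175, kPerNeedle = 4, D = 2,
                      center = c(20, 20))
    ae <- runArrayExperiment(spec, gridSide = 40, pCorr = 0.5, reps = 3,
                             horizonYears = 1, seed = 480)
    expect_equal(nrow(ae$needleAreas), 3 * 4)
    # initial dose: 4 needles x 4 cells; areas afterwards are non-negative
    expect_true(all(ae$needleAreas$cells >= 0))
    expect_equal(length(ae$totals), 3)
    expect_equal(ae$meanTotalArea, mean(ae$totals))
    perRep <- tapply(ae$needleAreas$areaMm2, ae$needleAreas$replicate, sum)
    expect_equal(as.numeric(perRep), ae$totals, tolerance = 1e-12)
})
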