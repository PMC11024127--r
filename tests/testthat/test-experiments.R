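# Experiment drivers: wild-type report, knockdown protocols, series.

test_that("wild-type reports are reproducible and internally consistent", {
    cfg <- simulationConfig(horizon = 45)
    r1 <- wtReport(3, cfg, seed = 2)
    r2 <- wtReport(3, cfg, seed = 2)
    expect_identical(r1$summary, r2$summary)
    expect_identical(r1$categories, r2$categories)
    expect_equal(nrow(r1$summary), 3L)
    expect_equal(sum(r1$divisionCounts), 3)
    expect_equal(sum(r1$categories$count),
                 sum(vapply(r1$trees, nCells, 0L)))
    expect_true(all(r1$summary$fractionOpen >= 0 &
                    r1$summary$fractionOpen <= 1))
})

test_that("a degenerate report on a zero horizon is a single closed root", {
    r <- wtReport(1, simulationConfig(horizon = 0), seed = 1)
    expect_equal(r$summary$divisions, 0L)
    expect_equal(r$summary$fractionOpen, 0)
    expect_equal(r$summary$nCells, 1L)
})

test_that("an onset at the horizon degenerates to wild type", {
    cfg <- simulationConfig(horizon = 45)
    wt <- runEnsemble(3, cfg, baseSeed = 9)
    kd <- knockdownExperiment(knockdownSpec("Tcf7", 0.2, onset = 45), 3,
                              cfg, seed = 9)
    expect_identical(wt$summary, kd$summary)
})

test_that("onset-0 knockdown scales the initial count inside the colony", {
    cfg <- simulationConfig(horizon = 1,
                            knockdown = knockdownSpec("PU.1", 0.2, 0))
    tree <- simulateColony(cfg, seed = 1)
    # root began at P = 1 (5 x 0.2); over 1 h it cannot exceed a few counts
    expect_lt(treeCells(tree)$P, 4)
    cfgT <- simulationConfig(horizon = 1,
                             knockdown = knockdownSpec("Tcf7", 0.2, 0))
    treeT <- simulateColony(cfgT, seed = 1)
    expect_lt(treeCells(treeT)$T, 3)   # started from 0
})

test_that("a length-one delayed series equals the plain knockdown experiment", {
    cfg <- simulationConfig(horizon = 45)
    ser <- delayedKDSeries("Gata3", 20, 3, cfg, seed = 4)
    kd <- knockdownExperiment(knockdownSpec("Gata3", 0.2, 20), 3, cfg,
                              seed = 4)
    expect_identical(ser$runs[[1]]$summary, kd$summary)
    expect_equal(nrow(ser$byOnset), 1L)
    expect_error(delayedKDSeries("Gata3", c(40, 20), 2, cfg, seed = 1),
                 "sorted")
})

test_that("the switch heuristic finds the first sustained Tcf7 > PU.1 state", {
    # construct a lineage with known final counts via the fixture builder
    tr <- makeAnnotatedTree(c(NA, 1, 1, 2, 2), open = rep(FALSE, 5))
    df <- treeCells(tr)
    # default fixture counts: T = 2, P = 5 everywhere: never switches
    expect_true(is.na(switchGeneration(tr, df$id[4])))
    df$T <- c(1, 6, 1, 7, 1); df$P <- c(5, 2, 5, 1, 5)
    tr@cells <- df
    expect_equal(switchGeneration(tr, df$id[4]), 1L)
})
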