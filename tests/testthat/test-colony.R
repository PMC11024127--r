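# Proliferation level: division times, inheritance, colony assembly.

test_that("division times follow the generation table and stay positive", {
    d0 <- drawDivisionTime(0, n = 1e5, seed = 1)
    expect_equal(mean(d0), 34, tolerance = 0.01)   # slight truncation bias
    expect_equal(stats::sd(d0), 13, tolerance = 0.02)
    expect_true(all(d0 > 0))
    # generations beyond the table reuse the last row
    frozen <- divisionTimeModel(sigma = rep(0, 5))
    expect_equal(drawDivisionTime(7, frozen, n = 3, seed = 1), rep(12, 3))
    expect_equal(drawDivisionTime(0, frozen, n = 1, seed = 1), 34)
    # heavy truncation still yields strictly positive draws
    wild <- divisionTimeModel(mu = rep(1, 5), sigma = rep(10, 5))
    expect_true(all(drawDivisionTime(2, wild, n = 5000, seed = 2) > 0))
})

test_that("region inheritance copies under X > 0 and opens under X = 0", {
    r <- regulatoryRegion(100, 200, 200)
    expect_equal(unname(inheritRegion(r, motherX = 3, seed = 1)),
                 c(100L, 200L, 200L))
    expect_equal(unname(inheritRegion(regulatoryRegion(500, 0, 0),
                                      motherX = 0, seed = 1)),
                 c(0L, 500L, 0L))
    # all-intermediate region: O' ~ Binomial(500, 1/2)
    draws <- t(vapply(1:10000, function(i)
        inheritRegion(regulatoryRegion(0, 500, 0), motherX = 0, seed = i),
        c(C = 0L, I = 0L, O = 0L)))
    expect_true(all(rowSums(draws) == 500))
    expect_true(all(draws[, "C"] == 0))
    expect_equal(mean(draws[, "O"]), 250,
                 tolerance = 3 * sqrt(500 * 0.25 / 10000) / 250)
    # general region: E[O'] = O + I/2, sites conserved
    draws2 <- t(vapply(1:10000, function(i)
        inheritRegion(r, motherX = 0, seed = i), c(C = 0L, I = 0L, O = 0L)))
    expect_true(all(rowSums(draws2) == 500))
    expect_equal(mean(draws2[, "O"]), 300,
                 tolerance = 3 * sqrt(200 * 0.25 / 10000) / 300)
})

test_that("cell lifetimes censor at the horizon and are reproducible", {
    cfg <- simulationConfig(horizon = 10)
    res <- simulateCellLifetime(geneState(), regulatoryRegion(),
                                config = cfg, seed = 1, cellId = 0L)
    expect_false(res$divided)          # g=0 division times are ~34 h
    expect_equal(res$end, 10)
    # zero-duration lifetime: born at the horizon
    res0 <- simulateCellLifetime(geneState(), regulatoryRegion(),
                                 isRoot = TRUE, birth = 10, config = cfg,
                                 seed = 1, cellId = 1L)
    expect_equal(res0$end, 10)
    expect_equal(unname(res0$finalState), unname(as.numeric(geneState())))
    expect_equal(unname(res0$finalRegion), c(500L, 0L, 0L))
    res2 <- simulateCellLifetime(geneState(), regulatoryRegion(),
                                 config = cfg, seed = 1, cellId = 0L)
    expect_identical(res, res2)
})

test_that("a zero horizon yields a single censored root", {
    tree <- simulateColony(simulationConfig(horizon = 0), seed = 1)
    df <- treeCells(tree)
    expect_equal(nrow(df), 1L)
    expect_equal(df$cause, "censored")
    expect_equal(df$end, 0)
})

test_that("a deterministic 20 h division schedule gives 6 synchronous rounds", {
    cfg <- simulationConfig(division = divisionTimeModel(mu = rep(20, 5),
                                                         sigma = rep(0, 5)))
    tree <- simulateColony(cfg, seed = 1)
    df <- treeCells(tree)
    expect_equal(max(df$generation), 6L)
    expect_equal(sum(df$cause == "censored"), 64L)   # 2^6 leaves
    expect_equal(nrow(df), 127L)                      # 2^7 - 1 cells
    expect_true(all(df$end <= 120))
})

test_that("simulated trees satisfy the binary-tree and timing invariants", {
    tree <- simulateColony(simulationConfig(), seed = 2)
    df <- treeCells(tree)
    expect_true(validObject(tree))
    nLeaves <- sum(df$cause == "censored")
    expect_equal(nLeaves, sum(df$cause == "divided") + 1L)
    pidx <- match(df$parent, df$id)
    expect_true(all(is.na(pidx) | df$birth == df$end[pidx]))
    expect_true(all(df$end <= treeHorizon(tree)))
    expect_true(all(df$end >= df$birth))
    expect_true(all(rowSums(df[, c("C", "I", "O")]) == 500))
    expect_true(all(df[, c("R", "T", "G", "P", "X", "N")] >= 0))
    # fixed seed reproducibility
    expect_identical(df, treeCells(simulateColony(simulationConfig(),
                                                  seed = 2)))
})

test_that("ensembles are seeded deterministically and summarised consistently", {
    cfg <- simulationConfig(horizon = 45)
    e1 <- runEnsemble(3, cfg, baseSeed = 5)
    e2 <- runEnsemble(3, cfg, baseSeed = 5)
    expect_identical(e1$summary, e2$summary)
    s <- colonySummary(e1$trees[[2]])
    expect_equal(s$nCells, nCells(e1$trees[[2]]))
    expect_equal(s$divisions, max(treeCells(e1$trees[[2]])$generation))
    expect_true(s$fractionOpen >= 0 && s$fractionOpen <= 1)
    expect_equal(e1$summary$nCells[2], s$nCells)
})
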