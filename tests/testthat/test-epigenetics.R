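# Epigenetic level: three-state site model under the extended Gillespie
# (attempt-rate) scheme.

test_that("channel propensities follow the attempt-rate scheme", {
    ch <- channelPropensities(regulatoryRegion(500, 0, 0),
                              c(X = 8, R = 1, N = 7))
    # fully closed region: only the input-coupled C->I channel is live,
    # at (k2 N + k3 R) * C/S = (0.2*7 + 0.2*1) * 1 = 1.6 per hour
    live <- ch$propensity > 0
    expect_equal(sum(live), 1L)
    expect_equal(ch$from[live], "C")
    expect_equal(ch$to[live], "I")
    expect_equal(ch$propensity[live], 1.6)
})

test_that("zero inputs silence the direct channels; mixed states keep mediated ones", {
    ch <- channelPropensities(regulatoryRegion(200, 200, 100),
                              c(X = 0, R = 0, N = 0))
    direct <- is.na(ch$mediator)
    expect_true(all(ch$propensity[direct] == 0))
    expect_true(any(ch$propensity[!direct] > 0))
})

test_that("a fully open region with no X input is absorbing", {
    ch <- channelPropensities(regulatoryRegion(0, 0, 500),
                              c(X = 0, R = 5, N = 7))
    expect_true(all(ch$propensity == 0))
    r <- evolveRegion(regulatoryRegion(0, 0, 500), constantTraj(50, 0, 5, 7),
                      0, 50, seed = 1)
    expect_equal(unname(r$final), c(0L, 0L, 500L))
    expect_equal(r$nEvents, 0)
})

test_that("no single event changes both O and C (no direct O<->C flux)", {
    tr <- evolveRegion(regulatoryRegion(100, 300, 100),
                       constantTraj(2000, 10, 5, 7), 0, 2000,
                       seed = 3, record = TRUE)$trajectory
    dC <- diff(tr[, "C"]); dO <- diff(tr[, "O"])
    expect_true(all(!(dC != 0 & dO != 0)))
    expect_true(all(abs(dC) <= 1) && all(abs(dO) <= 1))
})

test_that("single extended-Gillespie steps conserve sites and obey the one-channel rule", {
    set.seed(7)
    st <- epigeneticStep(regulatoryRegion(500, 0, 0), c(X = 8, R = 1, N = 7),
                         t = 0, tMax = 100)
    expect_equal(unname(st$region), c(499L, 1L, 0L))
    expect_equal(st$channel, 3L)  # the C->I input channel
    # zero total propensity censors
    st0 <- epigeneticStep(regulatoryRegion(0, 0, 500),
                          c(X = 0, R = 1, N = 7), t = 0, tMax = 10)
    expect_equal(st0$t, 10)
    expect_true(is.na(st0$channel))
})

test_that("region evolution is reproducible and conserves the site total", {
    traj <- simulateGRN(geneState(), 0, 30, seed = 5)
    a <- evolveRegion(regulatoryRegion(), traj, 0, 30, seed = 5,
                      record = TRUE)
    b <- evolveRegion(regulatoryRegion(), traj, 0, 30, seed = 5,
                      record = TRUE)
    expect_identical(a, b)
    expect_true(all(rowSums(a$trajectory[, 2:4]) == 500))
    # zero-length interval returns the input region unchanged
    z <- evolveRegion(regulatoryRegion(123, 77, 300), traj, 10, 10, seed = 1)
    expect_equal(unname(z$final), c(123L, 77L, 300L))
    # interval not covered by the trajectory is rejected
    expect_error(evolveRegion(regulatoryRegion(), traj, 0, 60, seed = 1),
                 "cover")
})

test_that("with X = 0 and positive R, N the region only opens on average", {
    finals <- t(vapply(1:60, function(i)
        evolveRegion(regulatoryRegion(300, 150, 50),
                     constantTraj(40, 0, 5, 7), 0, 40, seed = i)$final,
        c(C = 0L, I = 0L, O = 0L)))
    expect_gt(mean(finals[, "O"]), 50)
    expect_lt(mean(finals[, "C"]), 300)
    # and X clamped large closes an open region
    finals2 <- t(vapply(1:60, function(i)
        evolveRegion(regulatoryRegion(0, 0, 500),
                     constantTraj(40, 50, 0, 0), 0, 40, seed = i)$final,
        c(C = 0L, I = 0L, O = 0L)))
    expect_lt(mean(finals2[, "O"]), 500)
})

test_that("openness threshold is >= 75% of sites", {
    expect_true(isRegionOpen(regulatoryRegion(0, 125, 375)))
    expect_false(isRegionOpen(regulatoryRegion(0, 126, 374)))
    expect_true(isRegionOpen(regulatoryRegion(0, 0, 500)))
    expect_error(isRegionOpen(regulatoryRegion(10, 10, 10)), "sum")
})

test_that("aggregate dynamics match a per-site simulation oracle at S = 10", {
    par10 <- epigeneticParameters(sites = 10L)
    set.seed(101)
    nrep <- 2000
    oracle <- t(replicate(nrep, perSiteSimulate(
        c(rep("C", 4), rep("I", 3), rep("O", 3)), X = 8, R = 1, N = 7,
        t1 = 2, params = par10)))
    agg <- t(vapply(seq_len(nrep), function(i)
        evolveRegion(c(C = 4L, I = 3L, O = 3L), constantTraj(2, 8, 1, 7),
                     0, 2, par10, seed = 5000 + i)$final,
        c(C = 0L, I = 0L, O = 0L)))
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    p <- chisqHomogeneity(key(oracle), key(agg))
    expect_gt(p, 0.01)
})
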