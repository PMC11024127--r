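# Transcriptional level: Shea-Ackers propensities and the Gillespie SSA.

test_that("production propensities match hand-evaluated regulation terms", {
    p <- grnParameters()
    # repression-free X production: T = G = 0
    s0 <- geneState(R = 0, T = 0, G = 0, P = 0, X = 0, N = 0)
    expect_equal(productionPropensities(s0, p)[["X"]], 1.0)
    # reference initial cell
    st <- geneState()
    pr <- productionPropensities(st, p)
    expect_equal(pr[["X"]], 1 / (1 + 2 * 2 + 1 * 1))
    expect_equal(pr[["N"]], 0.01 / (1 + 7))
    expect_equal(pr[["P"]], 2.5 * 5 / (1 + 2.5 * 5 + 2.6 * 1 * 1 * 2))
    expect_true(all(is.finite(pr)) && all(pr >= 0))
})

test_that("degradation is gamma times count and Notch never decays", {
    st <- geneState()
    dg <- degradationPropensities(st)
    expect_equal(dg[["X"]], 0.02 * 8)
    expect_equal(dg[["N"]], 0)
    zero <- geneState(0, 0, 0, 0, 0, 0)
    expect_true(all(degradationPropensities(zero) == 0))
})

test_that("invalid states and parameters are rejected", {
    expect_error(productionPropensities(c(R = -1, T = 0, G = 0, P = 0,
                                          X = 0, N = 0)),
                 "non-negative")
    expect_error(geneState(T = 1.5), "integer")
    expect_error(grnParameters(p = stats::setNames(c(-1, rep(1, 15)),
                                                   paste0("p", 1:16))))
})

test_that("a Gillespie step censors at tMax when no event fits the window", {
    # X's basal production keeps the total propensity positive for any
    # admissible parameters, so censoring is exercised through the horizon
    set.seed(1)
    res <- grnStep(geneState(), 0, grnParameters(), tMax = 1e-12)
    expect_equal(res$t, 1e-12)
    expect_identical(res$event, NA_character_)
    expect_equal(res$state, geneState())
})

test_that("first-event waiting times are exponential at the total propensity", {
    # PU.1 degradation (0.06 * 8 = 0.48 per hour) plus X's basal
    # production (rate 1) dominate the total propensity here; the SSA's
    # first event time must average 1 / a0
    p <- suppressedParams()
    init <- c(R = 0, T = 0, G = 0, P = 8, X = 0, N = 0)
    a0 <- sum(productionPropensities(init, p)) +
        sum(degradationPropensities(init, p))
    expect_equal(a0, 1.48, tolerance = 1e-6)
    first <- vapply(1:3000, function(i) {
        tr <- simulateGRN(init, 0, 200, p, seed = i)
        tr[2L, 1L]
    }, 0)
    expect_equal(mean(first), 1 / a0,
                 tolerance = 3 / sqrt(3000))
})

test_that("trajectories are reproducible, event-structured and legal", {
    a <- simulateGRN(geneState(), 0, 20, seed = 42)
    b <- simulateGRN(geneState(), 0, 20, seed = 42)
    expect_identical(a, b)
    expect_true(all(diff(a[, "time_h"]) >= 0))
    expect_true(all(a[, 2:7] >= 0))
    # consecutive event states differ by exactly one molecule in one species
    ev <- a[-nrow(a), , drop = FALSE]
    d <- abs(diff(ev[, 2:7]))
    expect_true(all(rowSums(d) == 1))
    # Notch count never decreases
    expect_true(all(diff(a[, "N"]) >= 0))
    # zero-length interval returns only the initial state (plus end stamp)
    z <- simulateGRN(geneState(), 5, 5, seed = 1)
    expect_equal(unname(z[, "time_h"]), rep(5, nrow(z)))
    expect_equal(unname(z[1L, 2:7]), unname(geneState()))
})

test_that("pure-death means decay at the tabulated gamma rates", {
    # R, T, G, P: productions suppressed; X isolated via a huge p14 and a
    # large decaying Tcf7 pool so its basal production is ~0 too
    p <- suppressedParams(p14 = 1e6)
    init <- c(R = 50, T = 50, G = 50, P = 50, X = 50, N = 0)
    fin <- grnFinals(init, 5, p, 2000)
    gam <- c(R = 0.15, T = 0.15, G = 0.23, P = 0.06, X = 0.02)
    for (sp in names(gam)) {
        expct <- 50 * exp(-gam[[sp]] * 5)
        se <- stats::sd(fin[, sp]) / sqrt(nrow(fin))
        expect_lt(abs(mean(fin[, sp]) - expct), 3 * se + 1e-9)
    }
})

test_that("a linear birth-death channel reaches production/gamma at steady state", {
    # with T and G pinned at 0 the X channel is linear: birth rate 1,
    # death rate 0.02 X, stationary mean 1/0.02 = 50
    p <- suppressedParams()
    tr <- simulateGRN(c(R = 0, T = 0, G = 0, P = 0, X = 50, N = 0),
                      0, 4000, p, seed = 9)
    keep <- tr[, "time_h"] >= 2000
    w <- diff(c(tr[keep, "time_h"], 4000))
    xbar <- sum(tr[keep, "X"] * w) / sum(w)
    expect_equal(xbar, 50, tolerance = 0.08)
})

test_that("knockdown scales production and optionally the initial count", {
    st <- geneState()
    kd <- applyKnockdown(grnParameters(), st, "PU.1", 0.2,
                         scaleInitial = TRUE)
    expect_equal(kd$state[["P"]], 1)           # 5 * 0.2 = 1 exactly
    expect_equal(kd$params@kdFactor[["P"]], 0.2)
    kd2 <- applyKnockdown(grnParameters(), st, "Tcf7", 0.2,
                          scaleInitial = TRUE)
    expect_equal(kd2$state[["T"]], 0)          # 0.4 rounds down to 0
    id <- applyKnockdown(grnParameters(), st, "Gata3", 1, scaleInitial = TRUE)
    expect_equal(id$state, st)
    expect_equal(id$params@kdFactor, grnParameters()@kdFactor)
    expect_error(applyKnockdown(grnParameters(), st, "Bcl11b", 0.2),
                 "unknown gene")
    expect_error(applyKnockdown(grnParameters(), st, "Tcf7", 0))
    # scaled production propensity
    pr <- productionPropensities(st, kd$params)
    expect_equal(pr[["P"]], 0.2 * productionPropensities(st)[["P"]])
})
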