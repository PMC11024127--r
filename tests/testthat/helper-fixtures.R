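# Shared helpers: parameter variants and a per-site epigenetic simulator
# used as an independent oracle for the aggregate site-count dynamics.

# GRN parameters with all productions suppressed (strictly positive but
# negligible); X's basal production is removed by a huge p14 so that X is a
# pure death process while a large Tcf7 pool is still decaying.
suppressedParams <- function(p14 = 1e-12) {
    p <- stats::setNames(rep(1e-12, 16), paste0("p", 1:16))
    p["p14"] <- p14
    grnParameters(p = p)
}

# constant-input GRN trajectory covering [0, t1]
constantTraj <- function(t1, X, R, N) {
    matrix(c(0, R, 0, 0, 0, X, N,
             t1, R, 0, 0, 0, X, N),
           nrow = 2, byrow = TRUE,
           dimnames = list(NULL, c("time_h", "R", "T", "G", "P", "X", "N")))
}

# Independent per-site oracle: explicit list of S site states, exact SSA on
# per-site hazards. Direct channels act on each matching site at weight/S;
# mediated channels at weight * mediatorFraction / S (the mediator may be
# the site itself for the I-mediated channel, matching the aggregate form).
perSiteSimulate <- function(sites, X, R, N, t1,
                            params = epigeneticParameters()) {
    r <- params@rates
    S <- length(sites)
    t <- 0
    repeat {
        nC <- sum(sites == "C"); nI <- sum(sites == "I")
        nO <- sum(sites == "O")
        openIn <- r[["k2"]] * N + r[["k3"]] * R
        # per-site hazards by current state
        hCI <- openIn / S + r[["delta"]] * (nO / S) / S
        hIO <- openIn / S + r[["gammaM"]] * (nO / S) / S
        hIC <- r[["k1"]] * X / S + r[["beta"]] * (nC / S) / S +
            r[["epsilon"]] * (nI / S) / S
        hOI <- r[["k1"]] * X / S + r[["alpha"]] * (nC / S) / S
        w <- c(CI = nC * hCI, IO = nI * hIO, IC = nI * hIC, OI = nO * hOI)
        a0 <- sum(w)
        if (a0 <= 0) break
        t <- t + stats::rexp(1L, a0)
        if (t > t1) break
        ch <- sample(names(w), 1L, prob = w)
        from <- substr(ch, 1L, 1L); to <- substr(ch, 2L, 2L)
        j <- sample(which(sites == from), 1L)
        sites[j] <- to
    }
    c(C = sum(sites == "C"), I = sum(sites == "I"), O = sum(sites == "O"))
}

# two-sample chi-square homogeneity test over categorical outcomes, pooling
# rare categories so expected counts stay reasonable
chisqHomogeneity <- function(a, b, minExpected = 5) {
    lev <- union(names(table(a)), names(table(b)))
    ta <- table(factor(a, levels = lev))
    tb <- table(factor(b, levels = lev))
    keep <- (ta + tb) / 2 >= minExpected
    if (any(!keep)) {
        ta <- c(ta[keep], other = sum(ta[!keep]))
        tb <- c(tb[keep], other = sum(tb[!keep]))
    }
    suppressWarnings(stats::chisq.test(rbind(ta, tb)))$p.value
}

# final states of n independent GRN replicates at time t1
grnFinals <- function(initial, t1, params, n, seedBase = 0L) {
    out <- matrix(0, n, 6)
    for (i in seq_len(n)) {
        tr <- simulateGRN(initial, 0, t1, params, seed = seedBase + i)
        out[i, ] <- tr[nrow(tr), 2:7]
    }
    colnames(out) <- c("R", "T", "G", "P", "X", "N")
    out
}
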