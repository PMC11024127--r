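checkState <- function(state) {
    if (length(state) != 6L)
        stop("'state' must have the six species R,T,G,P,X,N")
    if (is.null(names(state))) names(state) <- GENE_NAMES
    state <- state[GENE_NAMES]
    if (any(is.na(state)) || any(!is.finite(state)) || any(state < 0))
        stop("gene counts must be finite and non-negative")
    state
}

#' Shea-Ackers production propensities
#'
#' Evaluates the six production terms of the transcriptional network at the
#' current integer molecule counts, each multiplied by the species'
#' production scaling factor. The Notch signal production is
#' \code{p16 / (1 + N)}.
#'
#' @param state named numeric counts \code{R,T,G,P,X,N}.
#' @param params a [GRNParameters-class] object.
#' @return named numeric of six production rates (h^-1).
#' @examples
#' productionPropensities(geneState(), grnParameters())
#' @export
productionPropensities <- function(state, params = grnParameters()) {
    state <- checkState(state)
    validObject(params)
    grnPropensitiesCpp(state, params@p, params@gamma,
                       params@kdFactor)$production
}

#' First-order degradation propensities
#'
#' \code{gamma_i * count} for Runx1, Tcf7, Gata3, PU.1 and X; exactly 0 for
#' the Notch signal, which has no decay channel.
#'
#' @inheritParams productionPropensities
#' @return named numeric of six degradation rates (h^-1).
#' @export
degradationPropensities <- function(state, params = grnParameters()) {
    state <- checkState(state)
    validObject(params)
    grnPropensitiesCpp(state, params@p, params@gamma,
                       params@kdFactor)$degradation
}

#' One Gillespie step of the transcriptional network
#'
#' Draws an exponential waiting time at the total propensity and applies one
#' production (+1) or degradation (-1) event chosen proportionally to its
#' propensity. If the drawn time would pass \code{tMax} (or the total
#' propensity is zero) the unchanged state is returned stamped at
#' \code{tMax}. Uses R's RNG; seed with [set.seed()] for reproducibility.
#'
#' @param state named numeric counts \code{R,T,G,P,X,N}.
#' @param t current time (hours).
#' @param params a [GRNParameters-class] object.
#' @param tMax censoring time, > \code{t}.
#' @return list with \code{state}, \code{t} and \code{event} (species name
#'   signed "+"/"-", or NA if censored).
#' @export
grnStep <- function(state, t, params = grnParameters(), tMax) {
    state <- checkState(state)
    if (t >= tMax) stop("'t' must be below 'tMax'")
    prod <- productionPropensities(state, params)
    deg <- degradationPropensities(state, params)
    a0 <- sum(prod) + sum(deg)
    if (a0 <= 0)
        return(list(state = state, t = tMax, event = NA_character_))
    dt <- stats::rexp(1L, rate = a0)
    if (t + dt > tMax)
        return(list(state = state, t = tMax, event = NA_character_))
    w <- c(prod, deg)
    k <- sample.int(12L, 1L, prob = w)
    sp <- GENE_NAMES[(k - 1L) %% 6L + 1L]
    dir <- if (k <= 6L) 1 else -1
    state[sp] <- state[[sp]] + dir
    list(state = state, t = t + dt,
         event = paste0(if (dir > 0) "+" else "-", sp))
}

#' Simulate the transcriptional network by the Gillespie algorithm
#'
#' Exact SSA over \code{[t0, t1]}; the trajectory is piecewise constant
#' between events. The returned matrix holds the initial state, one row per
#' reaction event and a final stamp at \code{t1}.
#'
#' @param initial named numeric counts \code{R,T,G,P,X,N}.
#' @param t0,t1 interval in hours, \code{t0 <= t1}.
#' @param params a [GRNParameters-class] object.
#' @param seed integer seed of the trajectory's RNG stream.
#' @return numeric matrix with columns \code{time_h, R, T, G, P, X, N}.
#' @examples
#' traj <- simulateGRN(geneState(), 0, 5, seed = 1)
#' head(traj)
#' @export
simulateGRN <- function(initial, t0 = 0, t1, params = grnParameters(),
                        seed = 1L) {
    initial <- checkState(initial)
    validObject(params)
    if (t0 > t1) stop("'t0' must not exceed 't1'")
    simulateGRNCpp(initial, t0, t1, params@p, params@gamma,
                   params@kdFactor, params@kdFactor, Inf, as.integer(seed))
}

#' Deterministic rate-equation solution of the transcriptional network
#'
#' Integrates the network's rate equations treating counts as real numbers
#' (lsoda, relative tolerance 1e-8). This mode exists for validation of the
#' stochastic simulator and for knockdown sanity checks; it is never used
#' inside colony simulation.
#'
#' @param initial named numeric initial values \code{R,T,G,P,X,N} (reals).
#' @param times numeric vector of output times (hours).
#' @param params a [GRNParameters-class] object.
#' @return matrix with columns \code{time_h, R, T, G, P, X, N}.
#' @examples
#' integrateODE(geneState(), seq(0, 10, by = 1))
#' @export
integrateODE <- function(initial, times, params = grnParameters()) {
    validObject(params)
    if (length(initial) != 6L) stop("'initial' must have length 6")
    names(initial) <- GENE_NAMES
    kd <- params@kdFactor
    deriv <- function(t, y, parms) {
        pr <- grnPropensitiesCpp(pmax(y, 0), params@p, params@gamma, kd)
        list(pr$production - pr$degradation)
    }
    sol <- deSolve::ode(y = initial, times = times, func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-8, atol = 1e-10)
    if (attr(sol, "istate")[1L] < 0) stop("ODE integration failed")
    m <- unclass(sol)
    colnames(m) <- c("time_h", GENE_NAMES)
    m[, , drop = FALSE]
}

#' Export a trajectory matrix as CSV
#'
#' @param traj matrix from [simulateGRN()], [evolveRegion()] or
#'   [integrateODE()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTrajectoryCSV <- function(traj, path) {
    utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
    invisible(path)
}
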