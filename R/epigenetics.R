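checkRegion <- function(region, params) {
    if (length(region) != 3L)
        stop("'region' must have the three site classes C,I,O")
    if (is.null(names(region))) names(region) <- REGION_NAMES
    region <- region[REGION_NAMES]
    if (any(is.na(region)) || any(region < 0) || any(region != round(region)))
        stop("site counts must be non-negative integers")
    if (sum(region) != params@sites)
        stop(sprintf("site counts must sum to the site total (%d)",
                     params@sites))
    region
}

#' Propensities of the nine regulatory-site transition channels
#'
#' The site model is an attempt-rate (extended Gillespie) scheme: each
#' channel's weight is the rate at which the region attempts that
#' transition, and a uniformly chosen site must be in the source state for
#' the attempt to succeed; mediated channels additionally require a
#' uniformly chosen mediator site to match. The effective propensities are
#' therefore weights times state fractions: O to I at \code{k1 X O/S}, I to
#' C at \code{k1 X I/S}, C to I at \code{(k2 N + k3 R) C/S}, I to O at
#' \code{(k2 N + k3 R) I/S}; mediated: O to I at \code{alpha (O/S)(C/S)},
#' I to C at \code{beta (I/S)(C/S)}, I to O at \code{gammaM (I/S)(O/S)},
#' C to I at \code{delta (C/S)(O/S)} and I to C at
#' \code{epsilon (I/S)(I/S)}. Sites never transition directly between O
#' and C.
#'
#' @param region named counts \code{C,I,O}.
#' @param inputs named numeric with elements \code{X}, \code{R}, \code{N}
#'   (current transcriptional-level counts).
#' @param params an [EpigeneticParameters-class] object.
#' @return data.frame with columns from, to, mediator, propensity (h^-1).
#' @examples
#' channelPropensities(regulatoryRegion(), c(X = 8, R = 1, N = 7))
#' @export
channelPropensities <- function(region, inputs,
                                params = epigeneticParameters()) {
    validObject(params)
    region <- checkRegion(region, params)
    if (any(is.na(inputs[c("X", "R", "N")])))
        stop("'inputs' must provide X, R and N")
    w <- epiChannelPropensitiesCpp(as.numeric(region), params@sites,
                                   inputs[["X"]], inputs[["R"]],
                                   inputs[["N"]], params@rates)
    data.frame(
        from = c("O", "I", "C", "I", "O", "I", "I", "C", "I"),
        to = c("I", "C", "I", "O", "I", "C", "O", "I", "C"),
        mediator = c(NA, NA, NA, NA, "C", "C", "O", "O", "I"),
        rate = c("k1*X", "k1*X", "k2*N+k3*R", "k2*N+k3*R", "alpha", "beta",
                 "gammaM", "delta", "epsilon"),
        propensity = as.numeric(w))
}

#' One extended-Gillespie step of the regulatory region
#'
#' Selects a channel proportionally to its propensity, moves one site from
#' the channel's source class to its target class and advances time by an
#' exponential waiting time; the total site count is conserved. Uses R's
#' RNG; seed with [set.seed()].
#'
#' @inheritParams channelPropensities
#' @param t current time (hours).
#' @param tMax censoring time.
#' @return list with \code{region}, \code{t} and \code{channel} (row index
#'   into [channelPropensities()], or NA if censored).
#' @export
epigeneticStep <- function(region, inputs, params = epigeneticParameters(),
                           t, tMax) {
    ch <- channelPropensities(region, inputs, params)
    region <- checkRegion(region, params)
    a0 <- sum(ch$propensity)
    if (a0 <= 0) return(list(region = region, t = tMax, channel = NA_integer_))
    dt <- stats::rexp(1L, a0)
    if (t + dt > tMax)
        return(list(region = region, t = tMax, channel = NA_integer_))
    k <- sample.int(9L, 1L, prob = ch$propensity)
    region[ch$from[k]] <- region[[ch$from[k]]] - 1L
    region[ch$to[k]] <- region[[ch$to[k]]] + 1L
    list(region = region, t = t + dt, channel = k)
}

#' Evolve the regulatory region along a transcriptional trajectory
#'
#' Runs the extended Gillespie algorithm for the site model over
#' \code{[t0, t1]} with the inputs X, Runx1 and Notch read piecewise
#' constant from a transcriptional trajectory. At every input change the
#' waiting-time draw is restarted with updated propensities, which is exact
#' for piecewise-constant hazards by memorylessness.
#'
#' @param region named counts \code{C,I,O}.
#' @param grnTraj matrix from [simulateGRN()] covering \code{[t0, t1]}.
#' @param t0,t1 interval in hours.
#' @param params an [EpigeneticParameters-class] object.
#' @param seed integer seed of the region's RNG stream.
#' @param record return the full event trajectory (otherwise finals only).
#' @param maxRecord cap on recorded event rows.
#' @return list with \code{final} (named integer C,I,O), \code{nEvents} and,
#'   if \code{record}, \code{trajectory} (columns time_h, C, I, O).
#' @examples
#' traj <- simulateGRN(geneState(), 0, 5, seed = 1)
#' evolveRegion(regulatoryRegion(), traj, 0, 5, seed = 1)$final
#' @export
evolveRegion <- function(region, grnTraj, t0, t1,
                         params = epigeneticParameters(), seed = 1L,
                         record = FALSE, maxRecord = 2e6) {
    validObject(params)
    region <- checkRegion(region, params)
    if (t0 > t1) stop("'t0' must not exceed 't1'")
    if (!is.matrix(grnTraj) || ncol(grnTraj) != 7L)
        stop("'grnTraj' must be a 7-column trajectory matrix")
    tt <- grnTraj[, 1L]
    if (tt[1L] > t0 + 1e-9 || tt[length(tt)] < t1 - 1e-9)
        stop("'grnTraj' must cover the interval [t0, t1]")
    evolveRegionCpp(as.numeric(region), grnTraj, t0, t1, params@rates,
                    params@sites, as.integer(seed), record, maxRecord)
}

#' Is the regulatory region open?
#'
#' The region counts as open when the open-site fraction reaches the
#' configured threshold: with the defaults, 375 or more of 500 sites.
#'
#' @param region named counts \code{C,I,O}.
#' @param params an [EpigeneticParameters-class] object.
#' @return logical.
#' @examples
#' isRegionOpen(regulatoryRegion(C = 0, I = 125, O = 375))  # TRUE
#' @export
isRegionOpen <- function(region, params = epigeneticParameters()) {
    region <- checkRegion(region, params)
    region[["O"]] >= params@openFractionThreshold * params@sites
}

#' Region inheritance at cell division
#'
#' With the mother's final X above zero the daughter copies the mother's
#' site counts verbatim. With X = 0, every closed site becomes
#' intermediate, every intermediate site becomes intermediate or open with
#' probability one half each, and open sites stay open; realisations are
#' independent between the two daughters.
#'
#' @param region mother's final site counts \code{C,I,O}.
#' @param motherX mother's final X count.
#' @param params an [EpigeneticParameters-class] object.
#' @param seed integer seed of the daughter's RNG stream.
#' @return named integer daughter counts \code{C,I,O}.
#' @examples
#' inheritRegion(regulatoryRegion(500, 0, 0), motherX = 0, seed = 1)
#' @export
inheritRegion <- function(region, motherX, params = epigeneticParameters(),
                          seed = 1L) {
    region <- checkRegion(region, params)
    inheritRegionCpp(as.numeric(region), motherX, as.integer(seed))
}
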