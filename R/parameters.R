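# Default parameter values of the published model calibration.
# Transcriptional level: p1..p16 and degradation rates (h^-1).
DEFAULT_P <- c(p1 = 0.10, p2 = 1.00, p3 = 5.00, p4 = 1.00, p5 = 1.50,
               p6 = 0.01, p7 = 0.50, p8 = 0.70, p9 = 0.50, p10 = 1.00,
               p11 = 0.20, p12 = 2.50, p13 = 2.60, p14 = 2.00, p15 = 1.00,
               p16 = 0.01)
DEFAULT_GAMMA <- c(R = 0.15, T = 0.15, G = 0.23, P = 0.06, X = 0.02)
# Epigenetic level channel rates.
DEFAULT_EPI_RATES <- c(k1 = 0.28, k2 = 0.20, k3 = 0.20, alpha = 0.002,
                       beta = 0.002, gammaM = 0.0005, delta = 0.0005,
                       epsilon = 0.002)
# Proliferation level: per-generation division-time mean/sd (hours).
DEFAULT_DIV_MU <- c(34, 15, 13, 12, 12)
DEFAULT_DIV_SIGMA <- c(13, 5, 5, 4, 3)
# Initial ETP-like cell.
DEFAULT_STATE <- c(R = 1, T = 2, G = 1, P = 5, X = 8, N = 7)
DEFAULT_REGION <- c(C = 500L, I = 0L, O = 0L)

#' Construct transcriptional network parameters
#'
#' Defaults are the published calibration of the six-gene network: p1 = 0.10
#' ... p16 = 0.01 and degradation rates (h^-1) 0.15 (Runx1), 0.15 (Tcf7),
#' 0.23 (Gata3), 0.06 (PU.1), 0.02 (X); Notch does not decay.
#'
#' @param p named numeric \code{p1}..\code{p16}.
#' @param gamma named numeric degradation rates for \code{R,T,G,P,X}.
#' @param kdFactor named numeric production scaling per species (default 1).
#' @return a [GRNParameters-class] object.
#' @examples
#' grnParameters()
#' @export
grnParameters <- function(p = DEFAULT_P, gamma = DEFAULT_GAMMA,
                          kdFactor = c(R = 1, T = 1, G = 1, P = 1,
                                       X = 1, N = 1)) {
    new("GRNParameters", p = p, gamma = gamma, kdFactor = kdFactor)
}

#' Construct epigenetic region parameters
#'
#' Defaults: k1 = 0.28, k2 = 0.20, k3 = 0.20 (input-coupled channels),
#' alpha = beta = epsilon = 0.002, gammaM = delta = 0.0005 (mediated
#' channels), 500 sites, open threshold 0.75. \code{gammaM} is the mediated
#' I-to-O rate (named to avoid collision with the transcriptional-level
#' degradation rates).
#'
#' @param rates named numeric of the eight channel rates.
#' @param sites total number of regulatory sites.
#' @param openFractionThreshold fraction of open sites at or above which the
#'   whole region counts as open.
#' @return an [EpigeneticParameters-class] object.
#' @export
epigeneticParameters <- function(rates = DEFAULT_EPI_RATES, sites = 500L,
                                 openFractionThreshold = 0.75) {
    new("EpigeneticParameters", rates = rates,
        sites = as.integer(sites),
        openFractionThreshold = openFractionThreshold)
}

#' Construct the generation-dependent division-time model
#'
#' Defaults (hours): generation 0 mean 34 sd 13; generation 1: 15, 5;
#' generation 2: 13, 5; generation 3: 12, 4; generations >= 4: 12, 3.
#'
#' @param mu,sigma numeric length 5 (generations 0..3 and >= 4).
#' @return a [DivisionTimeModel-class] object.
#' @export
divisionTimeModel <- function(mu = DEFAULT_DIV_MU,
                              sigma = DEFAULT_DIV_SIGMA) {
    new("DivisionTimeModel", mu = as.numeric(mu), sigma = as.numeric(sigma))
}

#' Construct a knockdown specification
#'
#' @param gene one of \code{"Runx1"}, \code{"Tcf7"}, \code{"Gata3"},
#'   \code{"PU.1"}.
#' @param factor production scaling in (0, 1]; the conventional knockdown
#'   strength is 0.2 (production reduced to 20 percent).
#' @param onset time (hours) at which the knockdown is applied; 0 also
#'   scales the gene's initial count.
#' @return a [KnockdownSpec-class] object.
#' @examples
#' knockdownSpec("Tcf7")
#' @export
knockdownSpec <- function(gene, factor = 0.2, onset = 0) {
    new("KnockdownSpec", gene = gene, factor = factor, onset = onset)
}

#' Construct a gene state vector
#'
#' @param R,T,G,P,X,N non-negative integer molecule counts; defaults are the
#'   ETP-like initial cell (1, 2, 1, 5, 8, 7).
#' @return named numeric of length 6.
#' @export
geneState <- function(R = 1, T = 2, G = 1, P = 5, X = 8, N = 7) {
    s <- c(R = R, T = T, G = G, P = P, X = X, N = N)
    if (any(!is.finite(s)) || any(s < 0) || any(s != round(s)))
        stop("gene counts must be non-negative integers")
    s
}

#' Construct a regulatory-region state vector
#'
#' @param C,I,O non-negative closed/intermediate/open site counts; the
#'   default region is fully closed (500, 0, 0).
#' @return named integer of length 3.
#' @export
regulatoryRegion <- function(C = 500, I = 0, O = 0) {
    r <- c(C = C, I = I, O = O)
    if (any(!is.finite(r)) || any(r < 0) || any(r != round(r)))
        stop("site counts must be non-negative integers")
    as.integer(r) |> stats::setNames(REGION_NAMES)
}

#' Construct a full colony simulation configuration
#'
#' Defaults reproduce the wild-type setup end to end: published parameter
#' values on all three levels, the ETP-like initial cell (R = 1, T = 2,
#' G = 1, P = 5, X = 8, N = 7), a fully closed 500-site region and a 120 h
#' horizon.
#'
#' @param grn a [GRNParameters-class] object.
#' @param epigenetic an [EpigeneticParameters-class] object.
#' @param division a [DivisionTimeModel-class] object.
#' @param initialState named numeric counts \code{R,T,G,P,X,N}.
#' @param initialRegion named counts \code{C,I,O} summing to the site total.
#' @param horizon colony horizon in hours.
#' @param knockdown optional [KnockdownSpec-class].
#' @param keepTrajectories store per-cell trajectories (memory-hungry).
#' @return a [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(horizon = 60)
#' @export
simulationConfig <- function(grn = grnParameters(),
                             epigenetic = epigeneticParameters(),
                             division = divisionTimeModel(),
                             initialState = geneState(),
                             initialRegion = regulatoryRegion(),
                             horizon = 120,
                             knockdown = NULL,
                             keepTrajectories = FALSE) {
    new("SimulationConfig", grn = grn, epigenetic = epigenetic,
        division = division, initialState = initialState,
        initialRegion = as.integer(initialRegion) |>
            stats::setNames(REGION_NAMES),
        horizon = horizon, knockdown = knockdown,
        keepTrajectories = keepTrajectories)
}

#' Apply a knockdown to parameters (and optionally the cell state)
#'
#' Sets the production scaling factor of \code{gene} and, when
#' \code{scaleInitial}, multiplies the gene's molecule count by the same
#' factor, rounding to the nearest integer (ties away from zero).
#'
#' @param params a [GRNParameters-class] object.
#' @param state named numeric gene counts (\code{R,T,G,P,X,N}).
#' @param gene one of Runx1, Tcf7, Gata3, PU.1.
#' @param factor scaling in (0, 1].
#' @param scaleInitial also scale the gene's current count.
#' @return list with elements \code{params} and \code{state}.
#' @examples
#' kd <- applyKnockdown(grnParameters(), geneState(), "PU.1", 0.2,
#'                      scaleInitial = TRUE)
#' kd$state[["P"]]  # 5 * 0.2 = 1
#' @export
applyKnockdown <- function(params, state, gene, factor,
                           scaleInitial = FALSE) {
    if (!(is.character(gene) && length(gene) == 1L && gene %in% KD_GENES))
        stop(sprintf("unknown gene '%s'; knockdown targets are %s",
                     paste(gene, collapse = ","),
                     paste(KD_GENES, collapse = ", ")))
    if (!is.finite(factor) || factor <= 0 || factor > 1)
        stop("'factor' must lie in (0, 1]")
    key <- names(GENE_LABELS)[match(gene, GENE_LABELS)]
    params@kdFactor[key] <- params@kdFactor[[key]] * factor
    validObject(params)
    if (scaleInitial) {
        # round half away from zero (sign irrelevant for counts >= 0)
        state[key] <- floor(state[[key]] * factor + 0.5)
    }
    list(params = params, state = state)
}

kdGeneKey <- function(gene) names(GENE_LABELS)[match(gene, GENE_LABELS)]

#' @describeIn GRNParameters-class compact display
#' @param object a \code{GRNParameters} object
#' @export
setMethod("show", "GRNParameters", function(object) {
    cat("GRNParameters: 16 regulation parameters, degradation (h^-1):\n")
    print(object@gamma)
    if (any(object@kdFactor != 1)) {
        cat("production scaling:\n")
        print(object@kdFactor[object@kdFactor != 1])
    }
    invisible(object)
})

#' @describeIn EpigeneticParameters-class compact display
#' @param object an \code{EpigeneticParameters} object
#' @export
setMethod("show", "EpigeneticParameters", function(object) {
    cat(sprintf("EpigeneticParameters: %d sites, open threshold %.2f\n",
                object@sites, object@openFractionThreshold))
    print(object@rates)
    invisible(object)
})

#' @describeIn SimulationConfig-class compact display
#' @param object a \code{SimulationConfig} object
#' @export
setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf("SimulationConfig: horizon %g h, %d sites\n",
                object@horizon, object@epigenetic@sites))
    cat("initial state: ")
    cat(paste(names(object@initialState), object@initialState, sep = "=",
              collapse = " "), "\n")
    if (!is.null(object@knockdown)) {
        kd <- object@knockdown
        cat(sprintf("knockdown: %s to %g%% at %g h\n", kd@gene,
                    100 * kd@factor, kd@onset))
    }
    invisible(object)
})
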