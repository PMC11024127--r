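#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib tcellsim, .registration = TRUE
NULL

GENE_NAMES <- c("R", "T", "G", "P", "X", "N")
GENE_LABELS <- c(R = "Runx1", T = "Tcf7", G = "Gata3", P = "PU.1",
                 X = "X", N = "Notch")
REGION_NAMES <- c("C", "I", "O")
KD_GENES <- c("Runx1", "Tcf7", "Gata3", "PU.1")

#' Transcriptional network parameters
#'
#' Holds the sixteen dimensionless regulation parameters of the Shea-Ackers
#' production functions, the five first-order degradation rates (per hour;
#' the Notch signal has no decay channel), and a per-gene multiplicative
#' production scaling used by knockdown protocols.
#'
#' @slot p named numeric, \code{p1}..\code{p16}.
#' @slot gamma named numeric degradation rates for \code{R,T,G,P,X} (h^-1).
#' @slot kdFactor named numeric production scaling per species, in (0, 1].
#' @seealso [grnParameters()]
#' @export
setClass("GRNParameters",
    representation(p = "numeric", gamma = "numeric", kdFactor = "numeric"))

setValidity("GRNParameters", function(object) {
    msg <- character()
    if (length(object@p) != 16L ||
        !identical(names(object@p), paste0("p", 1:16)))
        msg <- c(msg, "'p' must be a named numeric p1..p16")
    if (length(object@gamma) != 5L ||
        !identical(names(object@gamma), GENE_NAMES[1:5]))
        msg <- c(msg, "'gamma' must be named R,T,G,P,X")
    if (length(object@kdFactor) != 6L ||
        !identical(names(object@kdFactor), GENE_NAMES))
        msg <- c(msg, "'kdFactor' must be named R,T,G,P,X,N")
    if (!all(is.finite(object@p)) || any(object@p <= 0))
        msg <- c(msg, "all regulation parameters must be strictly positive")
    if (!all(is.finite(object@gamma)) || any(object@gamma <= 0))
        msg <- c(msg, "all degradation rates must be strictly positive")
    if (!all(is.finite(object@kdFactor)) || any(object@kdFactor <= 0) ||
        any(object@kdFactor > 1))
        msg <- c(msg, "'kdFactor' entries must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Epigenetic region parameters
#'
#' Rates of the nine transition channels of the three-state (closed /
#' intermediate / open) regulatory-site model, the total number of sites,
#' and the open-fraction threshold at which the whole region counts as open.
#'
#' @slot rates named numeric: \code{k1,k2,k3} (input-coupled channels) and
#'   \code{alpha,beta,gammaM,delta,epsilon} (mediated channels).
#' @slot sites integer, total number of regulatory sites.
#' @slot openFractionThreshold numeric in (0, 1].
#' @seealso [epigeneticParameters()]
#' @export
setClass("EpigeneticParameters",
    representation(rates = "numeric", sites = "integer",
                   openFractionThreshold = "numeric"))

EPI_RATE_NAMES <- c("k1", "k2", "k3", "alpha", "beta", "gammaM", "delta",
                    "epsilon")

setValidity("EpigeneticParameters", function(object) {
    msg <- character()
    if (length(object@rates) != 8L ||
        !identical(names(object@rates), EPI_RATE_NAMES))
        msg <- c(msg, "'rates' must be named k1,k2,k3,alpha,beta,gammaM,delta,epsilon")
    if (!all(is.finite(object@rates)) || any(object@rates < 0))
        msg <- c(msg, "all rates must be finite and non-negative")
    if (length(object@sites) != 1L || is.na(object@sites) || object@sites < 1L)
        msg <- c(msg, "'sites' must be a positive integer")
    thr <- object@openFractionThreshold
    if (length(thr) != 1L || !is.finite(thr) || thr <= 0 || thr > 1)
        msg <- c(msg, "'openFractionThreshold' must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Generation-dependent division-time model
#'
#' Division times are Gaussian per generation, resampled until strictly
#' positive; generations beyond the last tabulated row reuse that row.
#'
#' @slot mu numeric means (hours) for generations 0, 1, 2, 3 and >= 4.
#' @slot sigma numeric standard deviations (hours), same length as mu.
#' @seealso [divisionTimeModel()], [drawDivisionTime()]
#' @export
setClass("DivisionTimeModel", representation(mu = "numeric", sigma = "numeric"))

setValidity("DivisionTimeModel", function(object) {
    msg <- character()
    if (length(object@mu) != 5L || length(object@sigma) != 5L)
        msg <- c(msg, "'mu' and 'sigma' must have length 5 (g = 0..3, g >= 4)")
    if (!all(is.finite(object@mu)) || any(object@mu <= 0))
        msg <- c(msg, "'mu' must be strictly positive")
    if (!all(is.finite(object@sigma)) || any(object@sigma < 0))
        msg <- c(msg, "'sigma' must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Knockdown specification
#'
#' A knockdown multiplies the production propensity of one gene by
#' \code{factor}. With \code{onset = 0} the gene's initial molecule count is
#' scaled by the same factor (rounded to the nearest integer, ties away from
#' zero); a delayed knockdown (\code{onset > 0}) changes only the production
#' factor of all live cells from the onset time on.
#'
#' @slot gene one of Runx1, Tcf7, Gata3, PU.1.
#' @slot factor numeric in (0, 1].
#' @slot onset hours, >= 0.
#' @seealso [knockdownSpec()], [applyKnockdown()]
#' @export
setClass("KnockdownSpec",
    representation(gene = "character", factor = "numeric", onset = "numeric"))

setValidity("KnockdownSpec", function(object) {
    msg <- character()
    if (length(object@gene) != 1L || !(object@gene %in% KD_GENES))
        msg <- c(msg, sprintf("'gene' must be one of %s",
                              paste(KD_GENES, collapse = ", ")))
    if (length(object@factor) != 1L || !is.finite(object@factor) ||
        object@factor <= 0 || object@factor > 1)
        msg <- c(msg, "'factor' must lie in (0, 1]")
    if (length(object@onset) != 1L || !is.finite(object@onset) ||
        object@onset < 0)
        msg <- c(msg, "'onset' must be a non-negative time in hours")
    if (length(msg)) msg else TRUE
})

#' Full colony simulation configuration
#'
#' Bundles the parameters of all three model levels with the initial cell
#' state, the colony horizon and an optional knockdown.
#'
#' @slot grn a [GRNParameters-class] object.
#' @slot epigenetic an [EpigeneticParameters-class] object.
#' @slot division a [DivisionTimeModel-class] object.
#' @slot initialState named numeric molecule counts \code{R,T,G,P,X,N}.
#' @slot initialRegion named integer site counts \code{C,I,O}.
#' @slot horizon colony horizon in hours.
#' @slot knockdown a [KnockdownSpec-class] or \code{NULL}.
#' @slot keepTrajectories logical; store per-cell trajectories in the tree
#'   metadata (memory-hungry, off by default).
#' @seealso [simulationConfig()], [simulateColony()]
#' @export
setClass("SimulationConfig",
    representation(grn = "GRNParameters", epigenetic = "EpigeneticParameters",
                   division = "DivisionTimeModel", initialState = "numeric",
                   initialRegion = "integer", horizon = "numeric",
                   knockdown = "ANY", keepTrajectories = "logical"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    st <- object@initialState
    if (length(st) != 6L || !identical(names(st), GENE_NAMES))
        msg <- c(msg, "'initialState' must be named R,T,G,P,X,N")
    else if (any(!is.finite(st)) || any(st < 0) || any(st != round(st)))
        msg <- c(msg, "'initialState' must be non-negative integer counts")
    rg <- object@initialRegion
    if (length(rg) != 3L || !identical(names(rg), REGION_NAMES))
        msg <- c(msg, "'initialRegion' must be named C,I,O")
    else {
        if (any(is.na(rg)) || any(rg < 0))
            msg <- c(msg, "'initialRegion' counts must be non-negative")
        else if (sum(rg) != object@epigenetic@sites)
            msg <- c(msg, "'initialRegion' must sum to the configured site total")
    }
    if (length(object@horizon) != 1L || !is.finite(object@horizon) ||
        object@horizon < 0)
        msg <- c(msg, "'horizon' must be a non-negative time in hours")
    if (!is.null(object@knockdown)) {
        if (!is(object@knockdown, "KnockdownSpec"))
            msg <- c(msg, "'knockdown' must be a KnockdownSpec or NULL")
        else if (object@knockdown@onset >= object@horizon &&
                 object@horizon > 0 && object@knockdown@onset > 0)
            msg <- c(msg, "knockdown onset must precede the horizon")
    }
    if (length(msg)) msg else TRUE
})

#' Simulated lineage tree of one cell colony
#'
#' A strictly binary rooted tree of cells. Each row of the cell table is one
#' cell with its lineage links, timing and end-of-life (final, before
#' division) molecule counts and regulatory-site counts. Classification with
#' [classifyTree()] adds per-cell status and LCA-category columns.
#'
#' @slot cells data.frame with columns id, parent, generation, birth, end,
#'   cause ("divided"/"censored"), R, T, G, P, X, N, C, I, O and, after
#'   classification, status, category, order.
#' @slot horizon colony horizon in hours.
#' @slot seed integer root seed the colony was simulated with (NA for
#'   constructed/parsed trees).
#' @slot sites total number of regulatory sites.
#' @slot openThreshold open-fraction threshold defining an open region.
#' @slot metadata list of optional extras (config echo, trajectories).
#' @export
setClass("LineageTree",
    representation(cells = "data.frame", horizon = "numeric",
                   seed = "integer", sites = "integer",
                   openThreshold = "numeric", metadata = "list"))

setValidity("LineageTree", function(object) {
    df <- object@cells
    need <- c("id", "parent", "generation", "birth", "end", "cause",
              GENE_NAMES, REGION_NAMES)
    if (!all(need %in% names(df)))
        return(sprintf("cell table lacks columns: %s",
                       paste(setdiff(need, names(df)), collapse = ", ")))
    if (anyDuplicated(df$id)) return("cell ids must be unique")
    rootRow <- which(is.na(df$parent))
    if (length(rootRow) != 1L) return("tree must have exactly one root")
    if (!all(df$parent[-rootRow] %in% df$id))
        return("every non-root parent id must exist")
    nk <- table(factor(df$parent[-rootRow], levels = df$id))
    if (!all(nk %in% c(0L, 2L))) return("tree must be strictly binary")
    divided <- df$cause == "divided"
    if (!all((nk == 2L) == divided))
        return("children exist iff the cell divided")
    idx <- match(df$parent, df$id)
    ok <- is.na(idx) |
        (abs(df$birth - df$end[idx]) < 1e-9 &
         df$generation == df$generation[idx] + 1L)
    if (!all(ok))
        return("child birth must equal parent end and generation must increment")
    if (any(df$end < df$birth)) return("cell end time must be >= birth time")
    TRUE
})
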