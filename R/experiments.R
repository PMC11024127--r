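# In silico experiment drivers: wild-type ensemble statistics, knockdown
# protocols and the commitment-delay analysis.

#' Wild-type ensemble report
#'
#' Simulates \code{n} identically initialised colonies and gathers the
#' population-level statistics: the division-count histogram, the
#' distribution of the fraction of open cells per colony grouped by colony
#' size, and the pooled per-LCA-category expression table.
#'
#' @param n number of colonies.
#' @param config a [SimulationConfig-class] object.
#' @param seed base seed.
#' @return list with \code{summary} (per colony), \code{divisionCounts}
#'   (table), \code{fractionOpenBySize} (data.frame), \code{categories}
#'   (from [categoryStatistics()]), \code{delay} (from
#'   [delayStatistics()]) and \code{trees}.
#' @examples
#' rep <- wtReport(2, simulationConfig(horizon = 40), seed = 1)
#' rep$summary
#' @export
wtReport <- function(n, config = simulationConfig(), seed = 1L) {
    ens <- runEnsemble(n, config, baseSeed = seed, classify = TRUE)
    s <- ens$summary
    list(summary = s,
         divisionCounts = table(divisions = s$divisions),
         fractionOpenBySize = s[c("colony", "divisions", "fractionOpen")],
         categories = categoryStatistics(ens$trees),
         delay = delayStatistics(ens$trees),
         trees = ens$trees)
}

#' Knockdown experiment
#'
#' Runs an ensemble under a knockdown. With onset 0 the gene's production
#' factor and initial count are scaled before simulation; with a later
#' onset, colonies evolve normally until the onset time, after which the
#' production factor applies to all live cells (and their descendants) for
#' the remainder of the run.
#'
#' @param spec a [KnockdownSpec-class] object.
#' @param n number of colonies.
#' @param config a [SimulationConfig-class] object (its knockdown slot is
#'   replaced by \code{spec}).
#' @param seed base seed.
#' @return list as in [wtReport()] (without the category table).
#' @examples
#' kd <- knockdownExperiment(knockdownSpec("PU.1"), 2,
#'                           simulationConfig(horizon = 40), seed = 1)
#' @export
knockdownExperiment <- function(spec, n, config = simulationConfig(),
                                seed = 1L) {
    validObject(spec)
    if (spec@onset < config@horizon) config@knockdown <- spec
    ens <- runEnsemble(n, config, baseSeed = seed, classify = FALSE)
    s <- ens$summary
    list(spec = spec, summary = s,
         divisionCounts = table(divisions = s$divisions),
         fractionOpenBySize = s[c("colony", "divisions", "fractionOpen")],
         trees = ens$trees)
}

#' Delayed-knockdown series
#'
#' One knockdown experiment per onset time, all with the same base seed
#' handling so that runs are reproducible. An onset at or beyond the
#' horizon degenerates to a wild-type run.
#'
#' @param gene knockdown target.
#' @param onsets sorted numeric onset times (hours).
#' @param nPerOnset colonies per onset.
#' @param config a [SimulationConfig-class] object.
#' @param seed base seed.
#' @param factor production scaling (default 0.2).
#' @return list with one [knockdownExperiment()] result per onset plus a
#'   \code{byOnset} summary data.frame (median fraction open, median
#'   colony-mean X).
#' @export
delayedKDSeries <- function(gene, onsets, nPerOnset,
                            config = simulationConfig(), seed = 1L,
                            factor = 0.2) {
    if (is.unsorted(onsets)) stop("'onsets' must be sorted")
    runs <- lapply(seq_along(onsets), function(k) {
        knockdownExperiment(knockdownSpec(gene, factor, onsets[k]),
                            nPerOnset, config,
                            seed = as.integer(seed) + 7919L * (k - 1L))
    })
    byOnset <- data.frame(
        onset = onsets,
        medianFractionOpen = vapply(runs, function(r)
            stats::median(r$summary$fractionOpen), 0),
        medianMeanX = vapply(runs, function(r)
            stats::median(r$summary$meanX), 0))
    list(gene = gene, runs = runs, byOnset = byOnset)
}

#' Commitment-delay statistics
#'
#' For every committed lineage the X-loss cell is the earliest cell on the
#' path from the root to an open cell whose end-of-life X is 0 while its
#' mother's was positive (the root qualifies if it ends with X = 0). Each
#' distinct X-loss cell contributes once per colony: its delay is the
#' minimal generation distance to an open descendant, and its LCA order is
#' recorded where the cell is an LCA. Trees without open cells contribute
#' nothing.
#'
#' @param trees a classified [LineageTree-class] object or list of them.
#' @return list with \code{delays} (integer vector), \code{lcaOrders}
#'   (integer vector over X-loss cells that are LCAs), \code{meanDelay}
#'   and \code{modalLCAOrder}.
#' @export
delayStatistics <- function(trees) {
    if (is(trees, "LineageTree")) trees <- list(trees)
    delays <- integer(0)
    orders <- integer(0)
    for (tr in trees) {
        df <- tr@cells
        if (!"category" %in% names(df)) tr <- classifyTree(tr)
        df <- tr@cells
        open <- df$status == "open"
        if (!any(open)) next
        pidx <- match(df$parent, df$id)
        lossPoint <- df$X == 0 & (is.na(pidx) | df$X[pidx] > 0)
        m <- minOpenDepth(tr)
        # earliest loss point on each root-to-open path: top-down propagation
        # of the first qualifying ancestor
        firstLoss <- rep(NA_integer_, nrow(df))
        for (i in order(df$generation)) {
            p <- pidx[i]
            inherited <- if (is.na(p)) NA_integer_ else firstLoss[p]
            firstLoss[i] <- if (!is.na(inherited)) inherited
                            else if (lossPoint[i]) i else NA_integer_
        }
        lossCells <- unique(firstLoss[open & !is.na(firstLoss)])
        delays <- c(delays, as.integer(m[lossCells]))
        isLCA <- df$category[lossCells] == "LCA"
        orders <- c(orders, df$order[lossCells][isLCA])
    }
    modal <- if (length(orders)) {
        tab <- table(orders)
        as.integer(names(tab)[which.max(tab)])
    } else NA_integer_
    list(delays = delays, lcaOrders = orders,
         meanDelay = if (length(delays)) mean(delays) else NA_real_,
         modalLCAOrder = modal)
}

#' Tcf7-versus-PU.1 switch heuristic
#'
#' Descriptive marker of the preparatory transcriptional switch towards
#' the T-cell fate: for a lineage (path from root to a cell), the first
#' generation at which the final Tcf7 count exceeds the final PU.1 count
#' and stays above it until the end of the lineage; NA if never.
#'
#' @param tree a [LineageTree-class] object.
#' @param id id of the lineage's terminal cell.
#' @return integer generation, or NA.
#' @export
switchGeneration <- function(tree, id) {
    df <- tree@cells
    i <- match(id, df$id)
    if (is.na(i)) stop("unknown cell id")
    path <- integer(0)
    while (!is.na(i)) {
        path <- c(i, path)
        i <- match(df$parent[path[1L]], df$id)
    }
    above <- df$T[path] > df$P[path]
    sustained <- rev(cumprod(rev(above))) > 0
    if (!any(sustained)) return(NA_integer_)
    df$generation[path[which.max(sustained)]]
}
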