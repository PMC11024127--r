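#' Draw generation-dependent division times
#'
#' Gaussian draw with the generation's mean and standard deviation (the
#' last tabulated row serves all later generations), resampled until
#' strictly positive.
#'
#' @param generation integer >= 0.
#' @param model a [DivisionTimeModel-class] object.
#' @param n number of draws.
#' @param seed integer seed.
#' @return numeric vector of division times (hours).
#' @examples
#' mean(drawDivisionTime(0, n = 1000, seed = 1))
#' @export
drawDivisionTime <- function(generation, model = divisionTimeModel(),
                             n = 1L, seed = 1L) {
    validObject(model)
    if (generation < 0) stop("'generation' must be >= 0")
    drawDivisionTimesCpp(as.integer(generation), model@mu, model@sigma,
                         as.integer(n), as.integer(seed))
}

kdSchedule <- function(config) {
    base <- config@grn@kdFactor
    kd <- config@knockdown
    if (is.null(kd))
        return(list(pre = base, post = base, onset = Inf))
    post <- base
    post[kdGeneKey(kd@gene)] <- post[[kdGeneKey(kd@gene)]] * kd@factor
    if (kd@onset <= 0)
        list(pre = post, post = post, onset = Inf)
    else
        list(pre = base, post = post, onset = kd@onset)
}

initialStateWithKD <- function(config) {
    st <- config@initialState
    kd <- config@knockdown
    if (!is.null(kd) && kd@onset <= 0) {
        key <- kdGeneKey(kd@gene)
        st[key] <- floor(st[[key]] * kd@factor + 0.5)
    }
    st
}

#' Simulate one cell's lifetime
#'
#' Applies the region inheritance rule (for non-root cells), draws the
#' division time for the cell's generation, runs the transcriptional SSA
#' over the lifetime and then the epigenetic SSA driven by it. The cell is
#' censored at the colony horizon if its drawn division time would pass it.
#'
#' @param state named numeric birth counts \code{R,T,G,P,X,N}.
#' @param motherRegion mother's final site counts (or the initial region
#'   for the root).
#' @param motherX mother's final X count (ignored for the root).
#' @param isRoot logical; the root copies \code{motherRegion} verbatim.
#' @param generation cell generation (root = 0).
#' @param birth birth time in hours.
#' @param config a [SimulationConfig-class] object.
#' @param seed root seed of the colony stream.
#' @param cellId integer id identifying the cell's RNG substream.
#' @param record return full trajectories.
#' @return list with \code{tDiv}, \code{end}, \code{divided},
#'   \code{finalState}, \code{finalRegion} and, if \code{record}, the two
#'   trajectories.
#' @export
simulateCellLifetime <- function(state, motherRegion, motherX = 1,
                                 isRoot = TRUE, generation = 0L, birth = 0,
                                 config = simulationConfig(), seed = 1L,
                                 cellId = 0L, record = FALSE) {
    validObject(config)
    sched <- kdSchedule(config)
    simulateCellCpp(checkState(state), as.numeric(motherRegion), motherX,
                    isRoot, as.integer(generation), birth, config@horizon,
                    config@grn@p, config@grn@gamma, sched$pre, sched$post,
                    sched$onset, config@epigenetic@rates,
                    config@epigenetic@sites, config@division@mu,
                    config@division@sigma, as.integer(seed),
                    as.integer(cellId), record, record)
}

newLineageTree <- function(cells, horizon, seed, sites, openThreshold,
                           metadata = list()) {
    cells <- cells[order(cells$id), , drop = FALSE]
    rownames(cells) <- NULL
    new("LineageTree", cells = cells, horizon = horizon,
        seed = as.integer(seed), sites = as.integer(sites),
        openThreshold = openThreshold, metadata = metadata)
}

#' Simulate a full cell colony
#'
#' Event-driven expansion from a single generation-0 cell: each cell's
#' lifetime is simulated to division or the colony horizon; divided cells
#' spawn two daughters that inherit the gene counts verbatim and the
#' regulatory-site counts according to the X-dependent inheritance rule.
#' Cell ids are heap-indexed (root 0, children of i are 2i+1 and 2i+2) and
#' each cell draws from its own RNG substream of \code{seed}, so results
#' are reproducible regardless of traversal order.
#'
#' @param config a [SimulationConfig-class] object.
#' @param seed integer root seed.
#' @return a [LineageTree-class] object.
#' @examples
#' tree <- simulateColony(simulationConfig(horizon = 40), seed = 1)
#' tree
#' @export
simulateColony <- function(config = simulationConfig(), seed = 1L) {
    validObject(config)
    seed <- as.integer(seed)
    sched <- kdSchedule(config)
    st0 <- initialStateWithKD(config)
    keep <- config@keepTrajectories
    epi <- config@epigenetic

    pending <- list(list(id = 0L, parent = NA_integer_, gen = 0L, birth = 0,
                         state = as.numeric(st0),
                         motherRegion = as.numeric(config@initialRegion),
                         motherX = 1, isRoot = TRUE))
    rows <- list()
    trajs <- if (keep) list() else NULL
    while (length(pending)) {
        task <- pending[[length(pending)]]
        pending[[length(pending)]] <- NULL
        res <- simulateCellCpp(task$state, task$motherRegion, task$motherX,
                               task$isRoot, task$gen, task$birth,
                               config@horizon, config@grn@p,
                               config@grn@gamma, sched$pre, sched$post,
                               sched$onset, epi@rates, epi@sites,
                               config@division@mu, config@division@sigma,
                               seed, task$id, keep, keep)
        fs <- res$finalState
        fr <- res$finalRegion
        rows[[length(rows) + 1L]] <- c(
            task$id, task$parent, task$gen, task$birth, res$end,
            as.numeric(res$divided), as.numeric(fs), as.numeric(fr))
        if (keep)
            trajs[[as.character(task$id)]] <-
                list(grn = res$grnTrajectory, region = res$regionTrajectory)
        if (res$divided) {
            for (childId in c(2L * task$id + 1L, 2L * task$id + 2L)) {
                pending[[length(pending) + 1L]] <- list(
                    id = childId, parent = task$id, gen = task$gen + 1L,
                    birth = res$end, state = as.numeric(fs),
                    motherRegion = as.numeric(fr), motherX = fs[["X"]],
                    isRoot = FALSE)
            }
        }
    }
    m <- do.call(rbind, rows)
    cells <- data.frame(
        id = as.integer(m[, 1L]), parent = as.integer(m[, 2L]),
        generation = as.integer(m[, 3L]), birth = m[, 4L], end = m[, 5L],
        cause = ifelse(m[, 6L] > 0, "divided", "censored"),
        R = m[, 7L], T = m[, 8L], G = m[, 9L], P = m[, 10L], X = m[, 11L],
        N = m[, 12L], C = as.integer(m[, 13L]), I = as.integer(m[, 14L]),
        O = as.integer(m[, 15L]))
    cells <- cells[order(cells$id), , drop = FALSE]
    meta <- list(config = config)
    if (keep) meta$trajectories <- trajs
    tree <- newLineageTree(cells, config@horizon, seed, epi@sites,
                           epi@openFractionThreshold, meta)
    validObject(tree)
    tree
}

#' Simulate an ensemble of independent colonies
#'
#' @param n number of colonies (>= 1).
#' @param config a [SimulationConfig-class] object.
#' @param baseSeed integer; per-colony seeds are derived deterministically.
#' @param classify also run [classifyTree()] on each tree.
#' @return list with \code{trees} (list of [LineageTree-class]) and
#'   \code{summary} (one row per colony; see [colonySummary()]).
#' @examples
#' ens <- runEnsemble(2, simulationConfig(horizon = 40), baseSeed = 1)
#' ens$summary
#' @export
runEnsemble <- function(n, config = simulationConfig(), baseSeed = 1L,
                        classify = FALSE) {
    if (n < 1) stop("'n' must be >= 1")
    seeds <- colonySeeds(baseSeed, n)
    trees <- lapply(seq_len(n), function(i) {
        tr <- simulateColony(config, seed = seeds[i])
        if (classify) tr <- classifyTree(tr)
        tr
    })
    summary <- do.call(rbind, lapply(trees, colonySummary))
    summary$colony <- seq_len(n)
    list(trees = trees, summary = summary)
}

# deterministic 31-bit per-colony seeds from one base seed
colonySeeds <- function(baseSeed, n) {
    as.integer((as.double(baseSeed) + 1664525 * seq_len(n)) %% 2147483647)
}

#' Per-colony summary statistics
#'
#' Leaves of a simulated tree are exactly the cells censored at the
#' horizon, i.e. the cells alive at the end of the experiment; the open
#' fraction and mean X are computed over them.
#'
#' @param tree a [LineageTree-class] object.
#' @return one-row data.frame: seed, nCells, nLeaves, divisions (maximum
#'   generation reached), fractionOpen, meanX, anyOpen.
#' @export
colonySummary <- function(tree) {
    df <- tree@cells
    leaf <- df$cause == "censored"
    open <- df$O >= tree@openThreshold * tree@sites
    data.frame(seed = tree@seed, nCells = nrow(df), nLeaves = sum(leaf),
               divisions = max(df$generation),
               fractionOpen = mean(open[leaf]),
               meanX = mean(df$X[leaf]),
               anyOpen = any(open[leaf]))
}
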