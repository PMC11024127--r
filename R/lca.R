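# Last-common-ancestor (LCA) classification of lineage trees.
#
# Category system: cells with an open region are "open". A closed cell with
# at least one open descendant in each of its two daughter branches is an
# LCA of order n, where n is the smaller of the two per-branch minimal
# generation distances to an open descendant. Remaining closed cells are
# "closed post-LCA m" if they have an LCA ancestor (m = generations below
# the most recent one) and "closed pre-LCA" otherwise.

#' Per-branch distance to the nearest open descendant
#'
#' For a divided cell, returns for each daughter branch the minimal
#' generation distance to an open descendant (a daughter that is itself
#' open is at distance 1); \code{Inf} where a branch contains none.
#'
#' @param tree a [LineageTree-class] object.
#' @param id cell id.
#' @return numeric of length 2 (or length 0 for a leaf).
#' @export
nearestOpenDistance <- function(tree, id) {
    df <- tree@cells
    i <- match(id, df$id)
    if (is.na(i)) stop("unknown cell id")
    m <- minOpenDepth(tree)
    kids <- childIndex(df)[[i]]
    if (length(kids) == 0L) return(numeric(0))
    1 + m[kids]
}

# minimal generation distance from each cell to an open cell in its own
# subtree (0 if the cell itself is open, Inf if none)
minOpenDepth <- function(tree) {
    df <- tree@cells
    open <- openCells(tree)
    kids <- childIndex(df)
    m <- rep(Inf, nrow(df))
    for (i in order(df$generation, decreasing = TRUE)) {
        if (open[i]) { m[i] <- 0; next }
        k <- kids[[i]]
        if (length(k)) m[i] <- 1 + min(m[k])
    }
    m
}

#' Classify every cell of a lineage tree into LCA categories
#'
#' Adds \code{status}, \code{category} (\code{"open"}, \code{"LCA"},
#' \code{"closed_pre_LCA"}, \code{"closed_post_LCA"}) and \code{order}
#' (the LCA order n, the post-LCA order m, otherwise NA) columns to the
#' cell table. The labels partition the tree: every cell receives exactly
#' one.
#'
#' @param tree a [LineageTree-class] object with region and X annotations.
#' @return the tree with classification columns added.
#' @examples
#' tree <- classifyTree(simulateColony(simulationConfig(horizon = 40), 1))
#' table(treeCells(tree)$category)
#' @export
classifyTree <- function(tree) {
    validObject(tree)
    df <- tree@cells
    status <- cellStatus(tree)
    open <- status == "open"
    kids <- childIndex(df)
    m <- minOpenDepth(tree)

    category <- rep(NA_character_, nrow(df))
    ord <- rep(NA_integer_, nrow(df))
    category[open] <- "open"
    for (i in which(!open)) {
        k <- kids[[i]]
        if (length(k) == 2L && all(is.finite(m[k])))  {
            category[i] <- "LCA"
            ord[i] <- as.integer(1 + min(m[k]))
        }
    }
    # top-down pass: distance to the most recent LCA ancestor
    pidx <- match(df$parent, df$id)
    dLCA <- rep(Inf, nrow(df))
    for (i in order(df$generation)) {
        p <- pidx[i]
        if (is.na(p)) next
        dLCA[i] <- if (identical(category[p], "LCA")) 1 else dLCA[p] + 1
    }
    rest <- is.na(category)
    category[rest & is.finite(dLCA)] <- "closed_post_LCA"
    ord[rest & is.finite(dLCA)] <- as.integer(dLCA[rest & is.finite(dLCA)])
    category[is.na(category)] <- "closed_pre_LCA"

    df$status <- status
    df$category <- category
    df$order <- ord
    tree@cells <- df
    tree
}

#' Reference LCA classifier by exhaustive enumeration
#'
#' Classifies each cell by directly enumerating all of its descendants
#' (per daughter branch) and all of its ancestors, straight from the
#' category definitions. Quadratic in tree size; intended as an
#' independent cross-check of [classifyTree()] on small trees.
#'
#' @param tree a [LineageTree-class] object.
#' @return data.frame with columns id, category, order.
#' @export
bruteForceLCA <- function(tree) {
    df <- tree@cells
    open <- openCells(tree)
    kids <- childIndex(df)
    n <- nrow(df)

    # all descendant rows of row i within the branch rooted at row k
    branchOpenDist <- function(k, gen0) {
        frontier <- k
        found <- Inf
        while (length(frontier)) {
            og <- df$generation[frontier][open[frontier]]
            if (length(og)) found <- min(found, min(og) - gen0)
            frontier <- unlist(kids[frontier])
        }
        found
    }
    isLCA <- rep(FALSE, n)
    ord <- rep(NA_integer_, n)
    category <- rep(NA_character_, n)
    for (i in seq_len(n)) {
        if (open[i]) { category[i] <- "open"; next }
        k <- kids[[i]]
        if (length(k) == 2L) {
            d1 <- branchOpenDist(k[1L], df$generation[i])
            d2 <- branchOpenDist(k[2L], df$generation[i])
            if (is.finite(d1) && is.finite(d2)) {
                isLCA[i] <- TRUE
                category[i] <- "LCA"
                ord[i] <- as.integer(min(d1, d2))
            }
        }
    }
    pidx <- match(df$parent, df$id)
    for (i in seq_len(n)) {
        if (!is.na(category[i])) next
        a <- pidx[i]; d <- 1L; best <- NA_integer_
        while (!is.na(a)) {
            if (isLCA[a]) { best <- d; break }
            a <- pidx[a]; d <- d + 1L
        }
        if (!is.na(best)) {
            category[i] <- "closed_post_LCA"; ord[i] <- best
        } else category[i] <- "closed_pre_LCA"
    }
    data.frame(id = df$id, category = category, order = ord)
}

#' Pooled per-category expression statistics
#'
#' Counts, means and standard deviations of the cells' final (before
#' division) gene counts and open-site fraction, pooled over a list of
#' classified trees and grouped by LCA category. Categories appear in
#' approximate developmental order: closed pre-LCA, LCA n (descending n),
#' open, then closed post-LCA m (ascending m). A category observed in a
#' single cell reports SD = NA.
#'
#' @param trees a [LineageTree-class] object or list of them, classified.
#' @return data.frame with count and mean/sd columns for R, T, G, P, X, N
#'   and the open-site fraction.
#' @export
categoryStatistics <- function(trees) {
    if (is(trees, "LineageTree")) trees <- list(trees)
    dfs <- lapply(trees, function(tr) {
        df <- tr@cells
        if (!"category" %in% names(df))
            stop("trees must be classified first (see classifyTree)")
        df$openFraction <- df$O / tr@sites
        df
    })
    pooled <- do.call(rbind, dfs)
    key <- ifelse(is.na(pooled$order), pooled$category,
                  paste(pooled$category, pooled$order))
    vars <- c(GENE_NAMES, "openFraction")
    stats <- lapply(split(pooled[vars], key), function(d) {
        c(count = nrow(d), vapply(d, mean, 0), sd = vapply(d, stats::sd, 0))
    })
    out <- as.data.frame(do.call(rbind, stats))
    names(out) <- c("count", paste0("mean_", vars), paste0("sd_", vars))
    out$category <- rownames(out)
    rownames(out) <- NULL
    # developmental ordering
    lab <- out$category
    ordn <- suppressWarnings(as.integer(sub("^.* ", "", lab)))
    rank <- ifelse(lab == "closed_pre_LCA", -1000,
            ifelse(grepl("^LCA", lab), -ordn,
            ifelse(lab == "open", 500, 1000 + ordn)))
    out <- out[order(rank), c("category", setdiff(names(out), "category"))]
    rownames(out) <- NULL
    out
}
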