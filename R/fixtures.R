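# Hand-specified annotated trees for tests and examples, plus a random
# labelled-tree generator used to stress the LCA classifier.

#' Construct an annotated lineage tree by hand
#'
#' Builds a schematic [LineageTree-class] from a parent vector and per-cell
#' open/X annotations. Every cell gets a 10 h lifetime, default gene counts
#' and a region of (0, 125, 375) if open, otherwise (400, 100, 0). Intended
#' for constructing classification fixtures, not for simulation output.
#'
#' @param parent integer vector; \code{parent[i]} is the 1-based index of
#'   cell i's mother, NA for the root.
#' @param open logical vector; is the cell's region open at end of life.
#' @param X numeric end-of-life X counts (default 1 for every cell).
#' @param sites,openThreshold region geometry (defaults 500 and 0.75).
#' @return a [LineageTree-class] object.
#' @examples
#' # closed root whose two daughters are both open
#' tr <- makeAnnotatedTree(c(NA, 1, 1), open = c(FALSE, TRUE, TRUE))
#' treeCells(classifyTree(tr))$category
#' @export
makeAnnotatedTree <- function(parent, open, X = rep(1, length(parent)),
                              sites = 500L, openThreshold = 0.75) {
    n <- length(parent)
    stopifnot(length(open) == n, length(X) == n)
    gen <- integer(n)
    for (i in seq_len(n))
        gen[i] <- if (is.na(parent[i])) 0L else gen[parent[i]] + 1L
    hasKids <- seq_len(n) %in% parent
    df <- data.frame(
        id = seq_len(n) - 1L,
        parent = ifelse(is.na(parent), NA_integer_,
                        as.integer(parent) - 1L),
        generation = gen, birth = 10 * gen, end = 10 * (gen + 1),
        cause = ifelse(hasKids, "divided", "censored"),
        R = 1, T = 2, G = 1, P = 5, X = X, N = 7,
        C = ifelse(open, 0L, 400L), I = ifelse(open, 125L, 100L),
        O = ifelse(open, 375L, 0L))
    tree <- newLineageTree(df, horizon = max(df$end), seed = NA_integer_,
                           sites = sites, openThreshold = openThreshold)
    validObject(tree)
    tree
}

#' Library of hand-built classification fixture trees
#'
#' Deterministic small annotated trees covering the canonical LCA
#' situations: a tree with no open cell, a fully open tree, an order-1 LCA
#' (closed root, both daughters open), an LCA whose two branches reach open
#' cells 5 and 6 generations down (order 5), and a lineage that passes from
#' LCA through closed post-LCA back to LCA again.
#'
#' @return named list of [LineageTree-class] objects.
#' @examples
#' names(fixtureTrees())
#' @export
fixtureTrees <- function() {
    out <- list()
    # all cells closed
    out$allClosed <- makeAnnotatedTree(c(NA, 1, 1, 2, 2),
                                       open = rep(FALSE, 5))
    # every cell open
    out$allOpen <- makeAnnotatedTree(c(NA, 1, 1), open = rep(TRUE, 3))
    # order-1 LCA: closed root, both daughters open
    out$order1 <- makeAnnotatedTree(c(NA, 1, 1), open = c(FALSE, TRUE, TRUE))
    # order 5 vs 6: two closed chains of different lengths, each ending open
    parent <- c(NA,                 # 1 root (the LCA)
                1, 2, 3, 4, 5,      # 2..6: left chain, cell 6 open (depth 5)
                1, 7, 8, 9, 10, 11, # 7..12: right chain, cell 12 open (depth 6)
                2, 3, 4, 5,         # padding siblings to keep the tree binary
                7, 8, 9, 10, 11)
    open <- rep(FALSE, length(parent))
    open[c(6, 12)] <- TRUE
    out$order5vs6 <- makeAnnotatedTree(parent, open)
    # lineage passing from LCA through closed post-LCA back to LCA:
    # root (LCA) -> cell 2 (post-LCA 1) -> cell 4 (post-LCA 2)
    #   -> cell 6 (LCA 1, both daughters open)
    parent <- c(NA, 1, 1, 2, 2, 4, 4, 3, 3, 6, 6)
    open <- c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
              TRUE, TRUE)
    out$postLCAReturn <- makeAnnotatedTree(parent, open)
    out
}

#' Random annotated tree for classifier stress tests
#'
#' Grows a random binary tree by independent division decisions per cell
#' up to \code{maxDepth}, then labels each cell open with probability
#' \code{pOpen} and zero-X with probability \code{pXZero}. Uses R's RNG.
#'
#' @param maxDepth maximum generation.
#' @param pDivide probability an internal candidate divides.
#' @param pOpen probability a cell is open.
#' @param pXZero probability a closed cell has X = 0.
#' @return a [LineageTree-class] object.
#' @export
randomAnnotatedTree <- function(maxDepth = 5L, pDivide = 0.7, pOpen = 0.25,
                                pXZero = 0.3) {
    parent <- NA_integer_
    depth <- 0L
    frontier <- 1L
    while (length(frontier)) {
        nxt <- integer(0)
        for (i in frontier) {
            if (depth[i] < maxDepth && stats::runif(1) < pDivide) {
                parent <- c(parent, i, i)
                depth <- c(depth, depth[i] + 1L, depth[i] + 1L)
                nxt <- c(nxt, length(parent) - 1L, length(parent))
            }
        }
        frontier <- nxt
    }
    n <- length(parent)
    open <- stats::runif(n) < pOpen
    X <- ifelse(stats::runif(n) < pXZero, 0, stats::rpois(n, 3) + 1)
    makeAnnotatedTree(parent, open, X)
}
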