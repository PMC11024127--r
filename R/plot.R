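#' Convert a lineage tree to an ape "phylo" object
#'
#' Each cell maps to one edge whose length is the cell's lifetime; leaves
#' are the cells alive at the horizon. Tip and node labels carry the cell
#' ids. The root cell's lifetime is stored as the root edge.
#'
#' @param tree a [LineageTree-class] object.
#' @return an object of class \code{phylo}.
#' @export
asPhylo <- function(tree) {
    df <- tree@cells
    if (nrow(df) == 1L) stop("a single-cell tree has no phylo representation")
    leaf <- df$cause == "censored"
    ntip <- sum(leaf)
    # ape numbering: tips 1..ntip, internal (ntip+1)..(ntip+nnode), root first
    nodeNo <- integer(nrow(df))
    nodeNo[leaf] <- seq_len(ntip)
    internal <- which(!leaf)
    rootIdx <- which(is.na(df$parent))
    internal <- c(rootIdx, setdiff(internal, rootIdx))
    nodeNo[internal] <- ntip + seq_along(internal)
    pidx <- match(df$parent, df$id)
    nonroot <- which(!is.na(pidx))
    edge <- cbind(nodeNo[pidx[nonroot]], nodeNo[nonroot])
    phy <- structure(list(
        edge = edge,
        edge.length = df$end[nonroot] - df$birth[nonroot],
        tip.label = as.character(df$id[leaf]),
        node.label = as.character(df$id[internal]),
        Nnode = length(internal),
        root.edge = df$end[rootIdx] - df$birth[rootIdx]),
        class = "phylo", order = "cladewise")
    phy
}

#' Plot a lineage tree radially
#'
#' Radial (fan) layout with the time axis pointing outwards; node colour
#' encodes end-of-life status: white = open region, black = closed with
#' X > 0, red = closed with X = 0.
#'
#' @param tree a [LineageTree-class] object with state annotations.
#' @param ... passed on to [ape::plot.phylo()].
#' @return the tree, invisibly.
#' @export
plotLineageTree <- function(tree, ...) {
    phy <- asPhylo(tree)
    cols <- cellColours(tree)
    df <- tree@cells
    leaf <- df$cause == "censored"
    rootIdx <- which(is.na(df$parent))
    internalIdx <- c(rootIdx, setdiff(which(!leaf), rootIdx))
    ape::plot.phylo(phy, type = "fan", show.tip.label = FALSE,
                    root.edge = TRUE, ...)
    ape::tiplabels(pch = 21, bg = cols[leaf], cex = 0.8)
    ape::nodelabels(pch = 21, bg = cols[internalIdx], cex = 0.8)
    invisible(tree)
}
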