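#' @rdname LineageTree-class
#' @param x,object a \code{LineageTree}
#' @export
setGeneric("treeCells", function(x) standardGeneric("treeCells"))

#' @rdname LineageTree-class
#' @export
setMethod("treeCells", "LineageTree", function(x) x@cells)

#' @rdname LineageTree-class
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname LineageTree-class
#' @export
setMethod("nCells", "LineageTree", function(x) nrow(x@cells))

#' @rdname LineageTree-class
#' @export
setGeneric("leafIds", function(x) standardGeneric("leafIds"))

#' @rdname LineageTree-class
#' @export
setMethod("leafIds", "LineageTree",
          function(x) x@cells$id[x@cells$cause == "censored"])

#' @rdname LineageTree-class
#' @export
setGeneric("treeHorizon", function(x) standardGeneric("treeHorizon"))

#' @rdname LineageTree-class
#' @export
setMethod("treeHorizon", "LineageTree", function(x) x@horizon)

#' Which cells have an open region at end of life?
#'
#' @param tree a [LineageTree-class] object.
#' @return named logical vector along the cell table.
#' @export
openCells <- function(tree) {
    if (any(is.na(tree@cells$O)))
        stop("tree lacks region annotations; cannot evaluate openness")
    stats::setNames(tree@cells$O >= tree@openThreshold * tree@sites,
                    tree@cells$id)
}

#' End-of-life cell status
#'
#' \code{open} if the region is open at the end of life; among closed
#' cells, \code{closed_X_positive} vs \code{closed_X_zero} by the final X
#' count. This is also the node colouring used for tree plots: white =
#' open, black = closed with X > 0, red = closed with X = 0.
#'
#' @param tree a [LineageTree-class] object.
#' @return character vector along the cell table.
#' @export
cellStatus <- function(tree) {
    open <- openCells(tree)
    if (any(is.na(tree@cells$X[!open])))
        stop("tree lacks X annotations; cannot evaluate status")
    ifelse(open, "open",
           ifelse(tree@cells$X > 0, "closed_X_positive", "closed_X_zero"))
}

#' @rdname cellStatus
#' @export
cellColours <- function(tree) {
    c(open = "white", closed_X_positive = "black",
      closed_X_zero = "red")[cellStatus(tree)]
}

#' @describeIn LineageTree-class compact display
#' @export
setMethod("show", "LineageTree", function(object) {
    df <- object@cells
    leaf <- df$cause == "censored"
    cat(sprintf("LineageTree: %d cells (%d leaves), %d divisions, horizon %g h\n",
                nrow(df), sum(leaf), max(df$generation), object@horizon))
    if (!any(is.na(df$O))) {
        open <- df$O >= object@openThreshold * object@sites
        cat(sprintf("open cells at horizon: %d / %d (%.1f%%)\n",
                    sum(open[leaf]), sum(leaf),
                    100 * mean(open[leaf])))
    }
    if ("category" %in% names(df))
        cat("classified: ", paste(utils::head(sort(unique(df$category)), 8L),
                                  collapse = ", "), "\n")
    invisible(object)
})

# children index list: childIdx[[i]] = row indices of children of row i
childIndex <- function(df) {
    pidx <- match(df$parent, df$id)
    kids <- split(seq_len(nrow(df)), factor(pidx, levels = seq_len(nrow(df))))
    names(kids) <- NULL
    kids
}
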