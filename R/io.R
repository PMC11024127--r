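# Lineage-tree serialization as Newick with NHX node annotations, and
# YAML configuration I/O. Branch lengths are cell lifetimes in hours.
#
# No installed package round-trips NHX node attributes, so the (small)
# grammar is implemented here and covered by round-trip tests.

fmtNum <- function(x) {
    ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

nhxAnnotation <- function(row, extra = NULL) {
    kv <- c(gen = row$generation, birth = fmtNum(row$birth),
            end = fmtNum(row$end), cause = row$cause,
            R = fmtNum(row$R), T = fmtNum(row$T), G = fmtNum(row$G),
            P = fmtNum(row$P), X = fmtNum(row$X), N = fmtNum(row$N),
            C = fmtNum(row$C), I = fmtNum(row$I), O = fmtNum(row$O))
    if (!is.null(row$category) && !is.na(row$category)) {
        kv <- c(kv, cat = row$category)
        if (!is.na(row$order)) kv <- c(kv, ord = row$order)
    }
    kv <- c(kv, extra)
    paste0("[&&NHX:", paste(names(kv), kv, sep = "=", collapse = ":"), "]")
}

#' Export a lineage tree as Newick/NHX
#'
#' Standard Newick topology with node labels = cell ids and branch lengths
#' = cell lifetimes (hours); all per-cell annotations (generation, times,
#' end cause, final counts, region counts and any classification) travel
#' in NHX comment blocks. Tree-level attributes (site total, open
#' threshold, horizon, seed) are attached to the root node.
#'
#' @param tree a [LineageTree-class] object.
#' @param path output file path.
#' @return the path, invisibly.
#' @seealso [parseTree()]
#' @export
exportTree <- function(tree, path) {
    df <- tree@cells
    hasCat <- "category" %in% names(df)
    kids <- childIndex(df)
    rootIdx <- which(is.na(df$parent))
    rec <- function(i) {
        row <- df[i, ]
        extra <- NULL
        if (i == rootIdx)
            extra <- c(S = tree@sites, thr = fmtNum(tree@openThreshold),
                       horizon = fmtNum(tree@horizon),
                       seed = if (is.na(tree@seed)) "NA" else tree@seed)
        lab <- paste0(row$id, ":", fmtNum(row$end - row$birth),
                      nhxAnnotation(row, extra))
        k <- kids[[i]]
        if (length(k) == 0L) return(lab)
        paste0("(", rec(k[1L]), ",", rec(k[2L]), ")", lab)
    }
    txt <- paste0(rec(rootIdx), ";")
    writeLines(txt, path)
    invisible(path)
}

#' Parse a Newick/NHX lineage tree
#'
#' Reads a tree written by [exportTree()] (or any binary Newick file).
#' Non-binary topologies are rejected. Files without NHX annotations load
#' with unknown (NA) cell states; such trees can be inspected but
#' classification refuses them.
#'
#' @param path input file path.
#' @return a [LineageTree-class] object.
#' @export
parseTree <- function(path) {
    txt <- paste(readLines(path, warn = FALSE), collapse = "")
    txt <- gsub("[[:space:]]", "", txt)
    if (!nzchar(txt) || !endsWith(txt, ";"))
        stop("malformed Newick: missing terminating ';'")
    pos <- 1L
    n <- nchar(txt)
    peek <- function() substr(txt, pos, pos)
    fail <- function(what) stop(sprintf(
        "parse error at character %d (near '%s'): %s", pos,
        substr(txt, max(1L, pos - 10L), min(n, pos + 10L)), what))
    nodes <- list()

    parseNode <- function() {
        children <- list()
        if (peek() == "(") {
            pos <<- pos + 1L
            repeat {
                children[[length(children) + 1L]] <- parseNode()
                ch <- peek()
                if (ch == ",") { pos <<- pos + 1L; next }
                if (ch == ")") { pos <<- pos + 1L; break }
                fail("expected ',' or ')'")
            }
            if (length(children) != 2L)
                fail(sprintf("non-binary node with %d children",
                             length(children)))
        }
        # label
        lab <- ""
        while (pos <= n && !(peek() %in% c(":", "[", ",", ")", ";")))  {
            lab <- paste0(lab, peek()); pos <<- pos + 1L
        }
        brlen <- NA_real_
        if (peek() == ":") {
            pos <<- pos + 1L
            num <- ""
            while (pos <= n && grepl("[-+0-9.eE]", peek())) {
                num <- paste0(num, peek()); pos <<- pos + 1L
            }
            brlen <- suppressWarnings(as.numeric(num))
            if (is.na(brlen)) fail("invalid branch length")
        }
        ann <- list()
        if (peek() == "[") {
            close <- regexpr("]", substr(txt, pos, n), fixed = TRUE)
            if (close < 0) fail("unterminated annotation block")
            block <- substr(txt, pos, pos + close - 1L)
            pos <<- pos + close
            body <- sub("^\\[&&NHX:?", "", sub("\\]$", "", block))
            if (nzchar(body)) {
                for (kv in strsplit(body, ":", fixed = TRUE)[[1L]]) {
                    eq <- regexpr("=", kv, fixed = TRUE)
                    if (eq < 0) fail("annotation entry without '='")
                    ann[[substr(kv, 1L, eq - 1L)]] <-
                        substr(kv, eq + 1L, nchar(kv))
                }
            }
        }
        nodes[[length(nodes) + 1L]] <<-
            list(label = lab, brlen = brlen, ann = ann,
                 nChildren = length(children),
                 children = vapply(children, identity, 0L))
        length(nodes)
    }

    rootNode <- parseNode()
    if (peek() != ";") fail("trailing characters before ';'")

    num <- function(a, key) {
        v <- a[[key]]
        if (is.null(v) || identical(v, "NA")) NA_real_ else as.numeric(v)
    }
    rows <- vector("list", length(nodes))
    build <- function(nodeIdx, parentId, parentEnd, depth, nextId) {
        nd <- nodes[[nodeIdx]]
        a <- nd$ann
        id <- suppressWarnings(as.integer(nd$label))
        if (is.na(id)) { id <- nextId; nextId <- nextId + 1L }
        birth <- num(a, "birth")
        if (is.na(birth)) birth <- parentEnd
        end <- num(a, "end")
        if (is.na(end)) end <- birth + ifelse(is.na(nd$brlen), 0, nd$brlen)
        cause <- a[["cause"]]
        if (is.null(cause)) cause <- if (nd$nChildren) "divided" else "censored"
        gen <- num(a, "gen")
        if (is.na(gen)) gen <- depth
        rows[[nodeIdx]] <<- data.frame(
            id = id, parent = parentId, generation = as.integer(gen),
            birth = birth, end = end, cause = cause,
            R = num(a, "R"), T = num(a, "T"), G = num(a, "G"),
            P = num(a, "P"), X = num(a, "X"), N = num(a, "N"),
            C = as.integer(num(a, "C")), I = as.integer(num(a, "I")),
            O = as.integer(num(a, "O")),
            category = if (is.null(a[["cat"]])) NA_character_ else a[["cat"]],
            order = as.integer(num(a, "ord")))
        for (ch in nd$children)
            nextId <- build(ch, id, end, depth + 1L, nextId)
        nextId
    }
    build(rootNode, NA_integer_, 0, 0L, 100000L)
    cells <- do.call(rbind, rows)
    if (all(is.na(cells$category))) cells$category <- NULL
    if (is.null(cells$category)) cells$order <- NULL

    rootAnn <- nodes[[rootNode]]$ann
    sites <- num(rootAnn, "S")
    if (is.na(sites)) {
        sites <- sum(cells[1, c("C", "I", "O")])
        if (is.na(sites)) sites <- 500L
    }
    thr <- num(rootAnn, "thr")
    if (is.na(thr)) thr <- 0.75
    horizon <- num(rootAnn, "horizon")
    if (is.na(horizon)) horizon <- max(cells$end)
    seed <- num(rootAnn, "seed")
    tree <- newLineageTree(cells, horizon, ifelse(is.na(seed), NA, seed),
                           sites, thr)
    validObject(tree)
    if ("category" %in% names(tree@cells)) {
        # status is derivable from the serialized counts
        df <- tree@cells
        df$status <- cellStatus(tree)
        df <- df[c(setdiff(names(df), c("status", "category", "order")),
                   "status", "category", "order")]
        tree@cells <- df
    }
    tree
}

# --------------------------------------------------------------------------
# YAML configuration
# --------------------------------------------------------------------------

#' Write a simulation configuration to YAML
#'
#' @param config a [SimulationConfig-class] object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeSimulationConfig <- function(config, path) {
    validObject(config)
    kd <- config@knockdown
    obj <- list(
        grn = list(p = as.list(config@grn@p),
                   gamma = as.list(config@grn@gamma),
                   kd_factor = as.list(config@grn@kdFactor)),
        epigenetic = list(rates = as.list(config@epigenetic@rates),
                          sites = config@epigenetic@sites,
                          open_fraction_threshold =
                              config@epigenetic@openFractionThreshold),
        division = list(mu = as.numeric(config@division@mu),
                        sigma = as.numeric(config@division@sigma)),
        initial_state = as.list(config@initialState),
        initial_region = as.list(as.integer(config@initialRegion)) |>
            stats::setNames(REGION_NAMES),
        horizon = config@horizon,
        knockdown = if (is.null(kd)) NULL else
            list(gene = kd@gene, factor = kd@factor, onset = kd@onset))
    yaml::write_yaml(obj, path)
    invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' Missing sections fall back to the package defaults (the published
#' wild-type setup).
#'
#' @param path YAML file path.
#' @return a [SimulationConfig-class] object.
#' @export
readSimulationConfig <- function(path) {
    obj <- yaml::read_yaml(path)
    num <- function(x, nm) stats::setNames(as.numeric(unlist(x[nm])), nm)
    grn <- grnParameters()
    if (!is.null(obj$grn)) {
        if (!is.null(obj$grn$p)) grn@p <- num(obj$grn$p, paste0("p", 1:16))
        if (!is.null(obj$grn$gamma))
            grn@gamma <- num(obj$grn$gamma, GENE_NAMES[1:5])
        if (!is.null(obj$grn$kd_factor))
            grn@kdFactor <- num(obj$grn$kd_factor, GENE_NAMES)
        validObject(grn)
    }
    epi <- epigeneticParameters()
    if (!is.null(obj$epigenetic)) {
        e <- obj$epigenetic
        if (!is.null(e$rates)) epi@rates <- num(e$rates, EPI_RATE_NAMES)
        if (!is.null(e$sites)) epi@sites <- as.integer(e$sites)
        if (!is.null(e$open_fraction_threshold))
            epi@openFractionThreshold <- e$open_fraction_threshold
        validObject(epi)
    }
    div <- divisionTimeModel()
    if (!is.null(obj$division))
        div <- divisionTimeModel(obj$division$mu, obj$division$sigma)
    st <- if (is.null(obj$initial_state)) geneState() else
        stats::setNames(as.numeric(unlist(obj$initial_state[GENE_NAMES])),
                        GENE_NAMES)
    rg <- if (is.null(obj$initial_region)) regulatoryRegion() else
        stats::setNames(as.integer(unlist(obj$initial_region[REGION_NAMES])),
                        REGION_NAMES)
    kd <- if (is.null(obj$knockdown)) NULL else
        knockdownSpec(obj$knockdown$gene,
                      if (is.null(obj$knockdown$factor)) 0.2 else
                          obj$knockdown$factor,
                      if (is.null(obj$knockdown$onset)) 0 else
                          obj$knockdown$onset)
    simulationConfig(grn = grn, epigenetic = epi, division = div,
                     initialState = st, initialRegion = rg,
                     horizon = if (is.null(obj$horizon)) 120 else obj$horizon,
                     knockdown = kd)
}
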