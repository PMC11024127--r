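# Last-common-ancestor classification.

test_that("canonical fixtures classify as defined", {
    fx <- fixtureTrees()

    cl <- treeCells(classifyTree(fx$order1))
    expect_equal(cl$category, c("LCA", "open", "open"))
    expect_equal(cl$order[1], 1L)

    cl <- treeCells(classifyTree(fx$allClosed))
    expect_true(all(cl$category == "closed_pre_LCA"))

    cl <- treeCells(classifyTree(fx$allOpen))
    expect_true(all(cl$category == "open"))

    # open cells 5 and 6 generations down the two branches: order 5
    cl <- treeCells(classifyTree(fx$order5vs6))
    expect_equal(cl$category[1], "LCA")
    expect_equal(cl$order[1], 5L)

    # LCA -> closed post-LCA (1, 2) -> LCA again along one lineage
    cl <- treeCells(classifyTree(fx$postLCAReturn))
    lab <- paste(cl$category, cl$order)
    expect_equal(lab[cl$id == 0], "LCA 2")
    expect_equal(lab[cl$id == 1], "closed_post_LCA 1")
    expect_equal(lab[cl$id == 3], "closed_post_LCA 2")
    expect_equal(lab[cl$id == 5], "LCA 1")
})

test_that("per-branch open distances match the worked definitions", {
    fx <- fixtureTrees()
    expect_equal(sort(nearestOpenDistance(fx$order1, 0)), c(1, 1))
    expect_equal(sort(nearestOpenDistance(fx$order5vs6, 0)), c(5, 6))
    expect_equal(nearestOpenDistance(fx$allClosed, 0), c(Inf, Inf))
    expect_length(nearestOpenDistance(fx$order1, 1), 0)  # leaf
})

test_that("classification partitions the tree and satisfies its definitions", {
    set.seed(20)
    for (rep in 1:40) {
        tr <- classifyTree(randomAnnotatedTree())
        df <- treeCells(tr)
        expect_false(any(is.na(df$category)))
        expect_equal(sum(table(df$category)), nrow(df))
        kids <- split(seq_len(nrow(df)), factor(match(df$parent, df$id),
                                                levels = seq_len(nrow(df))))
        open <- df$status == "open"
        pidx <- match(df$parent, df$id)
        for (i in seq_len(nrow(df))) {
            cat <- df$category[i]
            if (cat == "LCA") {
                expect_false(open[i])
                d <- nearestOpenDistance(tr, df$id[i])
                expect_true(all(is.finite(d)))
                expect_equal(min(d), df$order[i])
            } else if (cat == "closed_post_LCA") {
                # an LCA ancestor exactly `order` generations up, none closer
                a <- pidx[i]; m <- 1L
                while (!is.na(a) && df$category[a] != "LCA") {
                    a <- pidx[a]; m <- m + 1L
                }
                expect_false(is.na(a))
                expect_equal(m, df$order[i])
            } else if (cat == "closed_pre_LCA") {
                a <- pidx[i]
                while (!is.na(a)) {
                    expect_false(df$category[a] == "LCA")
                    a <- pidx[a]
                }
            }
        }
    }
})

test_that("classifier agrees with the exhaustive-enumeration oracle", {
    set.seed(31)
    for (rep in 1:400) {
        tr <- randomAnnotatedTree()
        a <- treeCells(classifyTree(tr))
        b <- bruteForceLCA(tr)
        expect_identical(a$category, b$category)
        expect_identical(a$order, b$order)
    }
})

test_that("category statistics pool counts, means and flag singletons", {
    # two closed cells with X = 2 and 4 in the same (pre-LCA) category
    tr <- makeAnnotatedTree(c(NA, 1, 1), open = c(FALSE, FALSE, FALSE),
                            X = c(2, 4, 7))
    tab <- categoryStatistics(classifyTree(tr))
    expect_equal(tab$count, 3)
    expect_equal(tab$mean_X, mean(c(2, 4, 7)))
    # a single-cell category reports NA spread
    tr2 <- classifyTree(fixtureTrees()$order1)
    tab2 <- categoryStatistics(tr2)
    expect_equal(sum(tab2$count), 3)
    expect_true(is.na(tab2$sd_X[tab2$category == "LCA 1"]))
    expect_equal(tab2$category, c("LCA 1", "open"))
    expect_error(categoryStatistics(fixtureTrees()$order1), "classified")
})

test_that("commitment delay is the generation gap from X loss to opening", {
    # root X>0; cell2 loses X (end X=0); opens two generations later
    parent <- c(NA, 1, 1, 2, 2, 4, 4)
    open <- c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
    X <- c(3, 0, 5, 0, 2, 0, 0)
    tr <- classifyTree(makeAnnotatedTree(parent, open, X))
    d <- delayStatistics(tr)
    expect_equal(d$delays, 2L)
    expect_equal(d$meanDelay, 2)
    # a tree with no open cells contributes nothing
    d0 <- delayStatistics(classifyTree(fixtureTrees()$allClosed))
    expect_length(d0$delays, 0)
    expect_true(is.na(d0$meanDelay))
})
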