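test_that("Newick parsing reads labels and lengths and rejects malformed input", {
    tr <- parseNewick("(A:1,B:2);")
    expect_s3_class(tr, "phylo")
    expect_setequal(tr$tip.label, c("A", "B"))
    expect_equal(sort(tr$edge.length), c(1, 2))

    expect_error(parseNewick("((A,B);"), "unbalanced parentheses")
    expect_error(parseNewick("(A,B),C);"), "unbalanced parentheses")
    expect_error(parseNewick(""), "empty")
    expect_error(parseNewick("(A,B)"), "terminated")
    expect_error(parseNewick("(A:1,A:2);"), "duplicate leaf labels")

    ## quoted and internal labels, scientific notation
    tr2 <- parseNewick("((A:1e-3,B:2)anno:0.5,C:1);")
    expect_equal(min(tr2$edge.length), 1e-3)
    expect_true("anno" %in% tr2$node.label)
})

test_that("parse/write round-trip is the identity on random trees", {
    set.seed(11)
    for (i in 1:50) {
        n <- sample(4:20, 1)
        tr <- ape::rtree(n)
        back <- parseNewick(writeNewick(tr))
        expect_setequal(back$tip.label, tr$tip.label)
        expect_equal(oracleRF(tr, back), 0)
        d1 <- ape::cophenetic.phylo(tr)
        d2 <- ape::cophenetic.phylo(back)[rownames(d1), colnames(d1)]
        expect_equal(d1, d2, tolerance = 1e-9)
    }
})

test_that("midpoint rooting balances the two deepest root-to-leaf paths", {
    tr <- midpointRoot(parseNewick("(A:1,B:5,C:1);"))
    d <- ape::node.depth.edgelength(tr)[1:3]
    names(d) <- tr$tip.label
    expect_equal(unname(d["A"]), 3)
    expect_equal(unname(d["B"]), 3)
    expect_equal(sum(tr$edge.length), 7)   # total length conserved

    tr2 <- midpointRoot(parseNewick("(A:1,B:1);"))
    expect_equal(ape::node.depth.edgelength(tr2)[1:2], c(1, 1))
})

test_that("midpoint rooting matches the all-pairs oracle on random trees", {
    set.seed(23)
    for (i in 1:40) {
        n <- sample(4:15, 1)
        tr <- ape::rtree(n)
        rooted <- midpointRoot(tr)
        total <- sum(tr$edge.length)
        expect_equal(sum(rooted$edge.length), total, tolerance = 1e-9)
        ## oracle: deepest leaf depth must equal half the tree diameter
        D <- ape::cophenetic.phylo(tr)
        depth <- ape::node.depth.edgelength(rooted)[seq_len(n)]
        expect_equal(max(depth), max(D) / 2, tolerance = 1e-9 * max(total, 1))
        ## the two root-child subtrees are equally deep
        root <- n + 1L
        kids <- rooted$edge[rooted$edge[, 1] == root, 2]
        sideDepth <- vapply(kids, function(k) {
            tips <- if (k <= n) k else
                unlist(phangorn::Descendants(rooted, k, "tips"))
            max(depth[tips])
        }, numeric(1))
        expect_lte(abs(max(sideDepth) - max(D) / 2), 1e-9 * max(total, 1))
        ## agreement with the established implementation
        pm <- phangorn::midpoint(tr)
        expect_equal(max(ape::node.depth.edgelength(pm)[seq_len(n)]),
                     max(depth), tolerance = 1e-8)
    }
})

test_that("midpoint rooting falls back deterministically on zero-length trees", {
    tr <- parseNewick("(A:0,B:0,C:0);")
    expect_warning(out <- midpointRoot(tr), "zero")
    expect_s3_class(out, "phylo")
    expect_setequal(out$tip.label, c("A", "B", "C"))
    expect_error(midpointRoot(parseNewick("(A,B,C);")), "branch lengths")
})

test_that("collapsing short branches contracts internal edges only", {
    tr <- parseNewick("((A:0,B:1):0,(C:1,D:1):1);")
    out <- collapseShortBranches(tr, 0)
    expect_equal(out$Nnode, 2L)                 # polytomy created
    expect_setequal(out$tip.label, tr$tip.label)
    expect_true(any(out$edge.length == 0))      # terminal zero branch kept

    tr2 <- parseNewick("((A:1,B:1):1e-9,(C:1,D:1):1);")
    expect_equal(collapseShortBranches(tr2, 0)$Nnode, tr2$Nnode)  # strict threshold
    expect_equal(collapseShortBranches(tr2, 1e-9)$Nnode, tr2$Nnode - 1L)
    expect_error(collapseShortBranches(tr2, -1), "non-negative")
})

test_that("pruning conserves path lengths among kept leaves", {
    tr <- parseNewick("(A:1,(B:1,C:1):1);")
    out <- pruneTo(tr, c("A", "B"))
    expect_setequal(out$tip.label, c("A", "B"))
    expect_equal(patristicDistance(out, "A", "B"), 3)

    expect_identical(pruneTo(tr, tr$tip.label), tr)
    one <- pruneTo(tr, "A")
    expect_equal(length(one$tip.label), 1L)
    expect_error(pruneTo(tr, c("A", "Z")), "unknown leaf")

    set.seed(5)
    for (i in 1:25) {
        tr <- ape::rtree(12)
        keep <- sample(tr$tip.label, sample(3:10, 1))
        sub <- pruneTo(tr, keep)
        for (pair in list(keep[1:2], keep[c(1, 3)]))
            expect_equal(patristicDistance(sub, pair[1], pair[2]),
                         patristicDistance(tr, pair[1], pair[2]),
                         tolerance = 1e-9)
    }
})

test_that("patristic distances sum branch lengths along the path", {
    expect_equal(patristicDistance(parseNewick("(A:1,B:2);"), "A", "B"), 3)
    expect_equal(patristicDistance(parseNewick("(A:1,B:2);"), "A", "A"), 0)
    expect_equal(patristicDistance(parseNewick("((A:1,B:1):2,C:1);"), "A", "C"), 4)
    expect_error(patristicDistance(parseNewick("(A,B);"), "A", "B"),
                 "branch lengths")
})

test_that("RF distance equals the brute-force split symmetric difference", {
    t1 <- parseNewick("((A,B),(C,D));")
    t2 <- parseNewick("((A,C),(B,D));")
    expect_identical(rfDistance(t1, t1)$raw, 0L)
    expect_equal(rfDistance(t1, t1)$normalized, 0)
    d <- rfDistance(t1, t2)
    expect_identical(d$raw, 2L)
    expect_equal(d$normalized, 1.0)
    expect_error(rfDistance(t1, parseNewick("((A,B),(C,E));")), "E")

    set.seed(31)
    for (i in 1:60) {
        n <- sample(4:8, 1)
        a <- ape::rtree(n); b <- ape::rtree(n)
        b$tip.label <- sample(a$tip.label)
        d <- rfDistance(a, b)
        expect_identical(d$raw, as.integer(oracleRF(a, b)))
        expect_identical(d$raw,
                         as.integer(phangorn::RF.dist(a, b, normalize = FALSE)))
        expect_identical(d$raw, rfDistance(b, a)$raw)       # symmetric
        expect_gte(d$normalized, 0); expect_lte(d$normalized, 1)
        expect_equal(d$normalized, d$raw / (2 * (n - 3)))   # binary trees
    }
})
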