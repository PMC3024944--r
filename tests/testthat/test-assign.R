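test_that("penaltyScore implements the formula and its edge cases", {
    ## worked partition: tp=3, fp=1, tn=3, fn=1 gives 1/3 for every q
    grid <- seq(0, 1, by = 0.1)
    expect_equal(penaltyScore(c(tp = 3, fp = 1, tn = 3, fn = 1), grid),
                 rep(1 / 3, length(grid)))
    ## at the LCA fn = 0, so PS = (1-q) fp/tp; zero at q = 1
    expect_equal(penaltyScore(c(tp = 4, fp = 4, tn = 0, fn = 0), grid),
                 (1 - grid) * 4 / 4)
    expect_identical(penaltyScore(c(tp = 4, fp = 4, tn = 0, fn = 0), 1), 0)
    ## empty-TP nodes are infinitely penalized
    expect_identical(penaltyScore(c(tp = 0, fp = 2, tn = 1, fn = 3), 0.5),
                     Inf)
    expect_error(penaltyScore(c(tp = 1, fp = 0, tn = 0, fn = 0), 1.2),
                 "0, 1")
    expect_error(penaltyScore(c(tp = 1, fp = 0, tn = 0, fn = 0), -0.1),
                 "0, 1")
})

test_that("q = 1 assigns to the LCA with score 0, q = 0 to a hit leaf", {
    set.seed(505)
    for (rep in 1:40) {
        inst <- randomInstance(maxLeaves = 80L, maxHits = 15L)
        a1 <- assignFast(inst$idx, inst$m, 1)
        expect_identical(assignmentScore(a1), 0)
        expect_identical(canonicalNode(a1), lcaOfSet(inst$idx,
                                                     hits(inst$m)))
        a0 <- assignFast(inst$idx, inst$m, 0)
        expect_identical(assignmentScore(a0), 0)
        expect_true(any(bestNodes(a0) %in% hits(inst$m)))
        ## canonical tie-break prefers the most specific node: a leaf
        expect_true(canonicalNode(a0) %in% hits(inst$m))
        n1 <- assignNaive(inst$idx, inst$m, 1)
        expect_identical(assignmentScore(n1), 0)
        n0 <- assignNaive(inst$idx, inst$m, 0)
        expect_true(any(bestNodes(n0) %in% hits(inst$m)))
    }
})

test_that("naive, fast and brute-force routes agree on random instances", {
    set.seed(606)
    qGrid <- seq(0, 1, by = 0.1)
    for (rep in 1:60) {
        inst <- randomInstance(maxLeaves = 60L, maxHits = 12L)
        for (q in qGrid) {
            oracle <- owAssign(inst$idx, hits(inst$m), q)
            nv <- assignNaive(inst$idx, inst$m, q)
            ft <- assignFast(inst$idx, inst$m, q)
            expect_equal(assignmentScore(nv), oracle$score,
                         tolerance = 1e-12)
            expect_equal(assignmentScore(ft), oracle$score,
                         tolerance = 1e-12)
            ## naive scores all of T_i: full tie set equals brute force
            expect_setequal(bestNodes(nv), oracle$best)
            ## fast ties are a subset (relevant nodes only)
            expect_true(all(bestNodes(ft) %in% oracle$best))
        }
    }
})

test_that("the LCA closed form holds exactly", {
    set.seed(707)
    for (rep in 1:30) {
        inst <- randomInstance(maxLeaves = 100L, maxHits = 20L)
        rootI <- lcaOfSet(inst$idx, hits(inst$m))
        li <- leafCounts(inst$idx)[rootI]
        M <- length(hits(inst$m))
        for (q in c(0, 0.3, 0.8)) {
            want <- (1 - q) * (li - M) / M
            got <- penaltyScore(c(tp = M, fp = li - M, tn = 0, fn = 0), q)
            expect_equal(got, want, tolerance = 1e-15)
        }
    }
})

test_that("restriction equals the quadratic relevant-node oracle", {
    set.seed(808)
    for (rep in 1:50) {
        inst <- randomInstance(maxLeaves = 60L, maxHits = 12L)
        rt <- buildRestriction(inst$idx, inst$m)
        M <- length(hits(inst$m))
        expect_setequal(rt@nodes, owRelevantNodes(inst$idx, hits(inst$m)))
        expect_lte(length(rt@nodes), 2L * M - 1L)
        expect_identical(rt@root, owLcaSet(inst$idx, hits(inst$m)))
        expect_identical(rt@mCount[1L], M)
        ## parent links: the nearest proper ancestor within the node set
        for (i in seq_along(rt@nodes)) {
            j <- rt@nodes[i]
            anc <- rt@nodes[isProperAncestor(inst$idx, rt@nodes, j)]
            if (length(anc) == 0L) {
                expect_identical(j, rt@root)
                expect_true(is.na(rt@parent[i]))
            } else {
                ## nearest proper ancestor in the node set = the deepest
                deepest <- anc[which.max(nodeDepths(inst$idx)[anc])]
                expect_identical(rt@parent[i], deepest)
            }
        }
        ## hit counts per relevant node, by explicit enumeration
        cnt <- owCounts(inst$idx, hits(inst$m))
        expect_identical(as.numeric(rt@mCount), cnt$tp[rt@nodes])
    }
})

test_that("degenerate restrictions are handled", {
    idx <- fig1Tree()
    ## two leaves: a 3-node cherry rooted at their LCA
    m2 <- HitSet("r", c("s1", "s2"), idx = idx)
    rt <- buildRestriction(idx, m2)
    expect_length(rt@nodes, 3L)
    expect_identical(rt@root, resolveNodes(idx, "a"))
    ## all leaves of a binary tree: restriction isomorphic to the tree
    bidx <- preprocessTaxonomy(parseTaxonomy("(((A,B)x,(C,D)y)w,(E,F)z)r;"))
    mall <- HitSet("r", c("A","B","C","D","E","F"), idx = bidx)
    rtall <- buildRestriction(bidx, mall)
    expect_identical(sort(rtall@nodes), sort(seq_len(nNodes(bidx))))
    expect_identical(rtall@parent[match(seq_len(nNodes(bidx)), rtall@nodes)],
                     nodeParents(bidx))
})

test_that("assignRead dispatches on the hit count", {
    idx <- fig1Tree()
    a0 <- assignRead(idx, HitSet("r0", character(0), idx = idx), 0.5)
    expect_identical(a0@status, "unassigned")
    expect_true(is.na(canonicalNode(a0)))
    a1 <- assignRead(idx, HitSet("r1", "s3", idx = idx), 0.5)
    expect_identical(a1@status, "unique")
    expect_identical(canonicalNode(a1), resolveNodes(idx, "s3"))
    expect_identical(assignmentScore(a1), 0)
    expect_identical(unname(confusionCounts(a1)), c(1, 0, 0, 0))
    a4 <- assignRead(idx, fig1HitSet(idx), 0.5)
    expect_identical(a4@status, "ambiguous")
    expect_identical(canonicalNode(a4), resolveNodes(idx, "j"))
})

test_that("sweepQ reproduces per-q assignments and the Lemma-1 grid point", {
    idx <- fig1Tree()
    m <- fig1HitSet(idx)
    sw <- sweepQ(idx, list(m), seq(0, 1, by = 0.1))
    expect_equal(nrow(sw), 11L)
    expect_equal(sw$score[sw$q == 0], 0)
    expect_equal(sw$score[sw$q == 1], 0)
    expect_identical(sw$node[sw$q == 1], "root")
    expect_true(sw$node[sw$q == 0] %in% c("s1", "s5", "s6", "s7"))
    ## q = 0.5 equals the brute-force F-measure argmax
    fbest <- owFMeasure(idx, hits(m))
    expect_true(sw$node_id[sw$q == 0.5] %in% fbest)
    ## grid agrees with one-read assignment calls
    for (q in c(0, 0.3, 0.7, 1)) {
        a <- assignFast(idx, m, q)
        expect_equal(sw$score[sw$q == q], assignmentScore(a))
        expect_identical(sw$node_id[sw$q == q], canonicalNode(a))
    }
})

test_that("rank distribution tallies canonical ranks and conserves reads", {
    ## two genera of one family: q = 1 sends every ambiguous read to family
    tbl <- c("leaf\tlevel1\tlevel2\tlevel3",
             "a1\tf1\tg1\ta1", "a2\tf1\tg1\ta2",
             "b1\tf1\tg2\tb1", "b2\tf1\tg2\tb2",
             "c1\tf2\tg3\tc1", "c2\tf2\tg3\tc2")
    idx <- preprocessTaxonomy(parseTaxonomy(tbl, "lineage_table"))
    hs <- readHitsTsv(c("r1\ta1,b1", "r2\ta2,b2", "r3\ta1,b2", "r4\t"),
                      idx)
    sw <- sweepQ(idx, hs, c(0, 1))
    tab <- rankDistribution(sw, idx)
    expect_identical(as.integer(tab["level1", "1"]), 3L)
    expect_identical(as.integer(tab["level3", "0"]), 3L)
    expect_identical(as.integer(attr(tab, "unassigned")[["1"]]), 1L)
    ## conservation: per-q counts sum to assigned reads
    expect_true(all(colSums(tab) == 3L))
})
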