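sq2 <- sqrt(2) / 2

test_that("truth-based confusion matches the printed counts", {
    idx <- fig1Tree()
    m <- fig1HitSet(idx)           # true hit s5, |L_i| = 8
    ## the worked candidate node: 4 leaves, truth inside
    rec <- truthConfusion(idx, m, "j")
    expect_identical(rec$tpr_h, 1)
    expect_equal(rec$fpr_h, 3 / 7)
    expect_identical(rec$l_i, 8L)
    expect_identical(rec$l_ij, 4L)
    ## LCA: both rates are 1 (no predictive power)
    lcaRec <- truthConfusion(idx, m, "root")
    expect_identical(lcaRec$tpr_h, 1)
    expect_identical(lcaRec$fpr_h, 1)
    expect_identical(lcaRec$d, 0)
    ## the true leaf itself: perfect point
    leafRec <- truthConfusion(idx, m, "s5")
    expect_identical(leafRec$tpr_h, 1)
    expect_identical(leafRec$fpr_h, 0)
    expect_equal(leafRec$d, sq2)
    ## a wrong leaf: truth outside, printed negative-branch formula
    wrong <- truthConfusion(idx, m, "s2")
    expect_identical(wrong$tpr_h, 0)
    expect_equal(wrong$d, -sq2 * (8 - 1 - 1) / (8 - 1))
    ## candidate outside T_i is rejected
    m57 <- HitSet("r", c("s5", "s7"), trueHit = "s5", idx = idx)
    expect_error(truthConfusion(idx, m57, "s1"), "subtree")
})

test_that("signed distances stay within the ROC bound", {
    set.seed(909)
    for (rep in 1:40) {
        inst <- randomInstance(maxLeaves = 60L, maxHits = 10L)
        idx <- inst$idx
        m <- inst$m
        m@trueHit <- hits(m)[1L]
        rootI <- lcaOfSet(idx, hits(m))
        nodes <- which(seq_len(nNodes(idx)) == rootI |
                       isProperAncestor(idx, rootI, seq_len(nNodes(idx))))
        for (node in sample(nodes, min(5L, length(nodes)))) {
            rec <- truthConfusion(idx, m, node)
            expect_lte(abs(rec$d), sq2 + 1e-15)
            ## sign convention: positive iff truth inside the subtree
            if (rec$l_ij < rec$l_i - 1 || rec$h_in_subtree)
                expect_identical(rec$d >= 0, rec$h_in_subtree)
            ed <- expectedDistance(idx, m, node)
            expect_lte(abs(ed$e_d), sq2 + 1e-15)
        }
    }
})

test_that("goodness G_q is the sum of per-read signed distances", {
    idx <- fig1Tree()
    reads <- list(
        HitSet("r1", c("s1", "s5", "s6", "s7"), trueHit = "s5", idx = idx),
        HitSet("r2", c("s2", "s3"), trueHit = "s2", idx = idx),
        HitSet("r3", c("s5", "s8"), trueHit = "s8", idx = idx))
    tab <- rocTable(idx, reads, qGrid = c(0, 0.5, 1))
    ## independent per-read recomputation
    for (q in c(0, 0.5, 1)) {
        rec <- tab[tab$q == q, ]
        again <- vapply(seq_len(nrow(rec)), function(i) {
            m <- reads[[match(rec$read_id[i],
                              vapply(reads, readId, character(1)))]]
            truthConfusion(idx, m, rec$node_id[i])$d
        }, numeric(1))
        expect_equal(goodnessGq(rec), sum(again))
    }
    ## every read at its true leaf scores n * sqrt(2)/2
    recTrue <- do.call(rbind, lapply(reads, function(m)
        truthConfusion(idx, m, trueHit(m))))
    expect_equal(goodnessGq(recTrue), 3 * sq2)
    ## every read at the LCA scores 0 when truth is inside
    recLca <- do.call(rbind, lapply(reads, function(m)
        truthConfusion(idx, m, lcaOfSet(idx, hits(m)))))
    expect_identical(goodnessGq(recLca), 0)
})

test_that("expected distance matches hand-computed values", {
    ## 4-leaf star, two hits, candidate = a hit leaf:
    ## p = 1/2, E(D) = (sqrt2/2) (1/2 * 3/3 - 1/2 * 2/3) = sqrt2/12
    idx <- preprocessTaxonomy(parseTaxonomy("(A,B,C,D)r;"))
    m <- HitSet("r", c("A", "B"), idx = idx)
    ed <- expectedDistance(idx, m, "A")
    expect_equal(ed$p, 0.5)
    expect_equal(ed$e_d, sqrt(2) / 12)
    ## the LCA has p = 1 and expected distance exactly 0
    edLca <- expectedDistance(idx, m, "r")
    expect_identical(edLca$p, 1)
    expect_identical(edLca$e_d, 0)
    ## a p = 0 node is negative whenever l_ij < l_i - 1
    edC <- expectedDistance(idx, m, "C")
    expect_identical(edC$p, 0)
    expect_lt(edC$e_d, 0)
})

test_that("best-q rule falls back to the LCA on non-positive distances", {
    ## hits = all leaves of a star: every non-LCA candidate has E(D) < 0
    idx <- preprocessTaxonomy(parseTaxonomy("(A,B,C,D)r;"))
    m <- HitSet("r", c("A", "B", "C", "D"), idx = idx)
    ch <- bestQPerRead(idx, m)
    expect_identical(ch$node, taxRoot(idx))
    expect_identical(ch$q, 1)
    expect_identical(ch$e_d, 0)
})

test_that("best-q rule picks the positive-maximum node when one exists", {
    idx <- fig1Tree()
    m <- fig1HitSet(idx)
    ch <- bestQPerRead(idx, m)
    ## the subtree holding 3 of 4 hits has the unique positive maximum
    expect_identical(ch$node, resolveNodes(idx, "j"))
    expect_gt(ch$e_d, 0)
    ## the LCA candidate scores 0, so it never beats the positive node
    expect_gt(ch$e_d, expectedDistance(idx, m, "root")$e_d)
})

test_that("precision and recall follow the singleton-truth semantics", {
    idx <- fig1Tree()
    reads <- list(
        HitSet("r1", c("s1", "s5", "s6", "s7"), trueHit = "s5", idx = idx),
        HitSet("r2", c("s2", "s3"), trueHit = "s2", idx = idx))
    recTrue <- do.call(rbind, lapply(reads, function(m)
        truthConfusion(idx, m, trueHit(m))))
    pr <- precisionRecallTruth(recTrue)
    expect_identical(unname(pr["precision"]), 1)
    expect_identical(unname(pr["recall"]), 1)
    ## q = 0: leaf assignments force precision == recall exactly
    tab <- rocTable(idx, reads, qGrid = 0)
    pr0 <- precisionRecallTruth(tab)
    expect_identical(pr0[["precision"]], pr0[["recall"]])
    expect_true(all(tab$l_ij == 1L))
})

test_that("LCA assignments have zero true and expected distance exactly", {
    ## Lemma-3 behavior on simulated reads whose hit set contains the truth
    cfg <- simConfig(seed = 23, nLeaves = 40, ranks = 4, seqLength = 300,
                     readLength = 60, nReads = 120)
    sim <- simulateTaxonomy(cfg)
    rd <- simulateReads(cfg, sim$sequences)
    hs <- matchKMismatch(rd$reads, sim$sequences, sim$taxonomy, k = 2)
    hs <- attachTruth(hs, rd$truth, sim$taxonomy)
    amb <- Filter(function(h)
        length(hits(h)) >= 2 && trueHit(h) %in% hits(h), hs)
    expect_gt(length(amb), 5L)
    for (m in amb) {
        rootI <- lcaOfSet(sim$taxonomy, hits(m))
        expect_identical(truthConfusion(sim$taxonomy, m, rootI)$d, 0)
        expect_identical(expectedDistance(sim$taxonomy, m, rootI)$e_d, 0)
    }
})

test_that("validateSweep aggregates per-q records consistently", {
    idx <- fig1Tree()
    reads <- list(
        HitSet("r1", c("s1", "s5", "s6", "s7"), trueHit = "s5", idx = idx),
        HitSet("r2", c("s2", "s3"), trueHit = "s3", idx = idx),
        HitSet("r3", "s4", trueHit = "s4", idx = idx))   # skipped: 1 hit
    val <- validateSweep(idx, reads, qGrid = c(0, 0.5, 1))
    expect_equal(nrow(val), 3L)
    expect_true(all(val$n == 2L))
    ## q = 1 rows are LCA assignments: G_q = 0 when truth is in every T_i
    expect_equal(val$G_q[val$q == 1], 0)
    expect_equal(val$recall[val$q == 1], 1)
})
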