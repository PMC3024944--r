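## Independent oracles and fixture builders. Everything here works from
## parent pointers only -- no postorder numbers, no interval tests, no
## Euler tour -- so the oracles share no machinery with the code they
## check.

## Figure-style 8-leaf fixture: root( a(s1..s4), j(s5..s8) ); the classic
## worked partition has hits {s1,s5,s6,s7} and candidate node "j" with
## TP = {s5,s6,s7}, FP = {s8}, TN = {s2,s3,s4}, FN = {s1}.
fig1Tree <- function() {
    preprocessTaxonomy(parseTaxonomy(
        "((s1,s2,s3,s4)a,(s5,s6,s7,s8)j)root;"))
}

fig1HitSet <- function(idx) {
    HitSet("r1", c("s1", "s5", "s6", "s7"), trueHit = "s5", idx = idx)
}

## random multifurcating tree with nLeaves leaves, by recursive random
## partition; children counts 2..4 so depths vary; returns an
## unpreprocessed index built from a Newick string (exercises the parser)
randomTreeNewick <- function(nLeaves) {
    counter <- new.env(parent = emptyenv())
    counter$leaf <- 0L; counter$int <- 0L
    rec <- function(n) {
        if (n == 1L) {
            counter$leaf <- counter$leaf + 1L
            return(paste0("L", counter$leaf))
        }
        k <- if (n == 2L) 2L else sample(2L:min(4L, n), 1L)
        parts <- tabulate(sample.int(k, n - k, replace = TRUE), k) + 1L
        counter$int <- counter$int + 1L
        paste0("(", paste(vapply(parts, rec, character(1)), collapse = ","),
               ")I", counter$int)
    }
    paste0(rec(nLeaves), ";")
}

randomTree <- function(nLeaves) {
    parseTaxonomy(randomTreeNewick(nLeaves))
}

randomInstance <- function(maxLeaves = 200L, maxHits = 40L) {
    nl <- sample(3:maxLeaves, 1L)
    idx <- preprocessTaxonomy(randomTree(nl))
    leaves <- taxLeaves(idx)
    m <- sample(2:min(maxHits, nl), 1L)
    HitSetIds <- sample(leaves, m)
    list(idx = idx, m = new("HitSet", readId = "r",
                            hits = as.integer(HitSetIds),
                            trueHit = NA_integer_))
}

## ancestors of j (j excluded), by parent walk
owAncestors <- function(idx, j) {
    p <- nodeParents(idx)
    out <- integer(0)
    j <- p[j]
    while (!is.na(j)) { out <- c(out, j); j <- p[j] }
    out
}

owIsProperAncestor <- function(idx, j, j2) {
    j %in% owAncestors(idx, j2)
}

## two-pointer parent-walk LCA
owLca <- function(idx, u, v) {
    au <- c(u, owAncestors(idx, u))
    while (!(v %in% au)) v <- nodeParents(idx)[v]
    v
}

owLcaSet <- function(idx, ids) {
    acc <- ids[1L]
    for (x in ids[-1L]) acc <- owLca(idx, acc, x)
    acc
}

## per-node hit and leaf counts by explicit leaf-set enumeration: every
## leaf walks to the root depositing itself along the way
owCounts <- function(idx, hitIds) {
    n <- nNodes(idx)
    tp <- numeric(n); l <- numeric(n)
    for (lf in taxLeaves(idx)) {
        chain <- c(lf, owAncestors(idx, lf))
        l[chain] <- l[chain] + 1
        if (lf %in% hitIds) tp[chain] <- tp[chain] + 1
    }
    list(tp = tp, l = l)
}

## brute-force penalty-score minimum over *all* nodes of T_i, by scoring
## every node of the taxonomy from enumerated leaf sets
owAssign <- function(idx, hitIds, q) {
    cnt <- owCounts(idx, hitIds)
    M <- length(hitIds)
    rootI <- owLcaSet(idx, hitIds)
    inTi <- vapply(seq_len(nNodes(idx)), function(j)
        j == rootI || owIsProperAncestor(idx, rootI, j), logical(1))
    ps <- rep(Inf, nNodes(idx))
    ok <- inTi & cnt$tp > 0
    ps[ok] <- (q * (M - cnt$tp[ok]) +
               (1 - q) * (cnt$l[ok] - cnt$tp[ok])) / cnt$tp[ok]
    smin <- min(ps)
    list(score = smin,
         best = which(ps - smin <= 1e-12 * max(1, abs(smin))),
         ps = ps, inTi = inTi, tp = cnt$tp, l = cnt$l, root = rootI)
}

## brute-force F-measure maximizers over T_i (nodes with tp = 0 score 0)
owFMeasure <- function(idx, hitIds) {
    cnt <- owCounts(idx, hitIds)
    M <- length(hitIds)
    rootI <- owLcaSet(idx, hitIds)
    inTi <- vapply(seq_len(nNodes(idx)), function(j)
        j == rootI || owIsProperAncestor(idx, rootI, j), logical(1))
    fn <- M - cnt$tp
    fp <- cnt$l - cnt$tp
    f <- ifelse(inTi, 2 * cnt$tp / (fn + fp + 2 * cnt$tp), -Inf)
    fmax <- max(f)
    which(f >= fmax - 1e-12 * max(1, abs(fmax)))
}

## quadratic relevant-node oracle: hits plus all pairwise LCAs
owRelevantNodes <- function(idx, hitIds) {
    out <- as.integer(hitIds)
    k <- length(hitIds)
    for (a in seq_len(k - 1L))
        for (b in (a + 1L):k)
            out <- c(out, owLca(idx, hitIds[a], hitIds[b]))
    sort(unique(out))
}
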