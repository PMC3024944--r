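## Penalty-score assignment of ambiguous reads.
##
## For a read with hit set M_i, let T_i be the subtree rooted at the LCA of
## M_i. Choosing a node j of T_i partitions the leaves of T_i into
## TP (hits under j), FP (non-hits under j), FN (hits outside j) and TN
## (non-hits outside j), and the penalty score is
##
##     PS(j) = ( q * |FN| + (1 - q) * |FP| ) / |TP|,   PS = Inf if |TP| = 0
##
## so q = 1 is minimized (score 0) at the LCA, q = 0 at a hit leaf, and
## q = 0.5 is equivalent to maximizing the F-measure. Two routes compute
## the same minimum: assignNaive scores every node of T_i by the recursive
## count relations (time O(|T_i|)), assignFast scores only the relevant
## nodes (hit leaves and LCAs of pairs of hits), which form the topological
## restriction T_i || M_i and always contain an optimum (time O(|M_i|)
## after preprocessing).

.PS_TOL <- 1e-12

.checkQ <- function(q) {
    if (!is.numeric(q) || anyNA(q) || any(q < 0) || any(q > 1))
        stop("q must lie in [0, 1]")
}

#' Penalty score from confusion counts
#'
#' \eqn{PS = q \cdot |FN|/|TP| + (1-q) \cdot |FP|/|TP|}, with
#' \eqn{PS = \infty} when \eqn{|TP| = 0}. Vectorized over \code{q}.
#'
#' @param counts named vector or list with elements \code{tp}, \code{fp},
#'   \code{fn} (and optionally \code{tn}, unused by the formula).
#' @param q weight(s) in [0,1]; \code{q = 1} weighs only false negatives
#'   (recall), \code{q = 0} only false positives (precision).
#' @return numeric score(s), possibly \code{Inf}.
#' @examples
#' penaltyScore(c(tp = 3, fp = 1, tn = 3, fn = 1), q = 0.5)  # 1/3
#' @export
penaltyScore <- function(counts, q) {
    .checkQ(q)
    counts <- as.list(counts)
    tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
    fn <- as.numeric(counts$fn)
    if (anyNA(c(tp, fp, fn)) || tp < 0 || fp < 0 || fn < 0)
        stop("counts must be non-negative and contain tp, fp, fn")
    if (tp == 0) return(rep(Inf, length(q)))
    (q * fn + (1 - q) * fp) / tp
}

## tie set under the package-wide relative tolerance
.tieSet <- function(scores) {
    smin <- min(scores)
    if (!is.finite(smin)) return(which(!is.finite(scores)))
    which(scores - smin <= .PS_TOL * max(1, abs(smin)))
}

## canonical representative: fewest subtree leaves, then smallest postorder
.canonical <- function(idx, ties) {
    ties[order(idx@nLeaves[ties], idx@post[ties])][1L]
}

.mkAssignment <- function(idx, m, q, bestIds, score, tp, fp, li) {
    canon <- .canonical(idx, bestIds)
    ctp <- tp[match(canon, bestIds)]
    cfp <- fp[match(canon, bestIds)]
    M <- length(m@hits)
    counts <- c(tp = ctp, fp = cfp,
                tn = (li - M) - cfp, fn = M - ctp)
    new("Assignment", readId = m@readId, q = q,
        bestNodes = as.integer(bestIds), canonicalNode = canon,
        score = score, counts = as.numeric(counts),
        rank = idx@rank[canon], status = "ambiguous")
}

#' Assign a read by scoring every node of the LCA subtree
#'
#' Reference implementation of the penalty-score optimum: identifies the
#' root of \eqn{T_i} by a bottom-up traversal from the hit leaves (the
#' first ancestor of all of them, detected by counting hit descendants),
#' then a top-down traversal of \eqn{T_i} computing \eqn{|M_{i,j}|},
#' \eqn{|L_{i,j}|} and the penalty score for every node by the recursive
#' relations: at a leaf, \eqn{|M_{i,j}|} is 1 if the leaf is a hit and 0
#' otherwise; at an internal node the counts are the sums over the
#' children, and \eqn{|N_{i,j}| = |L_{i,j}| - |M_{i,j}|}. Returns
#' \emph{all} minimum-score nodes. Time O(|T_i|).
#'
#' @param idx a preprocessed \code{\linkS4class{TaxonomyIndex}}.
#' @param m a \code{\linkS4class{HitSet}} with at least two hits.
#' @param q weight in [0,1].
#' @return an \code{\linkS4class{Assignment}}.
#' @seealso \code{\link{assignFast}} for the O(|M_i|) route.
#' @export
assignNaive <- function(idx, m, q) {
    .checkPreprocessed(idx)
    .checkQ(q)
    stopifnot(is(m, "HitSet"), length(q) == 1L)
    hitIds <- m@hits
    if (length(hitIds) < 2L)
        stop("assignNaive requires an ambiguous read (>= 2 hits)")
    if (any(hitIds < 1L | hitIds > nNodes(idx)) || !all(idx@leaf[hitIds]))
        stop("hits must be leaves of this taxonomy")
    M <- length(hitIds)
    ## bottom-up: count hit descendants along the leaf-to-root paths; the
    ## first (deepest) node with count |M_i| is the root of T_i
    cnt <- integer(nNodes(idx))
    for (h in hitIds) {
        j <- h
        while (!is.na(j)) { cnt[j] <- cnt[j] + 1L; j <- idx@parent[j] }
    }
    rootI <- hitIds[1L]
    while (cnt[rootI] < M) rootI <- idx@parent[rootI]
    ## top-down: collect T_i in BFS order, then apply the recursions from
    ## the leaves upward
    nodes <- rootI
    frontier <- rootI
    while (length(frontier)) {
        nxt <- unlist(idx@children[frontier], use.names = FALSE)
        nodes <- c(nodes, nxt)
        frontier <- nxt
    }
    k <- length(nodes)
    pos <- integer(nNodes(idx)); pos[nodes] <- seq_len(k)
    tp <- numeric(k); l <- numeric(k)
    isHit <- logical(nNodes(idx)); isHit[hitIds] <- TRUE
    for (i in k:1L) {
        j <- nodes[i]
        kids <- idx@children[[j]]
        if (length(kids) == 0L) {
            tp[i] <- as.numeric(isHit[j]); l[i] <- 1
        } else {
            tp[i] <- sum(tp[pos[kids]]); l[i] <- sum(l[pos[kids]])
        }
    }
    fp <- l - tp
    fn <- M - tp
    ps <- ifelse(tp == 0, Inf, (q * fn + (1 - q) * fp) / tp)
    ties <- .tieSet(ps)
    .mkAssignment(idx, m, q, nodes[ties], min(ps), tp[ties], fp[ties],
                  li = l[1L])
}

#' Build the topological restriction of the taxonomy to a hit set
#'
#' Computes \eqn{T_i || M_i}, the tree of relevant nodes, in O(|M_i|)
#' LCA/ancestor queries: sort the hit leaves by postorder number, take the
#' LCA of each adjacent pair, sort the union of hits and pair-LCAs by
#' (subtree-interval start, decreasing postorder) so that ancestors precede
#' descendants, and recover the edges with a stack of open ancestors. Hit
#' counts \eqn{|M_{i,j}|} are then accumulated bottom-up.
#'
#' @param idx a preprocessed \code{\linkS4class{TaxonomyIndex}}.
#' @param m a \code{\linkS4class{HitSet}} with at least two hits.
#' @return a \code{\linkS4class{RestrictedTree}} with nodes in root-first
#'   order.
#' @export
buildRestriction <- function(idx, m) {
    .checkPreprocessed(idx)
    stopifnot(is(m, "HitSet"))
    hitIds <- m@hits
    if (length(hitIds) < 2L)
        stop("buildRestriction requires >= 2 hits")
    if (!all(idx@leaf[hitIds]))
        stop("hits must be leaves of this taxonomy")
    lv <- hitIds[order(idx@post[hitIds])]
    ks <- .lcaVec(idx, lv[-length(lv)], lv[-1L])
    U <- unique(c(lv, ks))
    ## ancestors first: non-decreasing m(j), decreasing post(j)
    U <- U[order(idx@m[U], -idx@post[U])]
    k <- length(U)
    parent <- rep(NA_integer_, k)
    stack <- integer(k); sp <- 0L
    mm <- idx@m; pp <- idx@post
    for (i in seq_len(k)) {
        j <- U[i]
        while (sp > 0L &&
               !(mm[stack[sp]] <= mm[j] && pp[j] < pp[stack[sp]]))
            sp <- sp - 1L
        if (sp > 0L) parent[i] <- stack[sp]
        sp <- sp + 1L; stack[sp] <- j
    }
    mc <- as.integer(U %in% hitIds)
    posU <- integer(nNodes(idx)); posU[U] <- seq_len(k)
    for (i in k:2L)
        mc[posU[parent[i]]] <- mc[posU[parent[i]]] + mc[i]
    new("RestrictedTree", nodes = U, parent = parent, root = U[1L],
        mCount = mc)
}

setMethod("show", "RestrictedTree", function(object) {
    cat("RestrictedTree with", length(object@nodes),
        "relevant nodes, rooted at node", object@root, "\n")
})

## score all relevant nodes of a restriction for each q in qs; returns a
## list with one element per q: list(best, score, tp, fp)
.scoreRestriction <- function(idx, rt, qs) {
    tp <- as.numeric(rt@mCount)
    l <- as.numeric(idx@nLeaves[rt@nodes])
    fp <- l - tp
    M <- tp[1L]                       # root carries all hits
    fn <- M - tp
    lapply(qs, function(q) {
        ps <- (q * fn + (1 - q) * fp) / tp   # tp >= 1 at relevant nodes
        ties <- .tieSet(ps)
        list(best = rt@nodes[ties], score = min(ps),
             tp = tp[ties], fp = fp[ties])
    })
}

#' Assign a read by scoring only the relevant nodes
#'
#' Evaluates the penalty score on the nodes of the topological restriction
#' \eqn{T_i || M_i} only, using the precomputed subtree leaf counts
#' (\eqn{|N_{i,j}| = |L_j| - |M_{i,j}|}). An optimum is always attained at
#' a relevant node, so the minimum score equals the minimum of
#' \code{\link{assignNaive}} over all of \eqn{T_i}; the reported tie set,
#' however, contains relevant nodes only (non-relevant co-minimizers, which
#' can exist, are deliberately dropped). Time O(|M_i|) per read after
#' preprocessing.
#'
#' @inheritParams assignNaive
#' @return an \code{\linkS4class{Assignment}}.
#' @export
assignFast <- function(idx, m, q) {
    .checkPreprocessed(idx)
    .checkQ(q)
    stopifnot(length(q) == 1L)
    rt <- buildRestriction(idx, m)
    res <- .scoreRestriction(idx, rt, q)[[1L]]
    .mkAssignment(idx, m, q, res$best, res$score, res$tp, res$fp,
                  li = idx@nLeaves[rt@root])
}

#' Assign a read, dispatching on the number of hits
#'
#' No hits: an unassigned record. One hit: that leaf, score 0, counts
#' \code{tp = 1, fp = tn = fn = 0}. Two or more hits: the fast
#' penalty-score assignment.
#'
#' @inheritParams assignNaive
#' @param m a \code{\linkS4class{HitSet}} (any number of hits).
#' @return an \code{\linkS4class{Assignment}}.
#' @export
assignRead <- function(idx, m, q) {
    .checkPreprocessed(idx)
    .checkQ(q)
    n <- length(m@hits)
    if (n == 0L)
        return(new("Assignment", readId = m@readId, q = q,
                   bestNodes = integer(0), canonicalNode = NA_integer_,
                   score = NA_real_,
                   counts = c(tp = NA_real_, fp = NA_real_, tn = NA_real_,
                              fn = NA_real_),
                   rank = NA_character_, status = "unassigned"))
    if (n == 1L)
        return(new("Assignment", readId = m@readId, q = q,
                   bestNodes = m@hits, canonicalNode = m@hits,
                   score = 0,
                   counts = c(tp = 1, fp = 0, tn = 0, fn = 0),
                   rank = idx@rank[m@hits], status = "unique"))
    assignFast(idx, m, q)
}

#' Sweep the q grid over a set of reads
#'
#' One assignment per read per \code{q}, computed with a single
#' restriction build per read. Reported \code{q} values are rounded to
#' 1e-6.
#'
#' @param idx a preprocessed \code{\linkS4class{TaxonomyIndex}}.
#' @param hitsets a list of \code{\linkS4class{HitSet}}.
#' @param qGrid numeric grid in [0,1] (default 0, 0.1, ..., 1).
#' @return a \code{data.frame} with one row per (read, q): columns
#'   \code{read_id}, \code{q}, \code{node_id}, \code{node}, \code{rank},
#'   \code{score}, \code{tp}, \code{fp}, \code{tn}, \code{fn},
#'   \code{n_ties}, \code{status}.
#' @export
sweepQ <- function(idx, hitsets, qGrid = seq(0, 1, by = 0.1)) {
    .checkPreprocessed(idx)
    .checkQ(qGrid)
    qGrid <- round(qGrid, 6L)
    nq <- length(qGrid)
    rows <- vector("list", length(hitsets))
    for (r in seq_along(hitsets)) {
        m <- hitsets[[r]]
        nh <- length(m@hits)
        if (nh < 2L) {
            a <- assignRead(idx, m, qGrid[1L])
            rows[[r]] <- data.frame(
                read_id = m@readId, q = qGrid,
                node_id = if (nh) m@hits else NA_integer_,
                node = if (nh) idx@nodeName[m@hits] else NA_character_,
                rank = if (nh) idx@rank[m@hits] else NA_character_,
                score = if (nh) 0 else NA_real_,
                tp = if (nh) 1 else NA_real_, fp = if (nh) 0 else NA_real_,
                tn = if (nh) 0 else NA_real_, fn = if (nh) 0 else NA_real_,
                n_ties = if (nh) 1L else 0L, status = a@status,
                stringsAsFactors = FALSE)
            next
        }
        rt <- buildRestriction(idx, m)
        li <- idx@nLeaves[rt@root]
        M <- nh
        res <- .scoreRestriction(idx, rt, qGrid)
        canon <- vapply(res, function(x) .canonical(idx, x$best), integer(1))
        ctp <- vapply(seq_len(nq), function(i)
            res[[i]]$tp[match(canon[i], res[[i]]$best)], numeric(1))
        cfp <- vapply(seq_len(nq), function(i)
            res[[i]]$fp[match(canon[i], res[[i]]$best)], numeric(1))
        rows[[r]] <- data.frame(
            read_id = m@readId, q = qGrid, node_id = canon,
            node = idx@nodeName[canon], rank = idx@rank[canon],
            score = vapply(res, `[[`, numeric(1), "score"),
            tp = ctp, fp = cfp, tn = (li - M) - cfp, fn = M - ctp,
            n_ties = vapply(res, function(x) length(x$best), integer(1)),
            status = "ambiguous", stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Distribution of assignment ranks per q
#'
#' Tabulates the rank of the canonical node per value of \code{q};
#' unassigned reads are excluded from the table and reported in the
#' \code{"unassigned"} attribute.
#'
#' @param assignments the data.frame returned by \code{\link{sweepQ}}.
#' @param idx optional \code{\linkS4class{TaxonomyIndex}} used to order the
#'   ranks from root to leaf level.
#' @return a rank-by-q contingency table.
#' @export
rankDistribution <- function(assignments, idx = NULL) {
    keep <- assignments$status != "unassigned"
    tab <- table(rank = assignments$rank[keep],
                 q = assignments$q[keep])
    if (!is.null(idx)) {
        ord <- unique(idx@rank[order(idx@depth)])
        ord <- ord[ord %in% rownames(tab)]
        tab <- tab[ord, , drop = FALSE]
    }
    attr(tab, "unassigned") <-
        table(q = assignments$q[!keep])
    tab
}

## ---- Assignment accessors ------------------------------------------------

#' @rdname Assignment-class
#' @export
setMethod("readId", "Assignment", function(x) x@readId)

#' @rdname Assignment-class
#' @export
setMethod("bestNodes", "Assignment", function(x) x@bestNodes)

#' @rdname Assignment-class
#' @export
setMethod("canonicalNode", "Assignment", function(x) x@canonicalNode)

#' @rdname Assignment-class
#' @export
setMethod("assignmentScore", "Assignment", function(x) x@score)

#' @rdname Assignment-class
#' @export
setMethod("confusionCounts", "Assignment", function(x) {
    stats::setNames(x@counts, c("tp", "fp", "tn", "fn"))
})

setMethod("show", "Assignment", function(object) {
    cat("Assignment of read", object@readId, "at q =", object@q, "\n")
    if (object@status == "unassigned") {
        cat("  unassigned (no hits)\n")
    } else {
        cat("  node", object@canonicalNode, "(", object@rank, "), score",
            format(object@score), ",", length(object@bestNodes),
            "tie(s)\n")
        cat("  counts: tp", object@counts[1L], "fp", object@counts[2L],
            "tn", object@counts[3L], "fn", object@counts[4L], "\n")
    }
})
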