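## ROC-space validation against known true source leaves.
##
## For a simulated read the true source leaf H_i is known. Treating the
## truth as the singleton set {H_i}, an assignment to node j inside T_i has
## TPR_H = 1 if H_i lies under j and 0 otherwise, and
## FPR_H = (|L_{i,j}| - TPR_H) / (|L_i| - 1): the non-H leaves under j over
## all non-H leaves of T_i. The read is the point (FPR_H, TPR_H) in ROC
## space, and its signed distance to the diagonal is
##
##   D = +(sqrt(2)/2) (|L_i| - |L_{i,j]|)     / (|L_i| - 1)   if H under j
##   D = -(sqrt(2)/2) (|L_i| - |L_{i,j}| - 1) / (|L_i| - 1)   otherwise
##
## (both formulas implemented exactly as stated; note the negative branch
## is not the geometric point-to-diagonal distance of (FPR, 0) -- see the
## methods vignette). G_q sums D over reads at a fixed q. The expected
## distance replaces the unknown truth with p = |M_{i,j}|/|M_i|, the
## fraction of hits under j, and is therefore usable on real data:
## E(D) = p D_in + (1 - p) D_out. Assignments to the LCA always have
## D = 0 and E(D) = 0: they carry no predictive power.

.SQRT2_2 <- sqrt(2) / 2

## number of hits under node j, via the postorder interval of j
.hitsUnder <- function(idx, hitIds, node) {
    sum(idx@post[hitIds] >= idx@m[node] &
        idx@post[hitIds] <= idx@post[node])
}

#' Truth-based confusion for one read and one candidate node
#'
#' Computes the singleton-truth ROC quantities for assigning read
#' \code{m} (with known true hit) to \code{node}: whether the true leaf
#' lies in the subtree of \code{node}, the true and false positive rates,
#' the signed distance to the ROC diagonal, and the leaf counts
#' \eqn{|L_i|} (under the LCA of the hit set) and \eqn{|L_{i,j}|} (under
#' the candidate node). Records with \eqn{|L_i| = 1} are flagged
#' degenerate and excluded from all sums downstream.
#'
#' @param idx a preprocessed \code{\linkS4class{TaxonomyIndex}}.
#' @param m a \code{\linkS4class{HitSet}} with \code{trueHit} known.
#' @param node candidate node id or name (must lie in \eqn{T_i}).
#' @return a one-row \code{data.frame} (an ROC record) with columns
#'   \code{read_id}, \code{node_id}, \code{h_in_subtree}, \code{tpr_h},
#'   \code{fpr_h}, \code{d}, \code{l_i}, \code{l_ij}, \code{degenerate}.
#' @export
truthConfusion <- function(idx, m, node) {
    .checkPreprocessed(idx)
    stopifnot(is(m, "HitSet"))
    if (is.na(m@trueHit))
        stop("truthConfusion requires a known true hit")
    node <- resolveNodes(idx, node)
    rootI <- lcaOfSet(idx, m@hits)
    if (!(node == rootI || isProperAncestor(idx, rootI, node)))
        stop("candidate node must lie in the subtree rooted at the LCA")
    li <- idx@nLeaves[rootI]
    lij <- idx@nLeaves[node]
    hIn <- node == m@trueHit || isProperAncestor(idx, node, m@trueHit)
    tpr <- as.numeric(hIn)
    degenerate <- li <= 1L
    fpr <- if (degenerate) NA_real_ else (lij - tpr) / (li - 1)
    rec <- data.frame(read_id = m@readId, node_id = node,
                      h_in_subtree = hIn, tpr_h = tpr, fpr_h = fpr,
                      d = NA_real_, l_i = li, l_ij = lij,
                      degenerate = degenerate, stringsAsFactors = FALSE)
    rec$d <- rocDistance(rec)
    rec
}

#' Signed ROC distance of records to the diagonal
#'
#' Positive when the true hit lies under the assigned node, negative
#' otherwise; zero for LCA assignments. Vectorized over the rows of an
#' ROC record table; degenerate records give \code{NA}.
#'
#' @param rec a data.frame with columns \code{h_in_subtree}, \code{l_i},
#'   \code{l_ij} (as produced by \code{\link{truthConfusion}} or
#'   \code{\link{rocTable}}).
#' @return numeric vector of signed distances in
#'   \eqn{[-\sqrt2/2, \sqrt2/2]}.
#' @export
rocDistance <- function(rec) {
    d <- ifelse(rec$h_in_subtree,
                .SQRT2_2 * (rec$l_i - rec$l_ij) / (rec$l_i - 1),
                -.SQRT2_2 * (rec$l_i - rec$l_ij - 1) / (rec$l_i - 1))
    d[rec$l_i <= 1L] <- NA_real_
    d
}

#' Goodness G_q of a set of ROC records
#'
#' The sum of signed distances to the ROC diagonal over all reads assigned
#' at a fixed \code{q}; the \code{q} maximizing it has the highest
#' predictive power. Degenerate records are dropped.
#'
#' @param records a data.frame of ROC records.
#' @return a single number.
#' @export
goodnessGq <- function(records) {
    sum(records$d[!records$degenerate], na.rm = FALSE)
}

#' Expected signed distance without knowing the truth
#'
#' Weighs the two branches of the signed distance by the probability
#' \eqn{p = |M_{i,j}|/|M_i|} that the true hit lies under the candidate
#' node, assuming it is one of the hits:
#' \eqn{E(D) = p D_{H\in} + (1-p) D_{H\notin}}. Usable on real data; the
#' LCA always has \eqn{p = 1} and \eqn{E(D) = 0}.
#'
#' @param idx a preprocessed \code{\linkS4class{TaxonomyIndex}}.
#' @param m a \code{\linkS4class{HitSet}} with at least two hits (the true
#'   hit, if present, is ignored).
#' @param node candidate node id or name within \eqn{T_i}.
#' @return a one-row \code{data.frame} with columns \code{read_id},
#'   \code{node_id}, \code{p}, \code{e_d}, \code{l_i}, \code{l_ij},
#'   \code{degenerate}.
#' @export
expectedDistance <- function(idx, m, node) {
    .checkPreprocessed(idx)
    stopifnot(is(m, "HitSet"))
    if (length(m@hits) < 2L)
        stop("expectedDistance requires an ambiguous read (>= 2 hits)")
    node <- resolveNodes(idx, node)
    rootI <- lcaOfSet(idx, m@hits)
    if (!(node == rootI || isProperAncestor(idx, rootI, node)))
        stop("candidate node must lie in the subtree rooted at the LCA")
    li <- idx@nLeaves[rootI]
    lij <- idx@nLeaves[node]
    p <- .hitsUnder(idx, m@hits, node) / length(m@hits)
    degenerate <- li <= 1L
    ed <- if (degenerate) NA_real_ else
        p * .SQRT2_2 * (li - lij) / (li - 1) -
        (1 - p) * .SQRT2_2 * (li - lij - 1) / (li - 1)
    data.frame(read_id = m@readId, node_id = node, p = p, e_d = ed,
               l_i = li, l_ij = lij, degenerate = degenerate,
               stringsAsFactors = FALSE)
}

## expected distance from precomputed counts (vectorized)
.eDist <- function(p, li, lij) {
    p * .SQRT2_2 * (li - lij) / (li - 1) -
        (1 - p) * .SQRT2_2 * (li - lij - 1) / (li - 1)
}

#' Per-read, per-q ROC records for a dataset
#'
#' For every ambiguous read with known truth, assigns the read at each
#' \code{q} (canonical node of the fast assignment) and evaluates the
#' truth-based ROC record plus the truth-free expected distance at the
#' chosen node.
#'
#' @param idx a preprocessed \code{\linkS4class{TaxonomyIndex}}.
#' @param hitsets a list of \code{\linkS4class{HitSet}}; reads without a
#'   known true hit or with fewer than two hits are skipped.
#' @param qGrid numeric grid in [0,1].
#' @return a data.frame with one row per (read, q): the ROC record columns
#'   plus \code{q}, \code{p} and \code{e_d}.
#' @export
rocTable <- function(idx, hitsets, qGrid = seq(0, 1, by = 0.1)) {
    .checkPreprocessed(idx)
    .checkQ(qGrid)
    qGrid <- round(qGrid, 6L)
    rows <- vector("list", length(hitsets))
    for (r in seq_along(hitsets)) {
        m <- hitsets[[r]]
        if (length(m@hits) < 2L || is.na(m@trueHit)) next
        rt <- buildRestriction(idx, m)
        li <- idx@nLeaves[rt@root]
        res <- .scoreRestriction(idx, rt, qGrid)
        canon <- vapply(res, function(x) .canonical(idx, x$best), integer(1))
        pos <- match(canon, rt@nodes)
        lij <- idx@nLeaves[canon]
        p <- rt@mCount[pos] / length(m@hits)
        hIn <- canon == m@trueHit |
            (idx@m[canon] <= idx@m[m@trueHit] &
             idx@post[m@trueHit] < idx@post[canon])
        rec <- data.frame(read_id = m@readId, q = qGrid, node_id = canon,
                          h_in_subtree = hIn, tpr_h = as.numeric(hIn),
                          fpr_h = (lij - as.numeric(hIn)) / (li - 1),
                          d = NA_real_, l_i = li, l_ij = lij,
                          degenerate = li <= 1L, p = p,
                          e_d = .eDist(p, li, lij),
                          stringsAsFactors = FALSE)
        rec$d <- rocDistance(rec)
        rows[[r]] <- rec
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
        stop("no ambiguous reads with known truth to validate")
    rownames(out) <- NULL
    out
}

#' Mean truth-based precision and recall over a set of records
#'
#' Per read, precision is \code{h_in_subtree / l_ij} (the singleton truth
#' over the leaves claimed) and recall is \code{h_in_subtree}; the dataset
#' values are unweighted means over the non-degenerate records. At q = 0
#' every assignment sits at a single leaf, so mean precision and mean
#' recall coincide exactly.
#'
#' @param records a data.frame of ROC records (one q at a time).
#' @return a named numeric vector \code{c(precision =, recall =, n =)}.
#' @export
precisionRecallTruth <- function(records) {
    keep <- !records$degenerate
    pr <- records$h_in_subtree[keep] / records$l_ij[keep]
    rc <- as.numeric(records$h_in_subtree[keep])
    c(precision = mean(pr), recall = mean(rc), n = sum(keep))
}

#' Per-q validation summary for a dataset
#'
#' For each \code{q} in the grid: the goodness \eqn{G_q} (sum of signed
#' distances), mean truth precision and mean truth recall.
#'
#' @inheritParams rocTable
#' @return a data.frame with columns \code{q}, \code{G_q},
#'   \code{precision}, \code{recall}, \code{n}.
#' @export
validateSweep <- function(idx, hitsets, qGrid = seq(0, 1, by = 0.1)) {
    tab <- rocTable(idx, hitsets, qGrid)
    qs <- sort(unique(tab$q))
    out <- do.call(rbind, lapply(qs, function(q) {
        rec <- tab[tab$q == q, , drop = FALSE]
        pr <- precisionRecallTruth(rec)
        data.frame(q = q, G_q = goodnessGq(rec),
                   precision = unname(pr["precision"]),
                   recall = unname(pr["recall"]), n = unname(pr["n"]))
    }))
    rownames(out) <- NULL
    out
}

#' Per-read best-q selection by expected distance
#'
#' Evaluates the truth-free expected distance at the canonical node for
#' each \code{q}; the read is assigned at the \code{q} (smallest in grid
#' order on ties) maximizing it if that maximum is positive, otherwise at
#' the LCA (reported as \code{q = } the top of the grid). Since the LCA
#' always has expected distance 0, it never wins over a strictly positive
#' alternative.
#'
#' @param idx a preprocessed \code{\linkS4class{TaxonomyIndex}}.
#' @param m a \code{\linkS4class{HitSet}} with at least two hits.
#' @param qGrid numeric grid in [0,1].
#' @return a list with \code{node} (id), \code{q}, and \code{e_d} (the
#'   expected distance at the choice; 0 for the LCA fallback).
#' @export
bestQPerRead <- function(idx, m, qGrid = seq(0, 1, by = 0.1)) {
    .checkPreprocessed(idx)
    .checkQ(qGrid)
    if (length(m@hits) < 2L)
        stop("bestQPerRead requires an ambiguous read (>= 2 hits)")
    qGrid <- round(qGrid, 6L)
    rt <- buildRestriction(idx, m)
    li <- idx@nLeaves[rt@root]
    res <- .scoreRestriction(idx, rt, qGrid)
    canon <- vapply(res, function(x) .canonical(idx, x$best), integer(1))
    p <- rt@mCount[match(canon, rt@nodes)] / length(m@hits)
    ed <- .eDist(p, li, idx@nLeaves[canon])
    best <- which.max(ed)
    if (is.finite(ed[best]) && ed[best] > 0)
        list(node = canon[best], q = qGrid[best], e_d = ed[best])
    else
        list(node = rt@root, q = qGrid[length(qGrid)], e_d = 0)
}

#' Best-q assignment table and realized distances for a dataset
#'
#' Applies \code{\link{bestQPerRead}} to every ambiguous read and, where
#' the truth is known, computes the realized signed distance of the chosen
#' node. The realized sum of distances is the headline statistic of the
#' expected-distance metric; the fraction of reads per chosen \code{q}
#' describes how the rule spreads reads over the grid.
#'
#' @inheritParams rocTable
#' @return a data.frame with one row per ambiguous read: \code{read_id},
#'   \code{chosen_q}, \code{node_id}, \code{e_d}, and (when truth is
#'   known) \code{d}.
#' @export
bestQTable <- function(idx, hitsets, qGrid = seq(0, 1, by = 0.1)) {
    .checkPreprocessed(idx)
    rows <- lapply(hitsets, function(m) {
        if (length(m@hits) < 2L) return(NULL)
        ch <- bestQPerRead(idx, m, qGrid)
        d <- NA_real_
        if (!is.na(m@trueHit)) {
            rootI <- lcaOfSet(idx, m@hits)
            li <- idx@nLeaves[rootI]
            lij <- idx@nLeaves[ch$node]
            hIn <- ch$node == m@trueHit ||
                isProperAncestor(idx, ch$node, m@trueHit)
            d <- rocDistance(data.frame(h_in_subtree = hIn, l_i = li,
                                        l_ij = lij))
        }
        data.frame(read_id = m@readId, chosen_q = ch$q,
                   node_id = ch$node, e_d = ch$e_d, d = d,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        stop("no ambiguous reads to validate")
    rownames(out) <- NULL
    out
}
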