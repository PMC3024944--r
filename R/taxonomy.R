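## Reference taxonomy: parsing, preprocessing, ancestor and LCA queries.
##
## Node ids are integers 1..nNodes in creation order. All per-node
## quantities are plain integer vectors indexed by node id, which keeps the
## queries vectorizable. The preprocessing follows the classical scheme:
## left-to-right postorder numbers post(j), the smallest postorder number
## m(j) in each subtree (so that "j is a proper ancestor of j2" is the O(1)
## test m(j) <= m(j2) <= post(j2) < post(j)), subtree leaf counts |L_j|,
## and an Euler tour + sparse table for O(1) LCA queries.

.CANONICAL_RANKS <- c("domain", "phylum", "class", "order", "family",
                      "genus", "species")

#' Parse a reference taxonomy
#'
#' Reads a rooted, possibly multifurcating reference taxonomy either from a
#' Newick string/file (internal node labels allowed) or from a lineage
#' table: a TSV with header \code{leaf<TAB>domain<TAB>...<TAB>species} (or
#' generic \code{level1..levelK}) and one row per leaf. In lineage-table
#' mode internal nodes are created by prefix sharing of the lineages, in
#' first-appearance order; the node at the deepest rank is the leaf itself
#' and is named by the \code{leaf} column. Ranks are assigned by column
#' (table mode) or by depth (Newick mode: the seven canonical rank names
#' when every leaf sits at depth 7, generic \code{level-k} otherwise).
#'
#' @param source a file path, or a character string containing Newick text
#'   (must end in \code{;}), or lines of a lineage table.
#' @param format \code{"newick"} or \code{"lineage_table"}.
#' @return an unpreprocessed \code{\linkS4class{TaxonomyIndex}}; call
#'   \code{\link{preprocessTaxonomy}} before running queries.
#' @examples
#' idx <- parseTaxonomy("((A,B)g1,(C,D)g2)f1;")
#' idx <- preprocessTaxonomy(idx)
#' nodeNames(idx)[taxLeaves(idx)]
#' @export
parseTaxonomy <- function(source, format = c("newick", "lineage_table")) {
    format <- match.arg(format)
    if (length(source) == 0L || all(!nzchar(source)))
        stop("empty taxonomy input")
    if (format == "newick") {
        .parseNewick(source)
    } else {
        .parseLineageTable(source)
    }
}

.parseNewick <- function(source) {
    if (length(source) == 1L && !grepl(";", source) && file.exists(source))
        source <- paste(readLines(source), collapse = "")
    tr <- ape::read.tree(text = paste(source, collapse = ""))
    if (is.null(tr))
        stop("could not parse Newick input")
    ntip <- length(tr$tip.label)
    if (anyDuplicated(tr$tip.label))
        stop("duplicate leaf names in Newick input")
    nint <- tr$Nnode
    n <- ntip + nint
    nodeName <- character(n)
    nodeName[seq_len(ntip)] <- tr$tip.label
    if (!is.null(tr$node.label) && length(tr$node.label) == nint) {
        lab <- tr$node.label
        blank <- !nzchar(lab) | is.na(lab)
        lab[blank] <- paste0("N", which(blank) + ntip)
        nodeName[ntip + seq_len(nint)] <- lab
    } else {
        nodeName[ntip + seq_len(nint)] <- paste0("N", ntip + seq_len(nint))
    }
    parent <- rep(NA_integer_, n)
    children <- vector("list", n)
    for (i in seq_len(n)) children[[i]] <- integer(0)
    ## ape keeps edges in input (cladewise) order, preserving the Newick
    ## left-to-right order of children
    for (e in seq_len(nrow(tr$edge))) {
        p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
        parent[ch] <- p
        children[[p]] <- c(children[[p]], ch)
    }
    root <- ntip + 1L
    .finishParse(nodeName, parent, children, root,
                 leaf = seq_len(n) <= ntip, ranksByDepth = TRUE)
}

.parseLineageTable <- function(source) {
    if (length(source) == 1L && !grepl("\t", source) && file.exists(source))
        source <- readLines(source)
    lines <- source[nzchar(source)]
    if (length(lines) < 2L)
        stop("lineage table needs a header row and at least one leaf row")
    fields <- strsplit(lines, "\t", fixed = TRUE)
    header <- fields[[1L]]
    K <- length(header) - 1L
    if (K < 1L || header[1L] != "leaf")
        stop("lineage table header must be 'leaf' followed by rank columns")
    rankNames <- header[-1L]
    body <- fields[-1L]
    bad <- which(lengths(body) != K + 1L)
    if (length(bad))
        stop("ragged lineage row at line ", bad[1L] + 1L)
    leafNames <- vapply(body, `[`, character(1), 1L)
    if (anyDuplicated(leafNames))
        stop("duplicate leaf names in lineage table: ",
             leafNames[duplicated(leafNames)][1L])
    ## nodes keyed by full lineage prefix; created in first-appearance order
    nodeName <- "root"; parent <- NA_integer_
    children <- list(integer(0)); rank <- "root"; isLeaf <- FALSE
    keyId <- new.env(parent = emptyenv())
    for (r in seq_along(body)) {
        row <- body[[r]]
        prev <- 1L; key <- ""
        for (d in seq_len(K)) {
            label <- if (d == K) row[1L] else row[d + 1L]
            key <- paste0(key, "\r", row[d + 1L])
            id <- keyId[[key]]
            if (is.null(id)) {
                id <- length(nodeName) + 1L
                nodeName[id] <- label
                parent[id] <- prev
                children[[id]] <- integer(0)
                children[[prev]] <- c(children[[prev]], id)
                rank[id] <- rankNames[d]
                isLeaf[id] <- (d == K)
                keyId[[key]] <- id
            } else if (d == K) {
                stop("two leaves share the full lineage ending in '",
                     row[K + 1L], "'")
            }
            prev <- id
        }
    }
    idx <- .finishParse(nodeName, parent, children, root = 1L,
                        leaf = isLeaf, ranksByDepth = FALSE)
    idx@rank <- rank
    idx
}

.finishParse <- function(nodeName, parent, children, root, leaf,
                         ranksByDepth) {
    n <- length(nodeName)
    depth <- rep(NA_integer_, n)
    depth[root] <- 0L
    queue <- root
    while (length(queue)) {
        nxt <- unlist(children[queue], use.names = FALSE)
        depth[nxt] <- depth[rep.int(queue, lengths(children[queue]))] + 1L
        queue <- nxt
    }
    rank <- rep(NA_character_, n)
    if (ranksByDepth) {
        leafDepths <- unique(depth[leaf])
        if (length(leafDepths) == 1L && leafDepths == 7L) {
            scheme <- .CANONICAL_RANKS
        } else {
            scheme <- paste0("level-", seq_len(max(depth)))
        }
        rank[depth == 0L] <- "root"
        pos <- depth >= 1L
        rank[pos] <- scheme[pmin(depth[pos], length(scheme))]
    }
    lookup <- which(leaf)
    names(lookup) <- nodeName[leaf]
    new("TaxonomyIndex", nodeName = nodeName, parent = parent,
        children = children, rank = rank, leaf = leaf,
        post = integer(n), m = integer(n), nLeaves = integer(n),
        depth = depth, postToNode = integer(n), leafLookup = lookup,
        root = as.integer(root), preprocessed = FALSE, euler = list())
}

#' Preprocess a taxonomy for constant-time queries
#'
#' Performs a left-to-right postorder traversal enumerating the nodes from
#' 1 to the number of nodes, records for each node the smallest postorder
#' number \code{m(j)} in its subtree and its descendant leaf count, and
#' builds an Euler tour with a sparse table so that LCA queries take O(1)
#' time after O(n log n) preprocessing. Idempotent.
#'
#' @param idx a \code{\linkS4class{TaxonomyIndex}}.
#' @return the preprocessed index.
#' @export
preprocessTaxonomy <- function(idx) {
    stopifnot(is(idx, "TaxonomyIndex"))
    n <- length(idx@nodeName)
    children <- idx@children
    root <- idx@root
    post <- integer(n)
    tourLen <- 2L * n - 1L
    tour <- integer(tourLen)
    stack <- integer(n + 1L)
    ci <- integer(n)          # next-child pointer per node
    sp <- 1L; stack[1L] <- root
    cnt <- 0L; ti <- 1L; tour[1L] <- root
    while (sp > 0L) {
        j <- stack[sp]
        kids <- children[[j]]
        if (ci[j] < length(kids)) {
            ci[j] <- ci[j] + 1L
            ch <- kids[ci[j]]
            sp <- sp + 1L; stack[sp] <- ch
            ti <- ti + 1L; tour[ti] <- ch
        } else {
            cnt <- cnt + 1L
            post[j] <- cnt
            sp <- sp - 1L
            if (sp > 0L) { ti <- ti + 1L; tour[ti] <- stack[sp] }
        }
    }
    postToNode <- integer(n)
    postToNode[post] <- seq_len(n)
    ## bottom-up passes in postorder (children always precede parents)
    m <- integer(n); nl <- integer(n)
    depth <- idx@depth
    for (p in seq_len(n)) {
        j <- postToNode[p]
        kids <- children[[j]]
        if (length(kids) == 0L) {
            m[j] <- post[j]; nl[j] <- 1L
        } else {
            m[j] <- min(m[kids]); nl[j] <- sum(nl[kids])
        }
    }
    tourDepth <- depth[tour]
    K <- max(0L, floor(log2(tourLen)))
    tab <- matrix(0L, nrow = tourLen, ncol = K + 1L)
    tab[, 1L] <- seq_len(tourLen)
    if (K > 0L) {
        for (k in seq_len(K)) {
            half <- bitwShiftL(1L, k - 1L)
            len <- tourLen - 2L * half + 1L
            if (len < 1L) { tab[, k + 1L] <- tab[, k]; next }
            i <- seq_len(len)
            a <- tab[i, k]; b <- tab[i + half, k]
            tab[i, k + 1L] <- ifelse(tourDepth[a] <= tourDepth[b], a, b)
            rest <- seq.int(len + 1L, tourLen)
            tab[rest, k + 1L] <- tab[rest, k]
        }
    }
    first <- integer(n)
    first[tour[tourLen:1L]] <- tourLen:1L   # keeps the earliest occurrence
    idx@post <- post
    idx@m <- m
    idx@nLeaves <- nl
    idx@postToNode <- postToNode
    idx@euler <- list(node = tour, depth = tourDepth, first = first,
                      table = tab)
    idx@preprocessed <- TRUE
    validObject(idx)
    idx
}

.checkPreprocessed <- function(idx) {
    if (!is(idx, "TaxonomyIndex") || !idx@preprocessed)
        stop("taxonomy must be preprocessed (see preprocessTaxonomy)")
}

#' Resolve node references to node ids
#'
#' Accepts integer ids (validated against the index) or node names
#' (leaves first, then internal nodes).
#'
#' @param idx a \code{\linkS4class{TaxonomyIndex}}.
#' @param x integer ids or character names.
#' @return integer node ids.
#' @export
resolveNodes <- function(idx, x) {
    if (is.character(x)) {
        ids <- unname(idx@leafLookup[x])
        miss <- is.na(ids)
        if (any(miss)) {
            ids[miss] <- match(x[miss], idx@nodeName)
            if (anyNA(ids))
                stop("unknown node name(s): ",
                     paste(x[miss][is.na(ids[miss])], collapse = ", "))
        }
        return(as.integer(ids))
    }
    x <- as.integer(x)
    if (anyNA(x) || any(x < 1L) || any(x > length(idx@nodeName)))
        stop("node id out of range for this taxonomy")
    x
}

#' Constant-time proper-ancestor test
#'
#' \code{j} is a proper ancestor of \code{j2} iff
#' \eqn{m(j) \le m(j') \le post(j') < post(j)} in the postorder numbering.
#' Vectorized over \code{j2}.
#'
#' @param idx a preprocessed \code{\linkS4class{TaxonomyIndex}}.
#' @param j,j2 node ids or names.
#' @return logical vector.
#' @export
isProperAncestor <- function(idx, j, j2) {
    .checkPreprocessed(idx)
    j <- resolveNodes(idx, j); j2 <- resolveNodes(idx, j2)
    idx@m[j] <= idx@m[j2] & idx@post[j2] < idx@post[j]
}

## vectorized LCA over pairs of node ids (no name resolution, no checks)
.lcaVec <- function(idx, u, v) {
    e <- idx@euler
    a <- e$first[u]; b <- e$first[v]
    lo <- pmin(a, b); hi <- pmax(a, b)
    len <- hi - lo + 1L
    k <- floor(log2(len))
    half <- bitwShiftL(1L, k)
    i1 <- e$table[cbind(lo, k + 1L)]
    i2 <- e$table[cbind(hi - half + 1L, k + 1L)]
    e$node[ifelse(e$depth[i1] <= e$depth[i2], i1, i2)]
}

#' Lowest common ancestor of two nodes
#'
#' O(1) per query via the Euler tour and sparse table; \code{lca(u, u)}
#' is \code{u}. Vectorized over pairs.
#'
#' @param idx a preprocessed \code{\linkS4class{TaxonomyIndex}}.
#' @param u,v node ids or names.
#' @return integer node id(s).
#' @export
lca <- function(idx, u, v) {
    .checkPreprocessed(idx)
    .lcaVec(idx, resolveNodes(idx, u), resolveNodes(idx, v))
}

#' Lowest common ancestor of a set of leaves
#'
#' Fold of pairwise LCA queries over a non-empty node set; for a singleton
#' returns the node itself.
#'
#' @param idx a preprocessed \code{\linkS4class{TaxonomyIndex}}.
#' @param leaves node ids or names (non-empty).
#' @return integer node id.
#' @export
lcaOfSet <- function(idx, leaves) {
    .checkPreprocessed(idx)
    ids <- resolveNodes(idx, leaves)
    if (length(ids) == 0L)
        stop("lcaOfSet needs a non-empty node set")
    acc <- ids[1L]
    for (x in ids[-1L]) acc <- .lcaVec(idx, acc, x)
    acc
}

#' Per-node summary table
#'
#' One row per node with name, rank, parent, depth, postorder number,
#' subtree interval start \code{m}, and subtree leaf count.
#'
#' @param idx a \code{\linkS4class{TaxonomyIndex}}.
#' @return a \code{data.frame}.
#' @export
taxTable <- function(idx) {
    data.frame(id = seq_along(idx@nodeName), name = idx@nodeName,
               rank = idx@rank, parent = idx@parent, leaf = idx@leaf,
               depth = idx@depth, post = idx@post, m = idx@m,
               n_leaves = idx@nLeaves, stringsAsFactors = FALSE)
}

#' Serialize a taxonomy to Newick
#'
#' @param idx a \code{\linkS4class{TaxonomyIndex}}.
#' @return a single Newick string (with internal node labels).
#' @export
toNewick <- function(idx) {
    rec <- function(j) {
        kids <- idx@children[[j]]
        if (length(kids) == 0L) return(idx@nodeName[j])
        paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","),
               ")", idx@nodeName[j])
    }
    paste0(rec(idx@root), ";")
}

#' Convert a taxonomy to an ape phylo object
#'
#' @param idx a \code{\linkS4class{TaxonomyIndex}}.
#' @return an \code{ape} \code{phylo} object.
#' @export
asPhylo <- function(idx) {
    ape::read.tree(text = toNewick(idx))
}

#' Write a lineage table for a uniform-depth taxonomy
#'
#' Inverse of the \code{lineage_table} mode of \code{\link{parseTaxonomy}}:
#' one row per leaf, the rank columns holding the names of the leaf's
#' ancestors at depths 1..K (the deepest column repeats the leaf name).
#'
#' @param idx a \code{\linkS4class{TaxonomyIndex}} with uniform leaf depth.
#' @param file a path or connection.
#' @export
writeLineageTable <- function(idx, file) {
    leaves <- which(idx@leaf)
    K <- unique(idx@depth[leaves])
    if (length(K) != 1L)
        stop("lineage tables require a uniform leaf depth")
    if (K == 7L) rankNames <- .CANONICAL_RANKS
    else rankNames <- paste0("level", seq_len(K))
    rows <- vapply(leaves, function(lf) {
        lineage <- character(K)
        j <- lf
        for (d in seq.int(K, 1L)) { lineage[d] <- idx@nodeName[j]
                                    j <- idx@parent[j] }
        paste(c(idx@nodeName[lf], lineage), collapse = "\t")
    }, character(1))
    writeLines(c(paste(c("leaf", rankNames), collapse = "\t"), rows), file)
}

## ---- accessors -----------------------------------------------------------

#' Accessors for TaxonomyIndex
#'
#' @param x a \code{\linkS4class{TaxonomyIndex}}.
#' @name TaxonomyIndex-accessors
#' @aliases nNodes nodeNames nodeRanks nodeParents nodeDepths postOrder
#'   subtreeMin leafCounts taxRoot taxLeaves isPreprocessed
NULL

#' @rdname TaxonomyIndex-accessors
#' @export
setMethod("nNodes", "TaxonomyIndex", function(x) length(x@nodeName))

#' @rdname TaxonomyIndex-accessors
#' @export
setMethod("nodeNames", "TaxonomyIndex", function(x) x@nodeName)

#' @rdname TaxonomyIndex-accessors
#' @export
setMethod("nodeRanks", "TaxonomyIndex", function(x) x@rank)

#' @rdname TaxonomyIndex-accessors
#' @export
setMethod("nodeParents", "TaxonomyIndex", function(x) x@parent)

#' @rdname TaxonomyIndex-accessors
#' @export
setMethod("nodeDepths", "TaxonomyIndex", function(x) x@depth)

#' @rdname TaxonomyIndex-accessors
#' @export
setMethod("postOrder", "TaxonomyIndex", function(x) x@post)

#' @rdname TaxonomyIndex-accessors
#' @export
setMethod("subtreeMin", "TaxonomyIndex", function(x) x@m)

#' @rdname TaxonomyIndex-accessors
#' @export
setMethod("leafCounts", "TaxonomyIndex", function(x) x@nLeaves)

#' @rdname TaxonomyIndex-accessors
#' @export
setMethod("taxRoot", "TaxonomyIndex", function(x) x@root)

#' @rdname TaxonomyIndex-accessors
#' @export
setMethod("taxLeaves", "TaxonomyIndex", function(x) which(x@leaf))

#' @rdname TaxonomyIndex-accessors
#' @export
setMethod("isPreprocessed", "TaxonomyIndex", function(x) x@preprocessed)

setMethod("show", "TaxonomyIndex", function(object) {
    cat("TaxonomyIndex with", length(object@nodeName), "nodes (",
        sum(object@leaf), "leaves ), height",
        max(object@depth), "\n")
    cat("  preprocessed:", object@preprocessed, "\n")
    rk <- unique(object@rank[!is.na(object@rank) & object@rank != "root"])
    if (length(rk))
        cat("  ranks:", paste(rk, collapse = " > "), "\n")
})
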