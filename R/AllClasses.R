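
#' TaxonomyIndex: a preprocessed rooted reference taxonomy
#'
#' Container for a rooted, possibly multifurcating reference taxonomy with
#' named leaves. Nodes are addressed by integer ids \code{1..nNodes(x)} in
#' creation order. After \code{\link{preprocessTaxonomy}} the object also
#' carries, per node, its left-to-right postorder number, the smallest
#' postorder number in its subtree, its subtree leaf count and its depth,
#' plus an Euler-tour/sparse-table structure supporting constant-time
#' lowest-common-ancestor (LCA) queries. Ancestor tests then reduce to the
#' closed interval inclusion \eqn{m(j) \le m(j') \le post(j') < post(j)}.
#'
#' @slot nodeName character, one name per node (leaf names unique).
#' @slot parent integer, parent node id (\code{NA} at the root).
#' @slot children list of integer vectors, ordered left-to-right as in the
#'   input file (determinism of the postorder numbering).
#' @slot rank character rank label per node (\code{domain}..\code{species}
#'   or generic \code{level-k}).
#' @slot leaf logical, \code{TRUE} for leaves.
#' @slot post integer postorder number (1-based; 0 before preprocessing).
#' @slot m integer, smallest postorder number in the node's subtree.
#' @slot nLeaves integer, number of descendant leaves (1 for a leaf).
#' @slot depth integer, edges from the root.
#' @slot postToNode integer, inverse permutation of \code{post}.
#' @slot leafLookup named integer, leaf name to node id.
#' @slot root integer, root node id.
#' @slot preprocessed logical scalar.
#' @slot euler list with the Euler tour (\code{node}, \code{depth},
#'   \code{first}, and the sparse table \code{table}).
#'
#' @seealso \code{\link{parseTaxonomy}}, \code{\link{preprocessTaxonomy}},
#'   \code{\link{lca}}, \code{\link{isProperAncestor}}
#' @exportClass TaxonomyIndex
setClass("TaxonomyIndex",
    representation(
        nodeName = "character",
        parent = "integer",
        children = "list",
        rank = "character",
        leaf = "logical",
        post = "integer",
        m = "integer",
        nLeaves = "integer",
        depth = "integer",
        postToNode = "integer",
        leafLookup = "integer",
        root = "integer",
        preprocessed = "logical",
        euler = "list"
    ),
    prototype(preprocessed = FALSE, euler = list())
)

setValidity("TaxonomyIndex", function(object) {
    n <- length(object@nodeName)
    if (n == 0L)
        return("empty taxonomy")
    if (length(object@parent) != n || length(object@children) != n ||
        length(object@leaf) != n || length(object@rank) != n)
        return("per-node slots must have one entry per node")
    if (length(object@root) != 1L || is.na(object@root) ||
        object@root < 1L || object@root > n)
        return("invalid root id")
    if (!is.na(object@parent[object@root]))
        return("root must have no parent")
    leafNames <- object@nodeName[object@leaf]
    if (anyDuplicated(leafNames))
        return("duplicate leaf names")
    if (object@preprocessed) {
        if (!identical(sort(object@post), seq_len(n)))
            return("postorder numbers must be a permutation of 1..n")
        if (any(object@m > object@post))
            return("m(j) must not exceed post(j)")
        if (any(object@m[object@leaf] != object@post[object@leaf]))
            return("leaves must have m = post")
        if (any(object@nLeaves < 1L))
            return("subtree leaf counts must be positive")
    }
    TRUE
})

#' HitSet: one read's matched reference leaves
#'
#' The set \eqn{M_i} of taxonomy leaves whose sequences matched read
#' \eqn{R_i}, with an optional known true source leaf \eqn{H_i} (available
#' for simulated data only). Reads with an empty hit set are retained and
#' later reported as unassigned.
#'
#' @slot readId character scalar.
#' @slot hits integer vector of leaf node ids (duplicate-free).
#' @slot trueHit integer leaf node id or \code{NA}.
#'
#' @seealso \code{\link{readHitsTsv}}, \code{\link{assignRead}}
#' @exportClass HitSet
setClass("HitSet",
    representation(readId = "character", hits = "integer",
                   trueHit = "integer"),
    prototype(trueHit = NA_integer_)
)

setValidity("HitSet", function(object) {
    if (length(object@readId) != 1L || is.na(object@readId))
        return("readId must be a single non-NA string")
    if (anyDuplicated(object@hits))
        return("hits must be duplicate-free")
    if (anyNA(object@hits))
        return("hits must not contain NA")
    if (length(object@trueHit) != 1L)
        return("trueHit must be a single id or NA")
    TRUE
})

#' RestrictedTree: the topological restriction of the taxonomy to a hit set
#'
#' The tree of \emph{relevant} nodes for a hit set \eqn{M_i}: the hit
#' leaves themselves plus every LCA of two or more hit leaves. It is
#' obtained from the subtree rooted at the LCA of \eqn{M_i} by pruning all
#' paths that do not lead to a hit and contracting unary nodes, and has at
#' most \eqn{2|M_i| - 1} nodes. The penalty-score optimum is always
#' attained at a relevant node, which is what makes assignment in
#' \eqn{O(|M_i|)} time possible.
#'
#' @slot nodes integer, node ids of the taxonomy (relevant nodes),
#'   ordered root-first (parents precede children).
#' @slot parent integer, for each entry of \code{nodes} the taxonomy node
#'   id of its parent \emph{within the restriction} (\code{NA} at the root).
#' @slot root integer, taxonomy node id of the restriction root
#'   (= LCA of the hit set).
#' @slot mCount integer, per entry of \code{nodes}, the number of hit
#'   leaves in its subtree (\eqn{|M_{i,j}|}).
#'
#' @seealso \code{\link{buildRestriction}}, \code{\link{assignFast}}
#' @exportClass RestrictedTree
setClass("RestrictedTree",
    representation(nodes = "integer", parent = "integer", root = "integer",
                   mCount = "integer")
)

setValidity("RestrictedTree", function(object) {
    k <- length(object@nodes)
    if (length(object@parent) != k || length(object@mCount) != k)
        return("parent and mCount must parallel nodes")
    if (sum(is.na(object@parent)) != 1L)
        return("exactly one root (NA parent) expected")
    if (!object@root %in% object@nodes)
        return("root must be a member of nodes")
    TRUE
})

#' Assignment: the penalty-score assignment of one read
#'
#' Result of assigning one read at a given \eqn{q}: all nodes achieving
#' the minimum penalty score, a deterministic canonical representative
#' (fewest subtree leaves, then smallest postorder number), the score, and
#' the confusion counts (TP/FP/TN/FN with respect to the hit set) at the
#' canonical node. \code{status} is one of \code{"unassigned"} (no hits),
#' \code{"unique"} (a single hit) or \code{"ambiguous"}.
#'
#' @slot readId character scalar.
#' @slot q numeric weight in [0,1].
#' @slot bestNodes integer, all minimum-score nodes (empty if unassigned).
#' @slot canonicalNode integer node id (\code{NA} if unassigned).
#' @slot score numeric, the minimum penalty score (\code{NA} if unassigned).
#' @slot counts numeric named vector \code{c(tp=, fp=, tn=, fn=)}.
#' @slot rank character rank label of the canonical node.
#' @slot status character scalar.
#'
#' @seealso \code{\link{assignRead}}, \code{\link{penaltyScore}}
#' @exportClass Assignment
setClass("Assignment",
    representation(readId = "character", q = "numeric",
                   bestNodes = "integer", canonicalNode = "integer",
                   score = "numeric", counts = "numeric", rank = "character",
                   status = "character")
)

setValidity("Assignment", function(object) {
    if (!object@status %in% c("unassigned", "unique", "ambiguous"))
        return("invalid status")
    if (object@status != "unassigned" && length(object@bestNodes) < 1L)
        return("assigned reads must carry at least one best node")
    TRUE
})

#' SimConfig: parameters of the amplicon read simulator
#'
#' Stated world of the synthetic datasets: a uniform-depth ranked taxonomy
#' whose leaf sequences diverge along the tree, and short error-bearing
#' reads drawn from random leaves with a known true source. Defaults mirror
#' 16S rRNA amplicon sequencing with a 454-style error profile: full-length
#' references of 1,500 bp, seven ranks, 100 bp reads, substitution errors
#' plus single-base indels in homopolymer runs, and discarding of reads
#' shorter than 75\% of the expected length.
#'
#' @slot seed integer random seed.
#' @slot nLeaves integer number of reference leaves.
#' @slot ranks integer number of ranks below the root (default 7).
#' @slot branching numeric mean children per internal node.
#' @slot seqLength integer reference sequence length in bp.
#' @slot perLevelSubstitutionRate numeric per-site substitution probability
#'   applied on each parent-to-child edge of the taxonomy.
#' @slot readLength integer expected read length in bp.
#' @slot nReads integer number of reads to draw.
#' @slot substitutionErrorRate numeric per-base sequencing error rate.
#' @slot homopolymerIndelRate numeric probability that a homopolymer run
#'   gains or loses one base.
#' @slot minLengthFraction numeric, reads shorter than this fraction of
#'   \code{readLength} are discarded.
#'
#' @seealso \code{\link{simConfig}}, \code{\link{simulateTaxonomy}},
#'   \code{\link{simulateReads}}
#' @exportClass SimConfig
setClass("SimConfig",
    representation(
        seed = "integer", nLeaves = "integer", ranks = "integer",
        branching = "numeric", seqLength = "integer",
        perLevelSubstitutionRate = "numeric", readLength = "integer",
        nReads = "integer", substitutionErrorRate = "numeric",
        homopolymerIndelRate = "numeric", minLengthFraction = "numeric"
    )
)

setValidity("SimConfig", function(object) {
    rates <- c(object@perLevelSubstitutionRate,
               object@substitutionErrorRate, object@homopolymerIndelRate,
               object@minLengthFraction)
    if (any(rates < 0) || any(rates > 1))
        return("all rates must lie in [0, 1]")
    if (object@readLength >= object@seqLength)
        return("readLength must be smaller than seqLength")
    if (object@nLeaves < 2L)
        return("need at least two leaves")
    if (object@ranks < 1L)
        return("need at least one rank")
    TRUE
})
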