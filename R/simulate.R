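## Synthetic amplicon world: a uniform-depth ranked taxonomy, reference
## sequences that diverge along the tree (so that reads become ambiguous
## among nearby leaves), and short error-bearing reads with a known source
## leaf. The error profile is 454-like: per-base substitutions plus
## single-base indels in homopolymer runs, with short reads discarded.

.BASES <- c("A", "C", "G", "T")

#' Construct a simulation configuration
#'
#' Defaults describe a small 16S-like world: 200 reference leaves under
#' seven ranks, 1,500 bp references, 1\% per-site divergence per taxonomy
#' level (sister species about 98\% identical, the deepest splits about
#' 85\%), 2,000 reads of 100 bp with 0.5\% substitution errors and a 2\%
#' per-homopolymer-run indel rate, discarding reads shorter than 75\% of
#' the expected length.
#'
#' @param seed integer random seed.
#' @param nLeaves number of reference leaves.
#' @param ranks number of ranks below the root.
#' @param branching mean children per internal node.
#' @param seqLength reference length (bp).
#' @param perLevelSubstitutionRate per-site substitution probability per
#'   parent-to-child edge.
#' @param readLength expected read length (bp).
#' @param nReads number of reads to draw.
#' @param substitutionErrorRate per-base sequencing substitution rate.
#' @param homopolymerIndelRate per-homopolymer-run probability of a
#'   single-base insertion or deletion.
#' @param minLengthFraction discard reads shorter than this fraction of
#'   \code{readLength}.
#' @return a \code{\linkS4class{SimConfig}}.
#' @export
simConfig <- function(seed = 1L, nLeaves = 200L, ranks = 7L,
                      branching = 3, seqLength = 1500L,
                      perLevelSubstitutionRate = 0.01,
                      readLength = 100L, nReads = 2000L,
                      substitutionErrorRate = 0.005,
                      homopolymerIndelRate = 0.02,
                      minLengthFraction = 0.75) {
    new("SimConfig", seed = as.integer(seed), nLeaves = as.integer(nLeaves),
        ranks = as.integer(ranks), branching = as.numeric(branching),
        seqLength = as.integer(seqLength),
        perLevelSubstitutionRate = perLevelSubstitutionRate,
        readLength = as.integer(readLength), nReads = as.integer(nReads),
        substitutionErrorRate = substitutionErrorRate,
        homopolymerIndelRate = homopolymerIndelRate,
        minLengthFraction = minLengthFraction)
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig: ", object@nLeaves, " leaves / ", object@ranks,
        " ranks, refs ", object@seqLength, " bp (", 100 *
        object@perLevelSubstitutionRate, "% per level), ",
        object@nReads, " reads of ", object@readLength, " bp\n", sep = "")
})

## substitute each selected position by a uniformly random *different* base
.mutate <- function(codes, sel) {
    n <- sum(sel)
    if (n)
        codes[sel] <- 1L + (codes[sel] - 1L +
                            sample.int(3L, n, replace = TRUE)) %% 4L
    codes
}

#' Simulate a ranked taxonomy with tree-correlated leaf sequences
#'
#' Builds a uniform-depth multifurcating tree over \code{nLeaves} leaves
#' (every leaf at depth \code{ranks}; the seven canonical rank names are
#' applied when \code{ranks == 7}), draws a uniform random root sequence,
#' and mutates it along every edge at \code{perLevelSubstitutionRate} per
#' site, so sequence similarity decays with tree distance. This is what
#' makes short reads ambiguous among nearby leaves. Sets the RNG seed from
#' the configuration; identical configurations give identical output.
#'
#' @param cfg a \code{\linkS4class{SimConfig}}.
#' @return a list with \code{taxonomy} (a preprocessed
#'   \code{\linkS4class{TaxonomyIndex}}) and \code{sequences} (a
#'   \code{DNAStringSet} of leaf sequences named by leaf).
#' @export
simulateTaxonomy <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    set.seed(cfg@seed)
    nodeName <- "root"; parent <- NA_integer_
    children <- list(integer(0)); isLeaf <- FALSE
    seqs <- list(sample.int(4L, cfg@seqLength, replace = TRUE))
    nextLeaf <- 0L
    ## stack of (node id, leaves to place below it, depth); DFS so that
    ## leaf numbering is left-to-right
    stack <- list(list(id = 1L, n = cfg@nLeaves, depth = 0L))
    while (length(stack)) {
        top <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        nch <- if (top$depth == cfg@ranks - 1L) top$n
               else if (top$n == 1L) 1L
               else min(top$n, max(1L, stats::rpois(1L, cfg@branching)))
        parts <- if (nch == top$n) rep(1L, nch)
                 else tabulate(sample.int(nch, top$n - nch, replace = TRUE),
                               nch) + 1L
        kids <- integer(nch)
        for (c in seq_len(nch)) {
            id <- length(nodeName) + 1L
            leafHere <- top$depth + 1L == cfg@ranks
            if (leafHere) {
                nextLeaf <- nextLeaf + 1L
                nodeName[id] <- sprintf("s%04d", nextLeaf)
            } else {
                nodeName[id] <- paste0("n", id)
            }
            parent[id] <- top$id
            children[[id]] <- integer(0)
            isLeaf[id] <- leafHere
            seqs[[id]] <- .mutate(seqs[[top$id]],
                                  stats::runif(cfg@seqLength) <
                                      cfg@perLevelSubstitutionRate)
            kids[c] <- id
            if (!leafHere)
                stack[[length(stack) + 1L]] <-
                    list(id = id, n = parts[c], depth = top$depth + 1L)
        }
        children[[top$id]] <- kids
    }
    idx <- .finishParse(nodeName, parent, children, root = 1L,
                        leaf = isLeaf, ranksByDepth = TRUE)
    idx <- preprocessTaxonomy(idx)
    leaves <- which(isLeaf)
    seqChar <- vapply(seqs[leaves], function(s)
        paste(.BASES[s], collapse = ""), character(1))
    names(seqChar) <- nodeName[leaves]
    list(taxonomy = idx, sequences = Biostrings::DNAStringSet(seqChar))
}

## apply +-1 bp indels to homopolymer runs (>= 2 bases) of an integer-coded
## read; at most one event per run
.homopolymerIndels <- function(codes, rate) {
    if (rate <= 0) return(codes)
    r <- rle(codes)
    run <- r$lengths >= 2L
    if (!any(run)) return(codes)
    hit <- run & stats::runif(length(r$lengths)) < rate
    if (!any(hit)) return(codes)
    delta <- sample(c(-1L, 1L), sum(hit), replace = TRUE)
    r$lengths[hit] <- pmax(1L, r$lengths[hit] + delta)
    inverse.rle(r)
}

.drawReads <- function(cfg, sequences, lo, hi, seedOffset = 1L) {
    set.seed(cfg@seed + seedOffset)
    seqChar <- as.character(sequences)
    codes <- lapply(seqChar, function(s)
        match(strsplit(s, "", fixed = TRUE)[[1L]], .BASES))
    leafNames <- names(sequences)
    minLen <- ceiling(cfg@minLengthFraction * cfg@readLength)
    ids <- character(cfg@nReads); out <- character(cfg@nReads)
    src <- character(cfg@nReads); off <- integer(cfg@nReads)
    kept <- logical(cfg@nReads)
    for (i in seq_len(cfg@nReads)) {
        leaf <- sample.int(length(codes), 1L)
        o <- lo + sample.int(hi - lo + 1L, 1L) - 1L      # 0-based offset
        tmpl <- codes[[leaf]][(o + 1L):(o + cfg@readLength)]
        tmpl <- .homopolymerIndels(tmpl, cfg@homopolymerIndelRate)
        tmpl <- .mutate(tmpl, stats::runif(length(tmpl)) <
                                  cfg@substitutionErrorRate)
        ids[i] <- sprintf("read%05d", i)
        if (length(tmpl) >= minLen) {
            kept[i] <- TRUE
            out[i] <- paste(.BASES[tmpl], collapse = "")
            src[i] <- leafNames[leaf]
            off[i] <- o
        }
    }
    reads <- Biostrings::DNAStringSet(out[kept])
    names(reads) <- ids[kept]
    list(reads = reads,
         truth = data.frame(read_id = ids[kept], true_hit = src[kept],
                            offset = off[kept], stringsAsFactors = FALSE))
}

#' Simulate error-bearing reads with known source leaves
#'
#' Draws each read from a uniformly random leaf and a uniformly random
#' window of its reference sequence, applies homopolymer indels and
#' per-base substitution errors, and discards reads shorter than
#' \code{minLengthFraction} of the expected length. The truth table
#' records the source leaf \eqn{H_i} of every retained read. Seeds the RNG
#' from the configuration (offset by one from the taxonomy draw), so the
#' read set is reproducible given the configuration.
#'
#' @param cfg a \code{\linkS4class{SimConfig}}.
#' @param sequences leaf reference sequences (\code{DNAStringSet} named by
#'   leaf), as returned by \code{\link{simulateTaxonomy}}.
#' @return a list with \code{reads} (a named \code{DNAStringSet}) and
#'   \code{truth} (a data.frame with \code{read_id}, \code{true_hit},
#'   \code{offset}).
#' @export
simulateReads <- function(cfg, sequences) {
    stopifnot(is(cfg, "SimConfig"))
    .drawReads(cfg, sequences, lo = 0L,
               hi = cfg@seqLength - cfg@readLength)
}

#' Simulate reads restricted to a sub-region of the references
#'
#' Like \code{\link{simulateReads}} but source windows are restricted to
#' the 0-based half-open interval \code{window} of each reference,
#' emulating amplicons of a hypervariable region (e.g. the first 300 bp
#' for V1-V2).
#'
#' @inheritParams simulateReads
#' @param window integer vector \code{c(start, end)}, 0-based half-open;
#'   must satisfy \code{end - start >= readLength}.
#' @return as \code{\link{simulateReads}}.
#' @export
simulateRegionReads <- function(cfg, sequences, window) {
    stopifnot(is(cfg, "SimConfig"), length(window) == 2L)
    start <- as.integer(window[1L]); end <- as.integer(window[2L])
    if (start < 0L || end > cfg@seqLength ||
        end - start < cfg@readLength)
        stop("window must fit in the references and hold one read length")
    .drawReads(cfg, sequences, lo = start, hi = end - cfg@readLength)
}
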