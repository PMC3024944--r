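## Per-read hit sets M_i: constructors, file readers, and a naive
## k-mismatch matcher standing in for a dedicated read mapper. The matching
## criterion is: leaf l is a hit for read R iff some substring of l's
## reference sequence of length |R| has Hamming distance <= k to R.

#' Construct a HitSet
#'
#' @param readId read identifier.
#' @param hits leaf node ids, or leaf names if \code{idx} is supplied.
#' @param trueHit known true source leaf (id or name), or \code{NA}.
#' @param idx optional \code{\linkS4class{TaxonomyIndex}} used to resolve
#'   names and to check that every hit is a leaf.
#' @return a \code{\linkS4class{HitSet}}.
#' @examples
#' idx <- preprocessTaxonomy(parseTaxonomy("((A,B)g1,(C,D)g2)f1;"))
#' HitSet("r1", c("A", "C"), idx = idx)
#' @export
HitSet <- function(readId, hits, trueHit = NA, idx = NULL) {
    if (!is.null(idx)) {
        hits <- resolveNodes(idx, hits)
        if (!all(idx@leaf[hits]))
            stop("hit '", idx@nodeName[hits[!idx@leaf[hits]]][1L],
                 "' is not a leaf of the taxonomy")
        if (!is.na(trueHit[1L]))
            trueHit <- resolveNodes(idx, trueHit)
    }
    if (anyDuplicated(hits)) {
        warning("duplicate hits for read '", readId, "' deduplicated")
        hits <- unique(hits)
    }
    new("HitSet", readId = as.character(readId), hits = as.integer(hits),
        trueHit = as.integer(trueHit[1L]))
}

#' @rdname HitSet-class
#' @export
setMethod("readId", "HitSet", function(x) x@readId)

#' @rdname HitSet-class
#' @export
setMethod("hits", "HitSet", function(x) x@hits)

#' @rdname HitSet-class
#' @export
setMethod("trueHit", "HitSet", function(x) x@trueHit)

setMethod("show", "HitSet", function(object) {
    cat("HitSet", object@readId, "with", length(object@hits), "hit(s)")
    if (!is.na(object@trueHit)) cat(", true hit known")
    cat("\n")
})

#' Read per-read hit sets from a TSV file
#'
#' Rows are \code{read_id<TAB>comma-separated leaf names}, with an
#' optional third column naming the true source leaf. Duplicate names
#' within a row are deduplicated with a warning; an empty second column
#' gives an empty (unassigned) hit set.
#'
#' @param source a file path or character vector of lines.
#' @param idx a \code{\linkS4class{TaxonomyIndex}}.
#' @return a list of \code{\linkS4class{HitSet}}.
#' @export
readHitsTsv <- function(source, idx) {
    if (length(source) == 1L && !grepl("\t", source) && file.exists(source))
        source <- readLines(source)
    lines <- source[nzchar(source)]
    out <- vector("list", length(lines))
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 1L || length(f) > 3L || !nzchar(f[1L]))
            stop("malformed hits row ", i, ": '", lines[i], "'")
        nm <- if (length(f) >= 2L && nzchar(f[2L]))
            strsplit(f[2L], ",", fixed = TRUE)[[1L]] else character(0)
        unknown <- !(nm %in% names(idx@leafLookup))
        if (any(unknown))
            stop("row ", i, " (read '", f[1L], "'): unknown leaf name(s): ",
                 paste(nm[unknown], collapse = ", "))
        th <- if (length(f) == 3L && nzchar(f[3L])) f[3L] else NA
        out[[i]] <- HitSet(f[1L], nm, trueHit = th, idx = idx)
    }
    out
}

#' Read hit sets from BLAST tabular output with e-value tie grouping
#'
#' Parses 12-column BLAST tabular output (outfmt 6; subject ids must be
#' taxonomy leaf names). For each query, keeps every subject whose e-value
#' equals the query's minimum e-value \emph{and} is at most
#' \code{evalueCutoff}; queries whose best e-value exceeds the cutoff get
#' an empty hit set. This reproduces the convention of calling a read
#' ambiguous when it aligns to more than one species at the same e-value.
#'
#' @param source a file path or character vector of lines.
#' @param idx a \code{\linkS4class{TaxonomyIndex}}.
#' @param evalueCutoff positive e-value threshold (default 0.001).
#' @return a list of \code{\linkS4class{HitSet}} in first-appearance order
#'   of the queries.
#' @export
readBlastTies <- function(source, idx, evalueCutoff = 0.001) {
    stopifnot(evalueCutoff > 0)
    if (length(source) == 1L && !grepl("\t", source) && file.exists(source))
        source <- readLines(source)
    lines <- source[nzchar(source)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) != 12L))
        stop("BLAST tabular rows must have 12 columns")
    qid <- vapply(f, `[`, character(1), 1L)
    sid <- vapply(f, `[`, character(1), 2L)
    ev <- suppressWarnings(as.numeric(vapply(f, `[`, character(1), 11L)))
    if (anyNA(ev))
        stop("unparseable e-value at row ", which(is.na(ev))[1L])
    reads <- unique(qid)
    lapply(reads, function(r) {
        sel <- qid == r
        best <- min(ev[sel])
        keep <- if (best <= evalueCutoff)
            unique(sid[sel & ev == best]) else character(0)
        HitSet(r, keep, idx = idx)
    })
}

.asDNAStringSet <- function(x) {
    if (is(x, "DNAStringSet")) return(x)
    if (is.character(x) && length(x) == 1L && file.exists(x))
        return(Biostrings::readDNAStringSet(x))
    if (is.character(x)) {
        if (is.null(names(x)))
            names(x) <- paste0("seq", seq_along(x))
        return(Biostrings::DNAStringSet(x))
    }
    stop("expected a DNAStringSet, a FASTA path, or named sequences")
}

#' Naive k-mismatch matching of reads against leaf sequences
#'
#' Scans every reference for substrings of read length within Hamming
#' distance \code{k} of the read (no indels); a leaf is a hit if at least
#' one window matches, regardless of how many windows do. This is a
#' deliberately simple stand-in for a production read mapper, quadratic in
#' total reference length times read length, intended for simulations and
#' tests. \code{N} in a read mismatches every reference base (references
#' are assumed to be plain ACGT).
#'
#' @param reads FASTA path, \code{DNAStringSet}, or named character vector.
#' @param refs reference sequences (same forms); names must be leaf names.
#' @param idx a \code{\linkS4class{TaxonomyIndex}} resolving leaf names.
#' @param k maximum number of mismatches (default 2).
#' @param revcomp also scan the reverse complement of each read
#'   (default \code{FALSE}: amplicon reads are orientation-normalized).
#' @return a list of \code{\linkS4class{HitSet}}, one per non-empty read.
#' @export
matchKMismatch <- function(reads, refs, idx, k = 2L, revcomp = FALSE) {
    stopifnot(k >= 0L)
    reads <- .asDNAStringSet(reads)
    refs <- .asDNAStringSet(refs)
    refIds <- resolveNodes(idx, names(refs))
    if (!all(idx@leaf[refIds]))
        stop("every reference must be named after a taxonomy leaf")
    empty <- Biostrings::width(reads) == 0L
    if (any(empty)) {
        warning(sum(empty), " empty read(s) skipped")
        reads <- reads[!empty]
    }
    ## one subject: references joined by N separators; matches are filtered
    ## to windows lying fully inside a single reference
    sep <- strrep("N", 10L)
    refChar <- as.character(refs)
    subject <- Biostrings::DNAString(paste(refChar, collapse = sep))
    w <- Biostrings::width(refs)
    refStart <- cumsum(c(1L, head(w, -1L) + 10L))
    refEnd <- refStart + w - 1L
    scan <- function(pat) {
        v <- Biostrings::matchPattern(pat, subject, max.mismatch = k,
                                      with.indels = FALSE, fixed = TRUE)
        st <- Biostrings::start(v); en <- Biostrings::end(v)
        ri <- findInterval(st, refStart)
        ri[ri >= 1L & en <= refEnd[pmax(ri, 1L)]]
    }
    out <- vector("list", length(reads))
    for (i in seq_along(reads)) {
        pat <- reads[[i]]
        ri <- scan(pat)
        if (revcomp)
            ri <- c(ri, scan(Biostrings::reverseComplement(pat)))
        out[[i]] <- new("HitSet", readId = names(reads)[i],
                        hits = sort(unique(refIds[ri])),
                        trueHit = NA_integer_)
    }
    out
}

#' Attach known true source leaves to hit sets
#'
#' @param hitsets a list of \code{\linkS4class{HitSet}}.
#' @param truth a data.frame with columns \code{read_id} and
#'   \code{true_hit} (leaf names), as written by the simulator.
#' @param idx a \code{\linkS4class{TaxonomyIndex}}.
#' @return the list with \code{trueHit} filled in where known.
#' @export
attachTruth <- function(hitsets, truth, idx) {
    ids <- vapply(hitsets, readId, character(1))
    pos <- match(ids, truth$read_id)
    lapply(seq_along(hitsets), function(i) {
        h <- hitsets[[i]]
        if (!is.na(pos[i]))
            h@trueHit <- resolveNodes(idx, truth$true_hit[pos[i]])
        h
    })
}
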