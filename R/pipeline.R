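## End-to-end pipeline: simulate -> match -> assign -> summarize ->
## validate, writing plain-text artifacts plus a manifest. All outputs are
## TSV (UTF-8, LF); reruns with the same configuration are byte-identical.

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, eol = "\n")
}

.writeFasta <- function(x, path) {
    Biostrings::writeXStringSet(x, path, width = 80L)
}

#' Write hit sets to the TSV format read by readHitsTsv
#'
#' @param hitsets a list of \code{\linkS4class{HitSet}}.
#' @param idx a \code{\linkS4class{TaxonomyIndex}}.
#' @param path output file.
#' @export
writeHitsTsv <- function(hitsets, idx, path) {
    lines <- vapply(hitsets, function(h) {
        th <- if (is.na(h@trueHit)) "" else idx@nodeName[h@trueHit]
        paste(h@readId, paste(idx@nodeName[h@hits], collapse = ","), th,
              sep = "\t")
    }, character(1))
    writeLines(lines, path)
}

#' Run the full simulation-to-validation pipeline
#'
#' Simulates a taxonomy and reads, matches the reads against the leaf
#' sequences with the naive k-mismatch matcher, assigns every read over
#' the q grid, and validates against the known source leaves. Writes, in
#' \code{outDir}: \code{taxonomy.nwk}, \code{lineage.tsv},
#' \code{refs.fasta}, \code{reads.fasta}, \code{truth.tsv},
#' \code{hits.tsv}, \code{assignments.tsv}, \code{rank_by_q.tsv},
#' \code{validation.tsv}, \code{best_q.tsv} and \code{manifest.json}
#' (inputs, parameters, seed, package version).
#'
#' @param outDir output directory (created if missing).
#' @param cfg a \code{\linkS4class{SimConfig}}.
#' @param k maximum mismatches for the matcher (default 2).
#' @param qGrid numeric q grid (default 0, 0.1, ..., 1).
#' @param window optional 0-based half-open region restriction for read
#'   sampling (see \code{\link{simulateRegionReads}}).
#' @param revcomp also match reverse complements (default \code{FALSE}).
#' @return invisibly, a list with the taxonomy, hit sets, the assignment
#'   sweep, the validation summary and the written file paths.
#' @export
runPipeline <- function(outDir, cfg = simConfig(), k = 2L,
                        qGrid = seq(0, 1, by = 0.1), window = NULL,
                        revcomp = FALSE) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulateTaxonomy(cfg)
    idx <- sim$taxonomy
    rd <- if (is.null(window)) simulateReads(cfg, sim$sequences)
          else simulateRegionReads(cfg, sim$sequences, window)
    hs <- matchKMismatch(rd$reads, sim$sequences, idx, k = k,
                         revcomp = revcomp)
    hs <- attachTruth(hs, rd$truth, idx)
    sweep <- sweepQ(idx, hs, qGrid)
    ranks <- rankDistribution(sweep, idx)
    val <- validateSweep(idx, hs, qGrid)
    best <- bestQTable(idx, hs, qGrid)

    paths <- file.path(outDir, c(
        taxonomy = "taxonomy.nwk", lineage = "lineage.tsv",
        refs = "refs.fasta", reads = "reads.fasta", truth = "truth.tsv",
        hits = "hits.tsv", assignments = "assignments.tsv",
        rank_by_q = "rank_by_q.tsv", validation = "validation.tsv",
        best_q = "best_q.tsv", manifest = "manifest.json"))
    names(paths) <- c("taxonomy", "lineage", "refs", "reads", "truth",
                      "hits", "assignments", "rank_by_q", "validation",
                      "best_q", "manifest")
    writeLines(toNewick(idx), paths["taxonomy"])
    writeLineageTable(idx, paths["lineage"])
    .writeFasta(sim$sequences, paths["refs"])
    .writeFasta(rd$reads, paths["reads"])
    .writeTsv(rd$truth, paths["truth"])
    writeHitsTsv(hs, idx, paths["hits"])
    .writeTsv(sweep, paths["assignments"])
    rankDf <- as.data.frame.matrix(unclass(ranks))
    rankDf <- cbind(rank = rownames(rankDf), rankDf)
    .writeTsv(rankDf, paths["rank_by_q"])
    .writeTsv(val, paths["validation"])
    .writeTsv(best, paths["best_q"])
    manifest <- list(
        parameters = list(
            seed = cfg@seed, n_leaves = cfg@nLeaves, ranks = cfg@ranks,
            branching = cfg@branching, seq_length = cfg@seqLength,
            per_level_substitution_rate = cfg@perLevelSubstitutionRate,
            read_length = cfg@readLength, n_reads = cfg@nReads,
            substitution_error_rate = cfg@substitutionErrorRate,
            homopolymer_indel_rate = cfg@homopolymerIndelRate,
            min_length_fraction = cfg@minLengthFraction,
            k = k, q_grid = qGrid,
            window = if (is.null(window)) NULL else as.integer(window),
            revcomp = revcomp),
        versions = list(
            taxq = as.character(utils::packageVersion("taxq")),
            R = paste(R.version$major, R.version$minor, sep = ".")),
        outputs = basename(unname(paths)))
    jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(list(taxonomy = idx, hitsets = hs, sweep = sweep,
                   ranks = ranks, validation = val, best_q = best,
                   paths = paths))
}
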