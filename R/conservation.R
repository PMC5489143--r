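## Genus-wide regulon conservation scanning and the reciprocal best-hit
## orthologue screen used to tell a regulator apart from its close
## paralogs (e.g. separating rccR from hexR homologs).

#' Scan many genomes for conserved binding sites upstream of their genes
#'
#' For each genome with an annotation, extracts the upstream region of
#' every gene and scans it with either an IUPAC consensus or a
#' [palindrome_spec()]. Genomes without an annotation are skipped with a
#' warning.
#'
#' @param genomes Named list of [genome_record()] objects.
#' @param annotations Named list of [gene_features()] data frames,
#'   matched to `genomes` by name.
#' @param consensus Either an IUPAC consensus string or a
#'   [palindrome_spec()].
#' @param max_mismatches Mismatch budget (for a `palindrome_spec` this
#'   overrides its own `max_mismatches` when not `NULL`).
#' @param upstream_length Upstream window length in bp.
#' @return Data frame of hits: `genome_id`, `gene_id`, `start`, `end`
#'   (coordinates within the upstream region), `strand`,
#'   `matched_sequence`, `mismatches`, `linker_length`; sorted by genome
#'   then gene. Per-genome hit counts are attached as attribute
#'   `"summary"`.
#' @export
regulon_scan <- function(genomes, annotations, consensus,
                         max_mismatches = 1, upstream_length = 300) {
  stopifnot(!is.null(names(genomes)))
  rows <- list()
  for (gid in names(genomes)) {
    ann <- annotations[[gid]]
    if (is.null(ann)) {
      warning("regulon_scan: genome '", gid, "' has no annotation; skipped")
      next
    }
    ups <- extract_upstream(genomes[[gid]], ann, length = upstream_length)
    for (i in seq_len(nrow(ups))) {
      if (nchar(ups$sequence[i]) == 0L) next
      hits <- if (inherits(consensus, "palindrome_spec")) {
        spec <- consensus
        if (!is.null(max_mismatches)) spec$max_mismatches <- max_mismatches
        find_pseudopalindromes(ups$sequence[i], spec,
                               replicon_id = ups$gene_id[i])
      } else {
        scan_iupac(ups$sequence[i], consensus,
                   max_mismatches = max_mismatches,
                   replicon_id = ups$gene_id[i])
      }
      if (nrow(hits)) {
        hits$genome_id <- gid
        hits$gene_id <- ups$gene_id[i]
        rows[[length(rows) + 1L]] <- hits[, c("genome_id", "gene_id",
                                              "start", "end", "strand",
                                              "matched_sequence",
                                              "mismatches",
                                              "linker_length")]
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(genome_id = character(), gene_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), matched_sequence = character(),
                      mismatches = integer(), linker_length = integer(),
                      stringsAsFactors = FALSE)
  out <- out[order(out$genome_id, out$gene_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  counts <- table(factor(out$genome_id, levels = names(genomes)))
  attr(out, "summary") <- data.frame(genome_id = names(counts),
                                     n_hits = as.integer(counts),
                                     stringsAsFactors = FALSE)
  out
}

## Best local-alignment hit of one query against a named set of subjects.
## Score ties are broken by subject id (lexicographic), which is logged.
.best_hit <- function(query, subjects, sub_matrix, gap_open, gap_ext) {
  scores <- vapply(names(subjects), function(sid)
    Biostrings::pairwiseAlignment(query, subjects[[sid]], type = "local",
                                  substitutionMatrix = sub_matrix,
                                  gapOpening = gap_open,
                                  gapExtension = gap_ext,
                                  scoreOnly = TRUE),
    0)
  top <- which(scores == max(scores))
  if (length(top) > 1L) {
    pick <- sort(names(scores)[top])[1]
    message("best-hit tie among {", paste(names(scores)[top],
                                          collapse = ", "),
            "}; picked '", pick, "' (lexicographic)")
    return(list(id = pick, score = max(scores)))
  }
  list(id = names(scores)[top], score = scores[top])
}

#' Reciprocal best-hit orthologue screen
#'
#' For each query in proteome A, finds the best-scoring subject in
#' proteome B by local alignment (BLOSUM62, affine gaps); the pair is
#' reported only if the subject's own best hit in A is the query
#' (reciprocity) and the aligned-query coverage fraction exceeds
#' `min_hcov`.
#'
#' @param proteome_a,proteome_b Named character vectors (or named
#'   `AAStringSet`s) of protein sequences.
#' @param query_ids Queries from `proteome_a` to screen (default: all).
#' @param min_hcov Minimum aligned-query-coverage fraction (aligned query
#'   residues / query length).
#' @param gap_open,gap_ext Affine gap penalties.
#' @return Data frame of reciprocal pairs: `query_id`, `subject_id`,
#'   `score_ab`, `score_ba`, `hcov`.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b, query_ids = NULL,
                                 min_hcov = 0.7, gap_open = 11,
                                 gap_ext = 1) {
  as_set <- function(x, label) {
    if (inherits(x, "AAStringSet")) x <- as.character(x)
    if (length(x) == 0L) stop("reciprocal_best_hits: empty proteome ",
                              label)
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
      stop("reciprocal_best_hits: proteome ", label, " must be named")
    Biostrings::AAStringSet(x)
  }
  A <- as_set(proteome_a, "A")
  B <- as_set(proteome_b, "B")
  if (is.null(query_ids)) query_ids <- names(A)
  stopifnot(all(query_ids %in% names(A)))
  e <- new.env()
  utils::data(list = "BLOSUM62", package = "Biostrings", envir = e)
  M <- get("BLOSUM62", envir = e)
  rows <- list()
  for (q in query_ids) {
    ab <- .best_hit(A[[q]], B, M, gap_open, gap_ext)
    ba <- .best_hit(B[[ab$id]], A, M, gap_open, gap_ext)
    if (!identical(ba$id, q)) next
    aln <- Biostrings::pairwiseAlignment(A[[q]], B[[ab$id]], type = "local",
                                         substitutionMatrix = M,
                                         gapOpening = gap_open,
                                         gapExtension = gap_ext)
    qaln <- Biostrings::pattern(aln)
    hcov <- (BiocGenerics::end(qaln) - BiocGenerics::start(qaln) + 1) /
      length(A[[q]])
    if (hcov <= min_hcov) next
    rows[[length(rows) + 1L]] <-
      data.frame(query_id = q, subject_id = ab$id,
                 score_ab = unname(ab$score), score_ba = unname(ba$score),
                 hcov = unname(hcov), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(query_id = character(), subject_id = character(),
                      score_ab = numeric(), score_ba = numeric(),
                      hcov = numeric(), stringsAsFactors = FALSE)
  out
}
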