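## I/O for the standard formats the pipeline touches, and the coordinate
## contract used everywhere else: internal coordinates are ALWAYS 0-based
## half-open; GFF3 (1-based inclusive) is converted at the boundary; BED and
## bedGraph are natively 0-based and pass through unchanged.

GENOME_ALPHABET <- c("A", "C", "G", "T", "N")

#' Genome record
#'
#' A single replicon: an identifier, an upper-case DNA sequence over
#' `A,C,G,T,N`, and a flag saying whether the replicon is circular (bacterial
#' chromosomes usually are; window arithmetic wraps around on circular
#' replicons).
#'
#' @param replicon_id Replicon identifier (scalar character).
#' @param sequence DNA sequence as a single string; case-normalised to upper.
#' @param circular Logical; is the replicon circular?
#' @return An object of class `genome_record` with fields `replicon_id`,
#'   `sequence` and `circular`.
#' @export
genome_record <- function(replicon_id, sequence, circular = FALSE) {
  stopifnot(is.character(replicon_id), length(replicon_id) == 1L,
            is.character(sequence), length(sequence) == 1L,
            is.logical(circular), length(circular) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L)
    stop("genome_record: empty sequence for replicon '", replicon_id, "'")
  bad <- setdiff(unique(strsplit(sequence, "", fixed = TRUE)[[1]]),
                 GENOME_ALPHABET)
  if (length(bad))
    stop("genome_record: illegal characters in sequence of '", replicon_id,
         "': ", paste(bad, collapse = ", "))
  structure(list(replicon_id = replicon_id, sequence = sequence,
                 circular = circular),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp (%s)\n", x$replicon_id,
              nchar(x$sequence), if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Gene feature table
#'
#' Builds the internal gene annotation table. Coordinates are 0-based
#' half-open on the forward strand regardless of gene orientation; `strand`
#' is `"+"` or `"-"`.
#'
#' @param gene_id,replicon_id Character vectors.
#' @param start,end Integer vectors, 0-based half-open, `start < end`.
#' @param strand Character vector over `{"+", "-"}`.
#' @return A `data.frame` with one row per gene.
#' @export
gene_features <- function(gene_id, replicon_id, start, end, strand) {
  df <- data.frame(gene_id = as.character(gene_id),
                   replicon_id = as.character(replicon_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start < 0L) || any(df$start >= df$end))
      stop("gene_features: require 0 <= start < end")
    if (!all(df$strand %in% c("+", "-")))
      stop("gene_features: strand must be '+' or '-'")
  }
  df
}

#' Per-base coverage track
#'
#' @param replicon_id Replicon identifier.
#' @param counts Numeric vector of non-negative per-base read counts, one
#'   entry per base of the replicon.
#' @param circular Logical; circular replicon?
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(replicon_id, counts, circular = FALSE) {
  stopifnot(is.numeric(counts))
  if (length(counts) == 0L) stop("coverage_track: empty counts")
  if (any(counts < 0)) stop("coverage_track: negative coverage values")
  structure(list(replicon_id = as.character(replicon_id),
                 counts = as.numeric(counts),
                 circular = isTRUE(circular)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s: %d bp, mean %.3f (%s)\n", x$replicon_id,
              length(x$counts), mean(x$counts),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a FASTA file of replicons
#'
#' @param path Path to a FASTA file.
#' @param circular Logical, recycled over records: circularity is not
#'   encoded in FASTA, so the caller states it.
#' @return A list of [genome_record()] objects, in file order.
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("read_genome_fasta: no such file: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e)
                    stop("read_genome_fasta: malformed FASTA in '", path,
                         "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("read_genome_fasta: no records in ", path)
  circular <- rep_len(circular, length(set))
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i)
    genome_record(ids[i], as.character(set[[i]]), circular[i]))
}

#' Write replicons to FASTA
#'
#' @param records A list of [genome_record()] objects (or a single one).
#' @param path Output path.
#' @export
write_genome_fasta <- function(records, path) {
  if (inherits(records, "genome_record")) records <- list(records)
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "sequence"))
  names(set) <- vapply(records, `[[`, "", "replicon_id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene features from GFF3
#'
#' Keeps `gene` and `CDS` features (configurable); converts the GFF3 1-based
#' inclusive coordinates to the internal 0-based half-open convention. The
#' gene identifier is taken from the first available of the `locus_tag`,
#' `ID` and `Name` attributes.
#'
#' @param path Path to a GFF3 file.
#' @param feature_types GFF3 `type` values to keep.
#' @return A [gene_features()] data frame.
#' @export
read_gff3 <- function(path, feature_types = c("gene", "CDS")) {
  if (!file.exists(path)) stop("read_gff3: no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop("read_gff3: malformed GFF3 in '", path, "': ",
                        conditionMessage(e)))
  gr <- gr[as.character(gr$type) %in% feature_types]
  if (length(gr) == 0L)
    return(gene_features(character(), character(), integer(), integer(),
                         character()))
  str <- as.character(BiocGenerics::strand(gr))
  if (any(!str %in% c("+", "-")))
    stop("read_gff3: unknown strand in ", path)
  meta <- S4Vectors::mcols(gr)
  pick <- function(col) if (col %in% names(meta)) as.character(meta[[col]])
          else rep(NA_character_, length(gr))
  id <- pick("locus_tag")
  for (alt in c("ID", "Name")) {
    miss <- is.na(id)
    if (any(miss)) id[miss] <- pick(alt)[miss]
  }
  if (anyNA(id)) stop("read_gff3: features without an identifier in ", path)
  gene_features(id, as.character(GenomicRanges::seqnames(gr)),
                BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr), str)
}

#' Write gene features to GFF3
#'
#' The inverse boundary conversion of [read_gff3()]: internal 0-based
#' half-open back to GFF3 1-based inclusive.
#'
#' @param genes A [gene_features()] data frame.
#' @param path Output path.
#' @param type GFF3 feature type to emit (default `"gene"`).
#' @export
write_gff3 <- function(genes, path, type = "gene") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  gr$type <- type
  gr$ID <- genes$gene_id
  gr$locus_tag <- genes$gene_id
  gr$source <- "ChIPregulon"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a bedGraph file into a dense coverage track
#'
#' bedGraph intervals are 0-based half-open; positions not covered by any
#' interval get coverage 0. Overlapping intervals with conflicting values
#' are a format error; an interval extending past the stated replicon
#' length is an error.
#'
#' @param path Path to a bedGraph file.
#' @param replicon_id Replicon to extract (default: the single replicon
#'   present; an error if the file has several and none is named).
#' @param length Replicon length in bp.
#' @param circular Circularity flag for the returned track.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, replicon_id = NULL, length, circular = FALSE) {
  if (!file.exists(path)) stop("read_bedgraph: no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e)
                   stop("read_bedgraph: malformed bedGraph in '", path,
                        "': ", conditionMessage(e)))
  chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (is.null(replicon_id)) {
    if (length(chroms) > 1L)
      stop("read_bedgraph: several replicons in ", path,
           "; name one via replicon_id")
    replicon_id <- chroms
  }
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == replicon_id]
  counts <- numeric(length)
  if (length(gr)) {
    if (any(BiocGenerics::end(gr) > length))
      stop("read_bedgraph: interval beyond replicon end (length ", length,
           ") in ", path)
    ir <- IRanges::IRanges(BiocGenerics::start(gr), BiocGenerics::end(gr))
    depth <- IRanges::coverage(ir, width = length)
    if (max(depth) > 1L) {
      ## overlaps are legal only when the values agree
      hov <- IRanges::findOverlaps(ir, ir)
      hov <- hov[S4Vectors::queryHits(hov) < S4Vectors::subjectHits(hov)]
      q <- S4Vectors::queryHits(hov); s <- S4Vectors::subjectHits(hov)
      if (any(gr$score[q] != gr$score[s]))
        stop("read_bedgraph: overlapping intervals with conflicting values",
             " in ", path)
      ## equal-value overlaps: assign interval by interval (rare)
      st <- BiocGenerics::start(gr) - 1L
      for (i in seq_along(st))
        counts[(st[i] + 1L):BiocGenerics::end(gr)[i]] <- gr$score[i]
    } else {
      counts <- as.numeric(IRanges::coverage(ir, width = length,
                                             weight = gr$score))
    }
  }
  coverage_track(replicon_id, counts, circular)
}

#' Write a coverage track as run-length-merged bedGraph
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  r <- rle(track$counts)
  en <- cumsum(r$lengths)
  st <- en - r$lengths          # 0-based starts
  keep <- r$values != 0
  df <- data.frame(chrom = track$replicon_id, start = st[keep],
                   end = en[keep], value = r$values[keep])
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(df))
    writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end,
                       format(df$value, trim = TRUE, scientific = FALSE)),
               con)
  invisible(path)
}

#' Write intervals as BED6
#'
#' Intervals come in internally 0-based half-open and go out unchanged
#' (BED is 0-based half-open). Scores are clamped to `[0, 1000]`.
#'
#' @param intervals Data frame with columns `replicon_id`, `start`, `end`,
#'   `name`, `score`, `strand` (strand may be `"."`).
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(intervals)) {
    score <- pmin(1000, pmax(0, as.numeric(intervals$score)))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                       intervals$replicon_id,
                       as.integer(intervals$start),
                       as.integer(intervals$end),
                       as.character(intervals$name),
                       format(score, trim = TRUE),
                       as.character(intervals$strand)),
               con)
  }
  invisible(path)
}

#' Read BED6 intervals
#'
#' @param path Path to a BED file.
#' @return Data frame with columns `replicon_id`, `start`, `end`, `name`,
#'   `score`, `strand` (0-based half-open).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("read_bed: no such file: ", path)
  if (file.size(path) == 0L)
    return(data.frame(replicon_id = character(), start = integer(),
                      end = integer(), name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:6] <- c("replicon_id", "start", "end", "name", "score",
                      "strand")
  df[1:6]
}

#' Write a result table as TSV
#'
#' All pipeline result tables share one format: UTF-8 TSV with a header
#' row and no quoting or row names.
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV result table
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}
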