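## Inverted-repeat ("pseudo-palindrome") binding-site model and
## mismatch-tolerant scanning. Sites are a conserved arm pair
## (TGTAGT / ACTACA by default) separated by a non-conserved linker whose
## length defines the site class: 3 nt -> 15 bp, 16 nt -> 28 bp,
## 17 nt -> 29 bp.

.BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

## IUPAC letter -> bitmask over {A,C,G,T}
.iupac_mask_table <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  vapply(map, function(s)
    sum(.BASE_BITS[strsplit(s, "", fixed = TRUE)[[1]]]), 0L)
})

## bitmask -> minimal IUPAC letter
.mask_to_iupac <- local({
  out <- character(15)
  for (code in names(.iupac_mask_table))
    out[.iupac_mask_table[[code]]] <- code
  out
})

.pattern_masks <- function(pattern) {
  ch <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), names(.iupac_mask_table))
  if (length(bad))
    stop("illegal IUPAC character(s): ", paste(bad, collapse = ", "))
  unname(.iupac_mask_table[ch])
}

## Subject sequence -> per-base bitmasks. N (and any other ambiguity code
## in the subject) is mapped to 0 so it always counts as a mismatch:
## conservative treatment of undetermined genome positions.
.subject_codes <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), names(.iupac_mask_table))
  if (length(bad))
    stop("illegal character(s) in sequence: ", paste(bad, collapse = ", "))
  code <- unname(.BASE_BITS[ch])
  code[is.na(code)] <- 0L
  code
}

## Mismatch count of `masks` against every window of `codes`.
## Returns integer vector of length length(codes) - length(masks) + 1.
.mismatch_profile <- function(codes, masks) {
  n <- length(codes); m <- length(masks)
  nw <- n - m + 1L
  if (nw < 1L) return(integer(0))
  mm <- integer(nw)
  for (j in seq_len(m))
    mm <- mm + (bitwAnd(codes[j:(j + nw - 1L)], masks[j]) == 0L)
  mm
}

#' Reverse complement with IUPAC-aware complementation
#'
#' @param seq DNA string over the IUPAC alphabet (may be empty).
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

.empty_hits <- function() {
  data.frame(replicon_id = character(), start = integer(), end = integer(),
             strand = character(), matched_sequence = character(),
             mismatches = integer(), linker_length = integer(),
             stringsAsFactors = FALSE)
}

.order_hits <- function(hits) {
  hits <- hits[order(hits$start, hits$linker_length,
                     match(hits$strand, c("+", "-"))), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan a sequence for an IUPAC consensus with mismatches
#'
#' Every window (on both strands unless disabled) whose number of
#' positions failing IUPAC containment is at most `max_mismatches` is
#' reported. Overlapping and nested hits are all reported; coordinates
#' are 0-based half-open on the forward strand, and `matched_sequence`
#' is given 5'->3' on the hit strand.
#'
#' @param seq A DNA string or a [genome_record()].
#' @param pattern IUPAC consensus string.
#' @param max_mismatches Maximum mismatching positions per window.
#' @param both_strands Scan the reverse strand too?
#' @param replicon_id Identifier used in the hit table when `seq` is a
#'   plain string.
#' @return Hit data frame: `replicon_id`, `start`, `end`, `strand`,
#'   `matched_sequence`, `mismatches`, `linker_length` (`NA` for plain
#'   consensus scans), sorted by start then strand (`+` first).
#' @export
scan_iupac <- function(seq, pattern, max_mismatches = 0,
                       both_strands = TRUE, replicon_id = "seq") {
  if (inherits(seq, "genome_record")) {
    replicon_id <- seq$replicon_id
    seq <- seq$sequence
  }
  seq <- toupper(seq)
  m <- nchar(pattern)
  if (m < 1L) stop("scan_iupac: empty pattern")
  if (m > nchar(seq)) return(.empty_hits())
  codes <- .subject_codes(seq)
  hit_rows <- function(mm, strand) {
    idx <- which(mm <= max_mismatches)
    if (!length(idx)) return(NULL)
    win <- substring(seq, idx, idx + m - 1L)
    if (strand == "-")
      win <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(win)))
    data.frame(replicon_id = replicon_id, start = idx - 1L,
               end = idx - 1L + m, strand = strand,
               matched_sequence = win, mismatches = mm[idx],
               linker_length = NA_integer_, stringsAsFactors = FALSE)
  }
  out <- list(hit_rows(.mismatch_profile(codes, .pattern_masks(pattern)),
                       "+"))
  if (both_strands)
    out <- c(out, list(hit_rows(
      .mismatch_profile(codes, .pattern_masks(revcomp(pattern))), "-")))
  hits <- do.call(rbind, out)
  if (is.null(hits)) return(.empty_hits())
  .order_hits(hits)
}

#' Pseudo-palindrome specification
#'
#' An inverted-repeat site model: a left arm, a right arm (defaulting to
#' the reverse complement of the left), the set of allowed linker lengths
#' and the mismatch budget. With the defaults the three site classes are
#' 15, 28 and 29 bp long.
#'
#' @param left_arm,right_arm Arm sequences (IUPAC).
#' @param linker_lengths Integer vector of allowed linker lengths (nt).
#' @param max_mismatches Maximum mismatches, pooled over both arms (the
#'   linker is unconstrained unless `arm_only = FALSE` in
#'   [find_pseudopalindromes()]).
#' @return A list of class `palindrome_spec`.
#' @export
palindrome_spec <- function(left_arm = "TGTAGT",
                            right_arm = revcomp(left_arm),
                            linker_lengths = c(3L, 16L, 17L),
                            max_mismatches = 0) {
  stopifnot(nchar(left_arm) > 0, nchar(right_arm) > 0,
            all(linker_lengths >= 0))
  structure(list(left_arm = toupper(left_arm),
                 right_arm = toupper(right_arm),
                 linker_lengths = as.integer(sort(unique(linker_lengths))),
                 max_mismatches = max_mismatches),
            class = "palindrome_spec")
}

#' Find inverted-repeat sites with a variable linker
#'
#' For each allowed linker length `L`, reports every window where the
#' mismatches of the left arm (at offset 0) plus those of the right arm
#' (at offset `|left| + L`) stay within the budget; linker content is
#' unconstrained. Both strands are scanned, but a hit whose reverse
#' complement maps onto itself (always the case when the right arm is the
#' exact reverse complement of the left) is reported once, on `+`.
#'
#' @param seq A DNA string or [genome_record()].
#' @param spec A [palindrome_spec()].
#' @param arm_only Count mismatches in the arms only (default); set
#'   `FALSE` to score the whole site as an IUPAC consensus with a fully
#'   degenerate (`N`) linker, which additionally penalises `N` bases in
#'   the linker.
#' @param replicon_id Identifier used when `seq` is a plain string.
#' @return Hit data frame as for [scan_iupac()], with `linker_length`
#'   filled in.
#' @export
find_pseudopalindromes <- function(seq, spec = palindrome_spec(),
                                   arm_only = TRUE, replicon_id = "seq") {
  stopifnot(inherits(spec, "palindrome_spec"))
  if (inherits(seq, "genome_record")) {
    replicon_id <- seq$replicon_id
    seq <- seq$sequence
  }
  seq <- toupper(seq)
  codes <- .subject_codes(seq)
  nl <- nchar(spec$left_arm); nr <- nchar(spec$right_arm)
  scan_arms <- function(left, right, L, strand) {
    site_len <- nl + L + nr
    if (!arm_only) {
      pat <- paste0(left, strrep("N", L), right)
      h <- scan_iupac(seq, pat, spec$max_mismatches, both_strands = FALSE,
                      replicon_id = replicon_id)
      if (nrow(h)) {
        h$linker_length <- L
        h$strand <- strand
        if (strand == "-")
          h$matched_sequence <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(h$matched_sequence)))
      }
      return(h)
    }
    mmL <- .mismatch_profile(codes, .pattern_masks(left))
    mmR <- .mismatch_profile(codes, .pattern_masks(right))
    nw <- nchar(seq) - site_len + 1L
    if (nw < 1L) return(.empty_hits())
    tot <- mmL[seq_len(nw)] + mmR[seq_len(nw) + nl + L]
    idx <- which(tot <= spec$max_mismatches)
    if (!length(idx)) return(.empty_hits())
    win <- substring(seq, idx, idx + site_len - 1L)
    if (strand == "-")
      win <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(win)))
    data.frame(replicon_id = replicon_id, start = idx - 1L,
               end = idx - 1L + site_len, strand = strand,
               matched_sequence = win, mismatches = tot[idx],
               linker_length = L, stringsAsFactors = FALSE)
  }
  ## the site model seen from the minus strand
  left_rc <- revcomp(spec$right_arm)
  right_rc <- revcomp(spec$left_arm)
  self_symmetric <- identical(left_rc, spec$left_arm) &&
    identical(right_rc, spec$right_arm)
  out <- list()
  for (L in spec$linker_lengths) {
    plus <- scan_arms(spec$left_arm, spec$right_arm, L, "+")
    out <- c(out, list(plus))
    if (!self_symmetric) {
      minus <- scan_arms(left_rc, right_rc, L, "-")
      if (nrow(minus) && nrow(plus)) {
        dup <- paste(minus$start, minus$end) %in%
          paste(plus$start, plus$end)
        minus <- minus[!dup, , drop = FALSE]
      }
      out <- c(out, list(minus))
    }
  }
  hits <- do.call(rbind, out)
  if (is.null(hits) || nrow(hits) == 0L) return(.empty_hits())
  .order_hits(hits)
}

#' Build a position-frequency matrix and minimal IUPAC consensus
#'
#' @param sites Character vector of aligned, equal-length DNA strings
#'   (at least one).
#' @return A list with `pfm` (base-count matrix, rows A/C/G/T/N, one
#'   column per position) and `consensus` (the minimal IUPAC string
#'   covering all observed bases at each position).
#' @export
build_consensus <- function(sites) {
  stopifnot(length(sites) >= 1)
  sites <- toupper(sites)
  lens <- nchar(sites)
  if (length(unique(lens)) != 1L)
    stop("build_consensus: sites have ragged lengths: ",
         paste(unique(lens), collapse = ", "))
  L <- lens[1]
  chars <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  bad <- setdiff(unique(as.vector(chars)), names(.iupac_mask_table))
  if (length(bad))
    stop("build_consensus: illegal character(s): ",
         paste(bad, collapse = ", "))
  pfm <- vapply(seq_len(L), function(j)
    c(A = sum(chars[, j] == "A"), C = sum(chars[, j] == "C"),
      G = sum(chars[, j] == "G"), T = sum(chars[, j] == "T"),
      N = sum(!chars[, j] %in% c("A", "C", "G", "T"))),
    numeric(5))
  consensus <- vapply(seq_len(L), function(j) {
    mask <- Reduce(bitwOr, .iupac_mask_table[chars[, j]])
    .mask_to_iupac[mask]
  }, "")
  list(pfm = pfm, consensus = paste(consensus, collapse = ""))
}

#' Extract strand-aware upstream regions of genes
#'
#' Returns the `length`-bp window ending at each gene's own-strand start
#' (optionally extended `allow_into_cds` bp into the gene body), as a
#' 5'->3' sequence relative to the gene. Regions are truncated at the
#' ends of linear replicons and wrap around on circular ones.
#'
#' @param genome A [genome_record()].
#' @param genes A [gene_features()] data frame.
#' @param length Upstream window length in bp.
#' @param allow_into_cds Extension into the gene body in bp.
#' @return Data frame: `gene_id`, `sequence`, `start`, `end` (0-based
#'   half-open, forward-strand coordinates), `strand`.
#' @export
extract_upstream <- function(genome, genes, length = 300,
                             allow_into_cds = 0) {
  stopifnot(inherits(genome, "genome_record"))
  L <- nchar(genome$sequence)
  grab <- function(st, en) {          # 0-based half-open, may be out of range
    if (st >= 0L && en <= L)
      return(if (st >= en) "" else substr(genome$sequence, st + 1L, en))
    if (!genome$circular) {
      st <- max(0L, st); en <- min(L, en)
      return(if (st >= en) "" else substr(genome$sequence, st + 1L, en))
    }
    width <- en - st
    if (width <= 0L) return("")
    pos <- ((st %% L) + L) %% L
    pieces <- character(0)
    while (width > 0L) {
      take <- min(width, L - pos)
      pieces <- c(pieces, substr(genome$sequence, pos + 1L, pos + take))
      pos <- (pos + take) %% L
      width <- width - take
    }
    paste(pieces, collapse = "")
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (g$strand == "+") {
      st <- g$start - as.integer(length); en <- g$start + as.integer(allow_into_cds)
      s <- grab(st, en)
    } else {
      st <- g$end - as.integer(allow_into_cds); en <- g$end + as.integer(length)
      s <- grab(st, en)
      if (nchar(s)) s <- revcomp(s)
    }
    if (!genome$circular) { st <- max(0L, st); en <- min(L, en) }
    data.frame(gene_id = g$gene_id, sequence = s, start = st, end = en,
               strand = g$strand, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), sequence = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  out
}

#' Keep the best hit per locus
#'
#' Optional post-filter for overlapping/nested hits: among hits that
#' mutually overlap, keeps the one with the fewest mismatches, breaking
#' ties by leftmost start and then `+` strand.
#'
#' @param hits Hit data frame from [scan_iupac()] or
#'   [find_pseudopalindromes()].
#' @return Filtered hit data frame.
#' @export
dedupe_hits <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  hits <- hits[order(hits$mismatches, hits$start,
                     match(hits$strand, c("+", "-"))), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(hits)) > i)
    if (!length(later)) next
    ov <- hits$start[later] < hits$end[i] & hits$end[later] > hits$start[i]
    keep[later[ov]] <- FALSE
  }
  .order_hits(hits[keep, , drop = FALSE])
}
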