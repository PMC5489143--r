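## Independent reference implementations used as oracles. These are kept
## deliberately naive and share no code with the package internals.

## IUPAC letter -> set of plain bases it covers
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T"))

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M",
                V = "B", H = "D", D = "H", B = "V", N = "N")

naive_revcomp <- function(s) {
  if (nchar(s) == 0) return("")
  ch <- rev(strsplit(toupper(s), "")[[1]])
  paste(COMPLEMENT[ch], collapse = "")
}

## Position-by-position mismatch count; subject N (or any ambiguity code)
## always counts as a mismatch.
naive_mismatches <- function(window, pattern) {
  w <- strsplit(window, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  sum(vapply(seq_along(p), function(j) {
    if (!w[j] %in% c("A", "C", "G", "T")) return(TRUE)
    !w[j] %in% IUPAC_SETS[[p[j]]]
  }, TRUE))
}

## Naive scanner, both strands; coordinates 0-based half-open on the
## forward sequence; matched sequence 5'->3' on the hit strand.
naive_scan <- function(seq, pattern, max_mm, both_strands = TRUE) {
  seq <- toupper(seq); pattern <- toupper(pattern)
  m <- nchar(pattern); n <- nchar(seq)
  rows <- list()
  pats <- list("+" = pattern)
  if (both_strands) pats[["-"]] <- naive_revcomp(pattern)
  for (strand in names(pats)) {
    for (i in seq_len(max(0, n - m + 1))) {
      win <- substr(seq, i, i + m - 1)
      mm <- naive_mismatches(win, pats[[strand]])
      if (mm <= max_mm)
        rows[[length(rows) + 1]] <- data.frame(
          start = i - 1L, end = i - 1L + m, strand = strand,
          matched_sequence = if (strand == "+") win else naive_revcomp(win),
          mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(),
                      strand = character(), matched_sequence = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
}

## Reference BH step-up: q_(i) = min_{j >= i} p_(j) * n / j, capped at 1,
## returned in input order.
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, cummin((p[o] * n / seq_len(n))[n:1])[n:1])
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

## Small simulated track + config shared by several peak-caller tests
small_sim <- function(seed, genome_length = 3e5, n_genes = 12,
                      targets = c("tA", "tB", "tC")) {
  plan <- data.frame(gene_id = targets, site_class = "28bp",
                     arm_mismatches = 0L, stringsAsFactors = FALSE)
  cfg <- chip_sim_config(genome_length = genome_length, n_genes = n_genes,
                         seed = seed)
  generate_dataset(cfg, site_plan = plan,
                   target_slots = round(seq(2, n_genes - 1,
                                            length.out = length(targets))))
}
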