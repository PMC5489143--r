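test_that("reverse complement handles plain and IUPAC alphabets", {
  expect_equal(revcomp("TGTAGT"), "ACTACA")
  expect_equal(revcomp("TTGT"), "ACAA")
  expect_equal(revcomp(""), "")
  expect_equal(revcomp("ACGTN"), "NACGT")
  expect_equal(revcomp("WSRY"), "RYSW")
  expect_error(revcomp("ACGU"), ".")
})

test_that("revcomp is an involution", {
  set.seed(5)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N", "W", "S", "R", "Y"),
                      sample(1:30, 1), replace = TRUE), collapse = "")
    expect_equal(revcomp(revcomp(s)), s)
  }
})

test_that("scanning a sequence against itself hits at zero", {
  s <- "ACCGTTGAC"  # not self-reverse-complementary
  h <- scan_iupac(s, s, max_mismatches = 0)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 0)
  expect_equal(h$strand, "+")
  expect_equal(h$mismatches, 0)
})

test_that("the degenerate-linker consensus tolerates the printed mismatch", {
  ## first aceE 15-mer ends in T where the consensus has A
  h <- scan_iupac("TGTAGTTTTACTACT", "TGTAGTNNNACTACA",
                  max_mismatches = 1, both_strands = FALSE)
  expect_equal(nrow(h), 1)
  expect_equal(h$mismatches, 1)
  expect_equal(h$matched_sequence, "TGTAGTTTTACTACT")
  ## and is rejected with no mismatch budget
  expect_equal(nrow(scan_iupac("TGTAGTTTTACTACT", "TGTAGTNNNACTACA",
                               max_mismatches = 0, both_strands = FALSE)),
               0)
})

test_that("subject N always counts as a mismatch", {
  expect_equal(nrow(scan_iupac("ACNT", "ACNT", 0, both_strands = FALSE)),
               0)
  h <- scan_iupac("ACNT", "ACNT", 1, both_strands = FALSE)
  expect_equal(h$mismatches, 1)
})

test_that("the fast scanner equals the naive oracle on random cases", {
  set.seed(77)
  pat_alpha <- c("A", "C", "G", "T", "N", "W", "S", "R", "Y", "K", "M")
  for (i in 1:500) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), sample(20:60, 1),
                        replace = TRUE, prob = c(rep(0.24, 4), 0.04)),
                 collapse = "")
    pat <- paste(sample(pat_alpha, sample(4:8, 1), replace = TRUE),
                 collapse = "")
    mm <- sample(0:2, 1)
    got <- scan_iupac(seq, pat, mm)
    want <- naive_scan(seq, pat, mm)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      rownames(want) <- NULL
      expect_equal(got[c("start", "end", "strand", "matched_sequence",
                         "mismatches")], want,
                   ignore_attr = TRUE)
    }
  }
})

test_that("hit sets are strand-symmetric under sequence reversal", {
  set.seed(13)
  for (i in 1:20) {
    s <- random_dna(60)
    p <- "TGTAGT"
    fwd <- scan_iupac(s, p, 1)
    rev <- scan_iupac(revcomp(s), p, 1)
    ## reflect: a hit at [st,en) on seq maps to [L-en, L-st) on revcomp(seq)
    expect_equal(sort(60 - fwd$end), sort(rev$start))
    expect_equal(sum(fwd$strand == "+"), sum(rev$strand == "-"))
  }
})

test_that("pseudo-palindrome hits report class lengths 15/28/29", {
  spec <- palindrome_spec()
  for (L in c(3, 16, 17)) {
    set.seed(L)
    s <- paste0(random_dna(30), "TGTAGT", random_dna(L), "ACTACA",
                random_dna(30))
    h <- find_pseudopalindromes(s, spec)
    h <- h[h$mismatches == 0, ]
    expect_equal(nrow(h), 1)
    expect_equal(h$end - h$start, L + 12)
    expect_equal(h$linker_length, L)
    expect_equal(h$strand, "+")
    expect_equal(h$start, 30)
  }
  expect_equal(nrow(find_pseudopalindromes(strrep("A", 100), spec)), 0)
})

test_that("arm-only scanning nests the whole-site IUPAC scan", {
  set.seed(19)
  spec <- palindrome_spec(linker_lengths = c(3, 16),
                          max_mismatches = 1)
  for (i in 1:15) {
    s <- paste0(random_dna(20), "TGTAGT", random_dna(16), "ACTACA",
                random_dna(20))
    arm <- find_pseudopalindromes(s, spec, arm_only = TRUE)
    whole <- find_pseudopalindromes(s, spec, arm_only = FALSE)
    key <- function(h) paste(h$start, h$end, h$strand)
    expect_true(all(key(whole) %in% key(arm)))
    ## ACGT-only sequences: the two scans agree exactly
    expect_setequal(key(whole), key(arm))
    ## and the whole-site + strand scan equals scan_iupac on the pattern
    for (L in spec$linker_lengths) {
      si <- scan_iupac(s, paste0("TGTAGT", strrep("N", L), "ACTACA"),
                       max_mismatches = 1, both_strands = FALSE)
      expect_setequal(paste(si$start, si$end),
                      with(whole[whole$linker_length == L, ],
                           paste(start, end)))
    }
  }
})

test_that("hit counts grow with the mismatch budget", {
  set.seed(23)
  s <- random_dna(3000)
  spec0 <- palindrome_spec(max_mismatches = 0)
  counts <- vapply(0:3, function(m) {
    sp <- spec0; sp$max_mismatches <- m
    nrow(find_pseudopalindromes(s, sp))
  }, 0L)
  expect_true(all(diff(counts) >= 0))
  iup <- vapply(0:3, function(m)
    nrow(scan_iupac(s, "TGTAGTNNNACTACA", m)), 0L)
  expect_true(all(diff(iup) >= 0))
})

test_that("consensus construction yields minimal IUPAC codes", {
  cons <- build_consensus(aceE_sites())
  expect_equal(cons$consensus, "TGTAGTWWWACTACW")
  expect_equal(dim(cons$pfm), c(5, 15))
  expect_equal(unname(cons$pfm["A", 7]), 1)  # T/A split at linker pos 1
  expect_equal(build_consensus("ACGT")$consensus, "ACGT")
  expect_equal(build_consensus(c("A", "C", "G", "T"))$consensus, "N")
  expect_error(build_consensus(c("ACG", "AC")), "ragged")
})

test_that("upstream extraction is strand-aware and boundary-safe", {
  seq <- random_dna(3000)
  g <- genome_record("c", seq, circular = FALSE)
  genes <- gene_features(c("plus", "minus", "edge"), "c",
                         c(1000L, 1000L, 0L), c(2000L, 2000L, 100L),
                         c("+", "-", "+"))
  up <- extract_upstream(g, genes, length = 300)
  expect_equal(up$start[1], 700); expect_equal(up$end[1], 1000)
  expect_equal(up$sequence[1], substr(seq, 701, 1000))
  expect_equal(up$start[2], 2000); expect_equal(up$end[2], 2300)
  expect_equal(up$sequence[2], revcomp(substr(seq, 2001, 2300)))
  expect_equal(up$sequence[3], "")  # gene at position 0, linear: truncated
  ## circular genome wraps across the origin
  gc <- genome_record("c", seq, circular = TRUE)
  upc <- extract_upstream(gc, genes[3, ], length = 300)
  expect_equal(nchar(upc$sequence), 300)
  expect_equal(upc$sequence, substr(seq, 2701, 3000))
})

test_that("dedupe keeps the best hit per overlapping locus", {
  s <- paste0(random_dna(10), "TGTAGTAAAACTACA", random_dna(10))
  h <- scan_iupac(s, "TGTAGTNNNACTACA", 2)
  expect_true(nrow(h) >= 2)  # palindromic: both strands reported
  d <- dedupe_hits(h)
  expect_equal(nrow(d), 1)
  expect_equal(d$strand, "+")
  expect_equal(d$mismatches, min(h$mismatches))
})
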