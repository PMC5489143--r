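#!/usr/bin/env Rscript

## Stage 3: binding-site discovery and conservation scanning.
##
## Scans the called peak regions for the inverted-repeat site model
## (TGTAGT / ACTACA arms, linkers of 3/16/17 nt giving the 15/28/29 bp
## site classes, up to one arm mismatch), builds the position-frequency
## matrix and minimal IUPAC consensus from the exact hits, and then runs
## the upstream-region conservation scan over the genome -- the same
## machinery that scales to a genus-wide genome panel.

suppressMessages(library(ChIPregulon))

src <- "results/synthetic"
if (!file.exists("results/peaks.tsv"))
  stop("run analysis/02_call_peaks.R first")

genome <- read_genome_fasta(file.path(src, "genome.fasta"),
                            circular = TRUE)[[1]]
genes <- read_gff3(file.path(src, "genes.gff3"))
peaks <- read_tsv("results/peaks.tsv")

spec <- palindrome_spec(max_mismatches = 1)

## per-peak scans
hits <- do.call(rbind, lapply(seq_len(nrow(peaks)), function(i) {
  region <- substr(genome$sequence, peaks$start[i] + 1, peaks$end[i])
  h <- find_pseudopalindromes(region, spec, replicon_id = "synthetic_1")
  if (nrow(h)) {
    h$start <- h$start + peaks$start[i]
    h$end <- h$end + peaks$start[i]
    h$peak_target <- peaks$candidate_targets[i]
  }
  h
}))
write_tsv(hits, "results/peak_motif_hits.tsv")
cat("Inverted-repeat hits in peak regions:\n")
print(hits[, c("start", "end", "linker_length", "mismatches",
               "peak_target")])

## consensus from the exact 28 bp class hits
exact28 <- hits[hits$mismatches == 0 & hits$linker_length == 16, ]
cons <- build_consensus(exact28$matched_sequence)
cat("\n28 bp site consensus from", nrow(exact28), "exact hits:",
    cons$consensus, "\n")
writeLines(cons$consensus, "results/consensus_28bp.txt")

## upstream conservation scan (single-genome form of the genus scan)
reg <- regulon_scan(list(synthetic = genome), list(synthetic = genes),
                    consensus = spec, max_mismatches = 1,
                    upstream_length = 300)
write_tsv(reg, "results/regulon_hits.tsv")
cat("\nUpstream-scan hits by gene (<= 1 arm mismatch, 300 bp windows):\n")
print(table(reg$gene_id))
cat("\nSite-class lengths observed:",
    paste(sort(unique(reg$end - reg$start)), collapse = "/"), "bp\n")
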