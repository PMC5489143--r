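#!/usr/bin/env Rscript

## Stage 2: peak calling on the simulated ChIP experiment.
##
## Reads the stage-1 dataset back through the on-disk formats (FASTA,
## GFF3, bedGraph) to exercise the full I/O path, then runs the windowed
## enrichment caller at its defaults: 51-nt window stepping 25 nt over a
## 4001-nt background, ratio >= 1.5, NB-null p-values, BH alpha 0.05,
## two consecutive significant windows minimum, and a 2-fold screen
## against the control track at each summit.

suppressMessages(library(ChIPregulon))

src <- "results/synthetic"
if (!file.exists(file.path(src, "genome.fasta")))
  stop("run analysis/01_simulate_dataset.R first")

genome <- read_genome_fasta(file.path(src, "genome.fasta"),
                            circular = TRUE)[[1]]
genes <- read_gff3(file.path(src, "genes.gff3"))
L <- nchar(genome$sequence)
chip <- read_bedgraph(file.path(src, "chip.bedgraph"), length = L,
                      circular = TRUE)
control <- read_bedgraph(file.path(src, "control.bedgraph"), length = L,
                         circular = TRUE)
truth <- read_tsv(file.path(src, "truth_sites.tsv"))

cfg <- peak_caller_config()
res <- call_peak_set(chip, control, genes, cfg)
peaks <- res$peaks

write_tsv(res$enrichment[!is.na(res$enrichment$padj), ],
          "results/enrichment_retained.tsv")
write_tsv(peaks, "results/peaks.tsv")
write_bed(data.frame(replicon_id = peaks$replicon_id, start = peaks$start,
                     end = peaks$end,
                     name = sprintf("peak_%02d", seq_len(nrow(peaks))),
                     score = pmin(1000, peaks$max_ratio * 100),
                     strand = "."),
          "results/peaks.bed")

cat("Called", nrow(peaks), "peaks (", sum(peaks$intergenic),
    "intergenic ) from",
    sum(!is.na(res$enrichment$padj)), "retained windows\n\n")
print(peaks[, c("start", "end", "summit", "max_ratio", "min_padj",
                "fold_vs_control", "intergenic", "candidate_targets")])

recovered <- vapply(seq_len(nrow(truth)), function(i)
  any(peaks$start < truth$end[i] & peaks$end > truth$start[i]), TRUE)
cat("\nPlanted sites recovered:", sum(recovered), "/", nrow(truth), "\n")
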