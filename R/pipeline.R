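## The demonstration pipeline: one call that exercises every stage on
## synthetic data with known ground truth, writing its tables and a
## provenance file to an output directory. Deterministic under
## (config, seed): running it twice with the same seed produces
## byte-identical result tables.

#' Run the full synthetic demonstration pipeline
#'
#' Simulates a genome with planted binding sites and ChIP/control
#' coverage, calls, screens and annotates peaks, scans the peak regions
#' for pseudo-palindromic sites, builds the site consensus from the
#' recovered sequences, and scans every gene's upstream region with it
#' (the single-genome form of the conservation scan). All tables go to
#' `out_dir` as TSV/BED alongside the synthetic dataset itself and a
#' `provenance.txt` with every parameter and the seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving every random draw.
#' @param sim_config A [chip_sim_config()]; its seed is overridden by
#'   `seed`.
#' @param peak_config A [peak_caller_config()].
#' @param site_plan Site plan for [plant_sites()].
#' @param pal_spec A [palindrome_spec()] used for scanning peak regions
#'   and upstream regions.
#' @param scan_mismatches Mismatch budget of the final upstream scan.
#' @param upstream_length Upstream window of the final scan, bp.
#' @return Invisibly, a list with the dataset, peak set, per-peak motif
#'   hits, consensus, and regulon hit table.
#' @export
run_demo <- function(out_dir, seed,
                     sim_config = chip_sim_config(seed = seed),
                     peak_config = peak_caller_config(),
                     site_plan = default_site_plan(),
                     pal_spec = palindrome_spec(max_mismatches = 1),
                     scan_mismatches = 1, upstream_length = 300) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_config$seed <- as.integer(seed)

  dataset <- generate_dataset(sim_config, site_plan = site_plan)
  write_synthetic_dataset(dataset, file.path(out_dir, "synthetic"))

  res <- call_peak_set(dataset$chip, dataset$control, dataset$genes,
                       peak_config)
  peaks <- res$peaks
  write_tsv(res$enrichment[!is.na(res$enrichment$padj), ],
            file.path(out_dir, "enrichment_retained.tsv"))
  write_tsv(peaks, file.path(out_dir, "peaks.tsv"))
  if (nrow(peaks))
    write_bed(data.frame(replicon_id = peaks$replicon_id,
                         start = peaks$start, end = peaks$end,
                         name = sprintf("peak_%02d", seq_len(nrow(peaks))),
                         score = pmin(1000, peaks$max_ratio * 100),
                         strand = "."),
              file.path(out_dir, "peaks.bed"))

  ## scan each peak region for the inverted-repeat site model
  hits <- do.call(rbind, lapply(seq_len(nrow(peaks)), function(i) {
    st <- max(0L, peaks$start[i]); en <- min(nchar(dataset$genome$sequence),
                                             peaks$end[i])
    region <- substr(dataset$genome$sequence, st + 1L, en)
    h <- find_pseudopalindromes(region, pal_spec,
                                replicon_id = dataset$genome$replicon_id)
    if (nrow(h)) {
      h$start <- h$start + st
      h$end <- h$end + st
      h$peak <- i
    }
    h
  }))
  if (is.null(hits)) hits <- .empty_hits()
  write_tsv(hits, file.path(out_dir, "peak_motif_hits.tsv"))

  ## consensus from the exact (0-mismatch) hits of the dominant class
  consensus <- NULL
  exact <- hits[hits$mismatches == 0, , drop = FALSE]
  if (nrow(exact)) {
    main_class <- as.integer(names(sort(table(exact$linker_length),
                                        decreasing = TRUE))[1])
    consensus <- build_consensus(
      exact$matched_sequence[exact$linker_length == main_class])
    writeLines(consensus$consensus, file.path(out_dir, "consensus.txt"))
  }

  ## genus-scan machinery on the one synthetic genome
  regulon <- regulon_scan(
    stats::setNames(list(dataset$genome), "synthetic"),
    stats::setNames(list(dataset$genes), "synthetic"),
    consensus = pal_spec, max_mismatches = scan_mismatches,
    upstream_length = upstream_length)
  write_tsv(regulon, file.path(out_dir, "regulon_hits.tsv"))

  prov <- c(
    paste0("seed = ", seed),
    paste0("sim.", names(sim_config), " = ",
           vapply(sim_config, function(v) format(v, scientific = FALSE),
                  "")),
    paste0("peaks.", names(peak_config), " = ",
           vapply(peak_config, function(v) format(v, scientific = FALSE),
                  "")),
    paste0("pal.left_arm = ", pal_spec$left_arm),
    paste0("pal.right_arm = ", pal_spec$right_arm),
    paste0("pal.linker_lengths = ",
           paste(pal_spec$linker_lengths, collapse = ",")),
    paste0("pal.max_mismatches = ", pal_spec$max_mismatches),
    paste0("scan.mismatches = ", scan_mismatches),
    paste0("scan.upstream_length = ", upstream_length))
  writeLines(prov, file.path(out_dir, "provenance.txt"))

  invisible(list(dataset = dataset, peaks = peaks, enrichment = res$enrichment,
                 motif_hits = hits, consensus = consensus,
                 regulon = regulon))
}
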