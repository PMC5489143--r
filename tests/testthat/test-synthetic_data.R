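test_that("genome generation is deterministic under the seed", {
  cfg <- chip_sim_config(genome_length = 5e4, n_genes = 4, seed = 7)
  a <- make_genome(cfg)
  b <- make_genome(cfg)
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$genes, b$genes)
  c2 <- make_genome(chip_sim_config(genome_length = 5e4, n_genes = 4,
                                    seed = 8))
  expect_false(identical(a$genome$sequence, c2$genome$sequence))
})

test_that("gene packing respects spacers and zero-gene genomes work", {
  cfg <- chip_sim_config(genome_length = 5e4, n_genes = 0, seed = 1)
  g <- make_genome(cfg)
  expect_equal(nrow(g$genes), 0)
  cfg <- chip_sim_config(genome_length = 2e5, n_genes = 10, seed = 1)
  g <- make_genome(cfg)
  expect_equal(nrow(g$genes), 10)
  expect_true(all(diff(g$genes$start) > 0))
  gaps <- g$genes$start[-1] - g$genes$end[-nrow(g$genes)]
  expect_true(all(gaps >= 400))
  expect_error(make_genome(chip_sim_config(genome_length = 2e4,
                                           n_genes = 10, seed = 1)),
               "cannot pack")
})

test_that("background base composition is near-uniform at 1 Mb", {
  cfg <- chip_sim_config(seed = 3, n_genes = 0)
  g <- make_genome(cfg)
  gc <- sum(strsplit(g$genome$sequence, "")[[1]] %in% c("G", "C")) / 1e6
  expect_true(abs(gc - 0.5) < 0.01)
})

test_that("planted sites have the exact class architecture", {
  cfg <- chip_sim_config(genome_length = 2e5, n_genes = 8, seed = 11)
  gen <- make_genome(cfg, gene_ids = c("g1", "g2", sprintf("g%d", 3:8)))
  plan <- data.frame(gene_id = "g1", site_class = "28bp",
                     arm_mismatches = 0L)
  pl <- plant_sites(gen$genome, gen$genes, plan, seed = 11)
  expect_equal(nrow(pl$truth), 1)
  expect_equal(pl$truth$end - pl$truth$start, 28)
  site <- pl$truth$sequence
  expect_equal(substr(site, 1, 6), "TGTAGT")
  expect_equal(substr(site, 23, 28), "ACTACA")
  ## truth record validates against the emitted genome
  expect_equal(substr(pl$genome$sequence, pl$truth$start + 1,
                      pl$truth$end), site)
})

test_that("a 15 bp site pair is planted 68 bp apart", {
  cfg <- chip_sim_config(genome_length = 2e5, n_genes = 8, seed = 5)
  gen <- make_genome(cfg, gene_ids = sprintf("g%d", 1:8))
  plan <- data.frame(gene_id = c("g2", "g2"), site_class = "15bp",
                     arm_mismatches = 0L)
  pl <- plant_sites(gen$genome, gen$genes, plan, seed = 5)
  tr <- pl$truth[order(pl$truth$start), ]
  expect_equal(nrow(tr), 2)
  expect_equal(tr$end - tr$start, c(15, 15))
  expect_equal(tr$start[2] - tr$end[1], 68)
  ## both sites outside every gene body
  for (i in 1:2)
    expect_false(any(gen$genes$start < tr$end[i] &
                       gen$genes$end > tr$start[i]))
})

test_that("empty plans leave the genome unchanged and bad genes error", {
  cfg <- chip_sim_config(genome_length = 5e4, n_genes = 3, seed = 2)
  gen <- make_genome(cfg)
  pl <- plant_sites(gen$genome, gen$genes, NULL, seed = 2)
  expect_identical(pl$genome$sequence, gen$genome$sequence)
  expect_equal(nrow(pl$truth), 0)
  expect_error(plant_sites(gen$genome, gen$genes,
                           data.frame(gene_id = "nope",
                                      site_class = "28bp"), seed = 2),
               "nope")
})

test_that("control coverage matches the configured background law", {
  cfg <- chip_sim_config(genome_length = 4e5, n_genes = 0, seed = 21)
  gen <- make_genome(cfg)
  cov <- simulate_chip_coverage(gen$genome, NULL, cfg)
  mu <- cfg$background_mean
  se <- sqrt((mu + mu^2 / cfg$background_dispersion) / 4e5)
  expect_true(abs(mean(cov$control$counts) - mu) < 3 * se)
  ## with no sites and fold irrelevant, chip follows the same law
  expect_true(abs(mean(cov$chip$counts) - mu) < 3 * se)
})

test_that("unit enrichment makes chip and control exchangeable", {
  cfg <- chip_sim_config(genome_length = 3e5, n_genes = 6,
                         enrichment_fold = 1, seed = 9)
  ds <- generate_dataset(cfg, site_plan = data.frame(
    gene_id = c("g002", "g004"), site_class = "28bp",
    arm_mismatches = 0L), target_slots = c(2, 4))
  expect_true(abs(mean(ds$chip$counts) / mean(ds$control$counts) - 1)
              < 0.02)
})

test_that("summit coverage scales with the enrichment fold", {
  ## average summit coverage over sites and seeds ~ fold * background
  ratios <- unlist(lapply(1:6, function(s) {
    cfg <- chip_sim_config(genome_length = 2e5, n_genes = 8, seed = s)
    ds <- generate_dataset(cfg, site_plan = data.frame(
      gene_id = c("g002", "g005", "g007"), site_class = "28bp",
      arm_mismatches = 0L), target_slots = c(2, 5, 7))
    mid <- (ds$truth$start + ds$truth$end) %/% 2
    ds$chip$counts[mid + 1] / cfg$background_mean
  }))
  expect_true(mean(ratios) > 0.7 * 10 && mean(ratios) < 1.3 * 10)
})

test_that("SPR simulation inverts the Langmuir isotherm", {
  s <- simulate_spr_responses(kd = 5, rmax = 100, concentrations = 5,
                              noise_sd = 0)
  expect_equal(s$responses, 50)
  s <- simulate_spr_responses(kd = 5, rmax = 100,
                              concentrations = 5 * 1e4, noise_sd = 0)
  expect_true(abs(s$responses - 100) / 100 < 1e-4)
  expect_equal(spr_concentration_ladder(),
               c(100, 50, 25, 12.5, 6.25, 3.125, 1.56, 0.78, 0.39, 0.19))
})

test_that("Ct simulation encodes folds as cycle shifts", {
  ct <- simulate_ct_table(c(gA = 1), noise_sd = 0, seed = 1)
  r <- relative_expression_ddct(ct, calibrator_sample = "WT")
  expect_equal(r$delta_delta_ct[r$sample_id == "mutant"], 0)
  ct <- simulate_ct_table(c(gA = 4), noise_sd = 0, seed = 1)
  mut <- ct$ct[ct$gene_id == "gA" & ct$sample_id == "mutant"]
  wt <- ct$ct[ct$gene_id == "gA" & ct$sample_id == "WT"]
  expect_equal(unique(wt - mut), 2)
  expect_equal(sum(ct$gene_id == "gA" & ct$sample_id == "WT"), 3)
})

test_that("fixture regions carry the documented site architecture", {
  regs <- make_site_regions(seed = 4)
  expect_equal(names(regs), regulon_targets())
  expect_true(all(nchar(regs) == 300))
  expect_true(all(vapply(aceE_sites(), grepl, TRUE, x = regs[["aceE"]],
                         fixed = TRUE)))
  ## non-aceE regions contain an exact 28 bp site
  spec <- palindrome_spec(linker_lengths = 16, max_mismatches = 0)
  for (tg in setdiff(names(regs), "aceE"))
    expect_equal(nrow(find_pseudopalindromes(regs[[tg]], spec)), 1)
})
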