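test_that("uniform coverage yields ratio exactly 1 everywhere (circular)", {
  tr <- coverage_track("c", rep(7, 2e4), circular = TRUE)
  enr <- compute_enrichment(tr, peak_caller_config())
  expect_equal(nrow(enr), 800)
  expect_true(all(abs(enr$ratio - 1) < 1e-12))
})

test_that("a single enriched window matches the closed-form ratio", {
  ## value 10 on one exact 51-nt window centred at 5000, 1 elsewhere
  x <- rep(1, 2e4)
  x[4976:5026] <- 10
  tr <- coverage_track("c", x, circular = TRUE)
  enr <- compute_enrichment(tr)
  at <- enr$ratio[enr$position == 5000]
  expect_equal(at, 10 * 4001 / 4460, tolerance = 1e-12)
})

test_that("all-zero and sub-threshold tracks give no testable positions", {
  tr <- coverage_track("c", rep(0, 1e4), circular = TRUE)
  enr <- compute_enrichment(tr)
  expect_equal(nrow(enr), 0)
  expect_equal(nrow(call_peaks(score_enrichment(enr, tr))), 0)
})

test_that("linear tracks truncate the background window at the edges", {
  tr <- coverage_track("c", rep(3, 1e4), circular = FALSE)
  enr <- compute_enrichment(tr)
  ## truncated means still cancel on constant coverage
  expect_true(all(abs(enr$ratio - 1) < 1e-12))
  expect_equal(min(enr$position), 0)
})

test_that("NB fit recovers parameters from large samples", {
  set.seed(100)
  x <- rnbinom(1e5, size = 3, mu = 4)
  m <- fit_nb_null(x)
  expect_true(abs(m$size - 3) / 3 < 0.05)
  expect_true(abs(m$mu - 4) / 4 < 0.02)
})

test_that("NB fit falls back and caps on degenerate dispersion", {
  expect_warning(m <- fit_nb_null(rep(2, 50)), "Poisson-like|degenerate")
  expect_equal(m$mu, 2)
  expect_equal(m$size, 1e6)
  set.seed(101)
  suppressWarnings(mp <- fit_nb_null(rpois(2e4, 5)))
  expect_true(mp$size > 50)  # near-Poisson data push size far up
  expect_error(fit_nb_null(c(1, 2, 3)), "larger input")
})

test_that("NB tail p-values match closed forms and are monotone", {
  geom <- structure(list(size = 1, mu = 1), class = "nb_model")
  expect_equal(nb_tail_pvalue(2, geom), 0.25)  # P(X>=2), geometric p=1/2
  expect_equal(nb_tail_pvalue(0, geom), 1)
  m <- structure(list(size = 3, mu = 5), class = "nb_model")
  p <- nb_tail_pvalue(seq(0, 30, by = 0.5), m)
  expect_true(all(diff(p) <= 1e-15))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("BH adjustment matches hand-computed and reference values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_reference(p))
  }
})

## hand-built scored enrichment table
fake_enr <- function(pos, ratio, padj) {
  data.frame(replicon_id = "c", position = pos, window_mean = ratio * 5,
             background_mean = 5, ratio = ratio,
             pvalue = padj / 2, padj = padj)
}

test_that("peak construction merges runs and respects min_consecutive", {
  cfg <- peak_caller_config()
  expect_equal(nrow(call_peaks(fake_enr(c(0, 25), c(2, 2), c(0.5, 0.9)),
                               cfg)), 0)
  ## 5 consecutive significant positions -> one peak, summit at max ratio
  e <- fake_enr(seq(1000, 1100, by = 25), c(2, 3, 6, 4, 2), rep(0.01, 5))
  pk <- call_peaks(e, cfg)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$summit, 1050)
  expect_equal(pk$start, 1000 - 25)
  expect_equal(pk$end, 1100 + 26)
  expect_equal(pk$max_ratio, 6)
  ## two runs separated by a 100-nt hole -> two peaks
  e2 <- fake_enr(c(0, 25, 150, 175), c(3, 3, 4, 4), rep(0.01, 4))
  expect_equal(nrow(call_peaks(e2, cfg)), 2)
  ## singleton runs are discarded at min_consecutive = 2
  e3 <- fake_enr(c(0, 200), c(5, 5), c(0.01, 0.01))
  expect_equal(nrow(call_peaks(e3, cfg)), 0)
})

test_that("control screening uses the fold at the summit", {
  cfg <- peak_caller_config()
  pk <- data.frame(replicon_id = "c", start = 0L, end = 100L, summit = 50L,
                   n_windows = 3L, max_ratio = 8, min_padj = 1e-4)
  ctrl_flat <- data.frame(replicon_id = "c", position = seq(0, 200, 25),
                          window_mean = 5, background_mean = 5, ratio = 1)
  out <- filter_vs_control(pk, ctrl_flat, cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$fold_vs_control, 8)
  ## identical chip and control -> fold 1 -> removed
  ctrl_same <- transform(ctrl_flat, ratio = 8)
  expect_equal(nrow(filter_vs_control(pk, ctrl_same, cfg)), 0)
  ## control enriched 5x, chip 8x -> fold 1.6 < 2 -> removed
  ctrl5 <- transform(ctrl_flat, ratio = 5)
  expect_equal(nrow(filter_vs_control(pk, ctrl5, cfg)), 0)
  ## no control position near the summit -> retained with fold NA
  far <- data.frame(replicon_id = "c", position = 5000,
                    window_mean = 5, background_mean = 5, ratio = 1)
  expect_warning(kept <- filter_vs_control(pk, far, cfg), "retained")
  expect_equal(nrow(kept), 1)
  expect_true(is.na(kept$fold_vs_control))
})

test_that("annotation flags intergenic summits and orientation", {
  genes <- gene_features(c("gL", "gR", "gConvL", "gConvR"), "c",
                         c(1000L, 2100L, 5000L, 6500L),
                         c(1800L, 3000L, 5900L, 7400L),
                         c("-", "+", "+", "-"))
  pk <- data.frame(replicon_id = "c",
                   start = c(1850L, 1200L, 6000L),
                   end = c(2050L, 1400L, 6400L),
                   summit = c(1950L, 1300L, 6200L),
                   n_windows = 2L, max_ratio = 5, min_padj = 0.01)
  ann <- annotate_peaks(pk, genes)
  ## divergent pair: gL ends at 1800 ("-", start at its end), gR starts 2100
  expect_true(ann$intergenic[1])
  expect_equal(ann$candidate_targets[1], "gL,gR")
  ## summit inside a gene body
  expect_false(ann$intergenic[2])
  ## convergent pair: both genes point away -> no candidates
  expect_true(ann$intergenic[3])
  expect_equal(ann$candidate_targets[3], "")
  expect_equal(ann$left_gene[3], "gConvL")
  expect_equal(ann$right_gene[3], "gConvR")
})

test_that("adjusted p-values dominate raw p-values on simulated data", {
  ds <- small_sim(17)
  enr <- enrichment_table(ds$chip)
  tested <- !is.na(enr$padj)
  expect_true(any(tested))
  expect_true(all(enr$padj[tested] >= enr$pvalue[tested] - 1e-15))
})

test_that("peak counts shrink as alpha and control_fold tighten", {
  ds <- small_sim(23)
  loose <- call_peak_set(ds$chip, ds$control, ds$genes,
                         peak_caller_config(alpha = 0.05))
  tight <- call_peak_set(ds$chip, ds$control, ds$genes,
                         peak_caller_config(alpha = 1e-6))
  expect_true(nrow(tight$peaks) <= nrow(loose$peaks))
  harsher <- call_peak_set(ds$chip, ds$control, ds$genes,
                           peak_caller_config(control_fold = 100))
  expect_true(nrow(harsher$peaks) <= nrow(loose$peaks))
})

test_that("sum-preserving shuffles keep the mean ratio near 1", {
  ds <- small_sim(29)
  set.seed(1)
  shuffled <- coverage_track("c", sample(ds$chip$counts), circular = TRUE)
  enr <- compute_enrichment(shuffled)
  expect_true(abs(mean(enr$ratio) - 1) < 0.05)
})

test_that("the full caller recovers planted sites end to end", {
  for (s in c(301, 302)) {
    ds <- small_sim(s)
    res <- call_peak_set(ds$chip, ds$control, ds$genes)
    expect_equal(nrow(res$peaks), nrow(ds$truth))
    for (i in seq_len(nrow(ds$truth)))
      expect_true(any(res$peaks$start < ds$truth$end[i] &
                        res$peaks$end > ds$truth$start[i]))
    expect_true(all(res$peaks$intergenic))
  }
})

test_that("the ratio-based null remains available and runs", {
  ds <- small_sim(31)
  cfg <- peak_caller_config(null_on = "ratio")
  enr <- suppressWarnings(enrichment_table(ds$chip, cfg))
  tested <- !is.na(enr$padj)
  expect_true(any(tested))
  expect_true(all(enr$pvalue[tested] >= 0 & enr$pvalue[tested] <= 1))
})
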