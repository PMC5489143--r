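## qPCR quantification: relative expression by the 2^-ddCt method
## (normalised to a reference gene, compared to a calibrator sample) and
## absolute quantification against a genomic-DNA standard curve.

## Mean (or median) Ct over replicate wells of one gene in one sample.
.agg_ct <- function(ct, aggregate) {
  switch(aggregate, mean = mean(ct), median = stats::median(ct))
}

#' Relative expression by the 2^-ddCt method
#'
#' For each target gene and each non-calibrator sample:
#' `dCt = Ct_target - Ct_reference` within the sample,
#' `ddCt = dCt_sample - dCt_calibrator`, and
#' `fold = (1 + efficiency)^(-ddCt)` (base 2 at the default 100%
#' efficiency). Replicate wells are aggregated by the mean Ct (or
#' median). Per-replicate dCt values are retained (attribute
#' `"replicate_dct"`) for the downstream t-test on dCt; replicates are
#' paired with the reference well of the same replicate index when the
#' counts match, otherwise against the aggregated reference Ct.
#'
#' @param ct Data frame with columns `gene_id`, `sample_id`, `ct` (one
#'   row per well; a `replicate` column is optional).
#' @param calibrator_sample Sample id of the calibrator.
#' @param reference_gene Reference (endogenous control) gene id.
#' @param efficiency Amplification efficiency E, so folds use base
#'   `1 + E` (default 1, i.e. the classic base-2 readout).
#' @param aggregate `"mean"` (default) or `"median"` replicate
#'   aggregation.
#' @return Data frame with one row per (target gene, sample): `gene_id`,
#'   `sample_id`, `delta_ct`, `delta_delta_ct`, `fold`,
#'   `reference_gene`. Rows for the calibrator itself are included
#'   (`ddCt = 0`, `fold = 1`).
#' @export
relative_expression_ddct <- function(ct, calibrator_sample,
                                     reference_gene = "rpoD",
                                     efficiency = 1,
                                     aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(c("gene_id", "sample_id", "ct") %in% names(ct)),
            efficiency > 0)
  if (!calibrator_sample %in% ct$sample_id)
    stop("relative_expression_ddct: calibrator sample '",
         calibrator_sample, "' not in the table")
  samples <- unique(ct$sample_id)
  targets <- setdiff(unique(ct$gene_id), reference_gene)
  ref_ct <- function(s) {
    r <- ct$ct[ct$gene_id == reference_gene & ct$sample_id == s]
    if (!length(r))
      stop("relative_expression_ddct: reference gene '", reference_gene,
           "' missing in sample '", s, "'")
    r
  }
  dct <- function(g, s) {
    tc <- ct$ct[ct$gene_id == g & ct$sample_id == s]
    if (!length(tc)) return(NULL)
    .agg_ct(tc, aggregate) - .agg_ct(ref_ct(s), aggregate)
  }
  rep_dct <- function(g, s) {
    tc <- ct$ct[ct$gene_id == g & ct$sample_id == s]
    rc <- ref_ct(s)
    if (length(tc) == length(rc)) tc - rc
    else tc - .agg_ct(rc, aggregate)
  }
  rows <- list(); reps <- list()
  for (g in targets) {
    d_cal <- dct(g, calibrator_sample)
    if (is.null(d_cal))
      stop("relative_expression_ddct: target '", g,
           "' missing in the calibrator sample")
    for (s in samples) {
      d <- dct(g, s)
      if (is.null(d)) next
      ddct <- d - d_cal
      rows[[length(rows) + 1L]] <-
        data.frame(gene_id = g, sample_id = s, delta_ct = d,
                   delta_delta_ct = ddct,
                   fold = (1 + efficiency)^(-ddct),
                   reference_gene = reference_gene,
                   stringsAsFactors = FALSE)
      reps[[paste(g, s, sep = "\r")]] <- rep_dct(g, s)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "replicate_dct") <- reps
  out
}

#' Student's t-test on replicate dCt values
#'
#' Convenience wrapper over [stats::t.test()] comparing the
#' per-replicate dCt values of one gene in a sample against the
#' calibrator, as is standard practice for 2^-ddCt designs.
#'
#' @param expression Result of [relative_expression_ddct()].
#' @param gene_id Target gene.
#' @param sample_id Sample to compare.
#' @param calibrator_sample Calibrator sample id.
#' @param ... Passed to [stats::t.test()].
#' @return The `htest` object.
#' @export
ddct_t_test <- function(expression, gene_id, sample_id, calibrator_sample,
                        ...) {
  reps <- attr(expression, "replicate_dct")
  if (is.null(reps)) stop("ddct_t_test: no replicate dCt values attached")
  a <- reps[[paste(gene_id, sample_id, sep = "\r")]]
  b <- reps[[paste(gene_id, calibrator_sample, sep = "\r")]]
  if (is.null(a) || is.null(b))
    stop("ddct_t_test: gene/sample combination not present")
  stats::t.test(a, b, ...)
}

#' Absolute quantification against a standard curve
#'
#' Fits the ordinary least-squares line `Ct = a * log10(copies) + b` to
#' the standards (the slope must be negative: more template, earlier
#' amplification) and inverts it at the sample Ct. Sample Cts outside
#' the standards' Ct range are flagged as extrapolated.
#'
#' @param standards Data frame with columns `copies` (template copy
#'   number) and `ct`; at least 3 points.
#' @param sample_ct Sample Ct value(s).
#' @return Data frame with `sample_ct`, `copies`, `extrapolated`;
#'   attributes `"slope"`, `"intercept"`, `"r_squared"`.
#' @export
absolute_quantify <- function(standards, sample_ct) {
  stopifnot(all(c("copies", "ct") %in% names(standards)))
  if (nrow(standards) < 3L)
    stop("absolute_quantify: need at least 3 standards")
  if (any(standards$copies <= 0))
    stop("absolute_quantify: copy numbers must be positive")
  fit <- stats::lm(ct ~ log10(copies), data = standards)
  a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  if (!(a < 0))
    stop("absolute_quantify: non-negative slope (", signif(a, 4),
         "); amplification implies a negative slope")
  copies <- 10^((sample_ct - b) / a)
  out <- data.frame(sample_ct = sample_ct, copies = copies,
                    extrapolated = sample_ct < min(standards$ct) |
                      sample_ct > max(standards$ct))
  attr(out, "slope") <- a
  attr(out, "intercept") <- b
  ## direct R^2 (summary.lm warns on zero-residual exact lines)
  sst <- sum((standards$ct - mean(standards$ct))^2)
  attr(out, "r_squared") <-
    if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  out
}
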