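## Windowed-enrichment peak calling with a negative-binomial null.
##
## The test statistic at every `step`-th genomic position is the ratio of
## the mean coverage in a short window (default 51 nt) to the mean coverage
## in a long centred background window (default 4001 nt). Positions with
## ratio below a threshold are discarded; the survivors are assigned upper
## tail p-values under a fitted NB null, BH-adjusted, and merged into
## peaks, which are then screened against a control (e.g. deletion-strain)
## track and annotated against the gene model.

#' Peak-caller configuration
#'
#' @param window Short window width in nt (odd).
#' @param step Evaluation step in nt.
#' @param background Background window width in nt (odd, > `window`).
#' @param ratio_threshold Minimum enrichment ratio retained for testing.
#' @param alpha BH-adjusted p-value cutoff for peak membership.
#' @param min_consecutive Minimum number of consecutive significant
#'   positions forming a peak (suppresses single-window noise).
#' @param control_fold Minimum ratio of peak enrichment to control
#'   enrichment at the summit for a peak to survive the control screen.
#' @param null_on What the NB null is fitted to: `"coverage"` (default)
#'   fits the per-base coverage of the track and tests the rounded
#'   short-window mean coverage of each retained position against it;
#'   `"ratio"` fits the rounded retained enrichment ratios themselves and
#'   tests the rounded ratios (see the methods vignette for why coverage
#'   is the default).
#' @param ratio_mode `"mean"` (default) computes the ratio of window
#'   means, which equals 1 on uniform coverage and matches the
#'   `ratio_threshold` semantics; `"sum"` is the raw sum-over-sum audit
#'   variant (bounded above by 1, for inspection only).
#' @param round_scale Ratios are multiplied by this factor before rounding
#'   when `null_on = "ratio"` (1 = round to integers; 10 preserves one
#'   decimal).
#' @return A list of class `peak_caller_config`.
#' @export
peak_caller_config <- function(window = 51, step = 25, background = 4001,
                               ratio_threshold = 1.5, alpha = 0.05,
                               min_consecutive = 2, control_fold = 2,
                               null_on = c("coverage", "ratio"),
                               ratio_mode = c("mean", "sum"),
                               round_scale = 1) {
  null_on <- match.arg(null_on)
  ratio_mode <- match.arg(ratio_mode)
  stopifnot(window %% 2 == 1, background %% 2 == 1, background > window,
            step >= 1, ratio_threshold > 0, alpha > 0, alpha < 1,
            min_consecutive >= 1, control_fold > 0, round_scale > 0)
  structure(list(window = as.integer(window), step = as.integer(step),
                 background = as.integer(background),
                 ratio_threshold = ratio_threshold, alpha = alpha,
                 min_consecutive = as.integer(min_consecutive),
                 control_fold = control_fold, null_on = null_on,
                 ratio_mode = ratio_mode, round_scale = round_scale),
            class = "peak_caller_config")
}

## Centred moving-window sums at the evaluated positions. `centers` are
## 0-based. Circular tracks wrap; linear tracks truncate the window at the
## replicon ends and return the truncated width alongside.
.window_sums <- function(counts, centers, width, circular) {
  L <- length(counts)
  half <- (width - 1L) %/% 2L
  if (circular) {
    if (L < width)
      stop("window wider than circular replicon (", width, " > ", L, ")")
    cs <- c(0, cumsum(c(counts, counts[seq_len(min(width, L))])))
    st <- (centers - half) %% L        # 0-based start of window
    list(sum = cs[st + width + 1L] - cs[st + 1L],
         width = rep(width, length(centers)))
  } else {
    cs <- c(0, cumsum(counts))
    st <- pmax(0L, centers - half)
    en <- pmin(L, centers + half + 1L)  # 0-based half-open
    list(sum = cs[en + 1L] - cs[st + 1L], width = en - st)
  }
}

#' Compute the windowed enrichment ratio along a coverage track
#'
#' At every `step`-th position the enrichment ratio is the mean coverage
#' in the short window divided by the mean coverage in the long centred
#' background window. Positions whose background-window mean is zero are
#' skipped (no ratio is defined there).
#'
#' @param track A [coverage_track()].
#' @param config A [peak_caller_config()].
#' @return Data frame with columns `replicon_id`, `position` (0-based
#'   window centre), `window_mean`, `background_mean`, `ratio`.
#' @export
compute_enrichment <- function(track, config = peak_caller_config()) {
  stopifnot(inherits(track, "coverage_track"),
            inherits(config, "peak_caller_config"))
  L <- length(track$counts)
  if (L == 0L || all(track$counts == 0)) {
    if (L == 0L) stop("compute_enrichment: empty track")
  }
  centers <- seq.int(0L, L - 1L, by = config$step)
  w <- .window_sums(track$counts, centers, config$window, track$circular)
  b <- .window_sums(track$counts, centers, config$background,
                    track$circular)
  wmean <- w$sum / w$width
  bmean <- b$sum / b$width
  ratio <- if (config$ratio_mode == "mean") wmean / bmean else w$sum / b$sum
  keep <- bmean > 0
  data.frame(replicon_id = rep(track$replicon_id, sum(keep)),
             position = centers[keep],
             window_mean = wmean[keep], background_mean = bmean[keep],
             ratio = ratio[keep], stringsAsFactors = FALSE)
}

#' Fit a negative-binomial null to count-like data
#'
#' Values are rounded to the nearest non-negative integer and an NB is
#' fitted by maximum likelihood (method-of-moments initialisation). When
#' the ML fit fails, or the data are under- or equi-dispersed (variance
#' <= mean, where the NB degenerates towards Poisson), the fit falls back
#' to the moments estimate with the `size` parameter capped, and warns.
#'
#' @param x Numeric vector of non-negative values (>= `min_n` of them).
#' @param min_n Minimum number of observations.
#' @param size_cap Upper bound for the dispersion parameter.
#' @return An object of class `nb_model` with fields `size` and `mu`.
#' @export
fit_nb_null <- function(x, min_n = 10, size_cap = 1e6) {
  x <- round(x)
  if (any(x < 0)) stop("fit_nb_null: negative values")
  if (length(x) < min_n)
    stop("fit_nb_null: only ", length(x), " values (need >= ", min_n,
         "); provide a larger input")
  m <- mean(x); v <- stats::var(x)
  if (m <= 0) stop("fit_nb_null: all-zero input")
  if (v <= m) {
    warning("fit_nb_null: variance <= mean (Poisson-like or degenerate); ",
            "size capped at ", size_cap)
    return(structure(list(size = size_cap, mu = m), class = "nb_model"))
  }
  size0 <- m^2 / (v - m)
  fit <- tryCatch(
    suppressWarnings(MASS::fitdistr(x, "negative binomial",
                                    start = list(size = size0, mu = m),
                                    lower = c(1e-8, 1e-8))),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("fit_nb_null: ML fit failed; falling back to moments estimate")
    size <- min(size0, size_cap)
    return(structure(list(size = size, mu = m), class = "nb_model"))
  }
  size <- unname(fit$estimate["size"])
  mu <- unname(fit$estimate["mu"])
  if (size > size_cap) {
    warning("fit_nb_null: fitted size exceeds cap; capped at ", size_cap)
    size <- size_cap
  }
  structure(list(size = size, mu = mu), class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("<nb_model> size = %.4g, mu = %.4g\n", x$size, x$mu))
  invisible(x)
}

#' Upper-tail NB p-value for a count-like statistic
#'
#' `P(X >= round(x))` under the fitted null, computed as
#' `1 - F(round(x) - 1)`. Vectorised over `x`.
#'
#' @param x Observed statistic(s).
#' @param model An `nb_model` from [fit_nb_null()].
#' @return P-values in `[0, 1]`.
#' @export
nb_tail_pvalue <- function(x, model) {
  stopifnot(inherits(model, "nb_model"))
  stats::pnbinom(pmax(0, round(x)) - 1, size = model$size, mu = model$mu,
                 lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; output order
#' matches input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Score an enrichment table under the NB null
#'
#' Positions with ratio below the threshold are removed from testing
#' (their `pvalue`/`padj` are `NA`); the rest get NB upper-tail p-values
#' and BH adjustment over exactly that retained set.
#'
#' With `null_on = "coverage"` the null is fitted to the track's per-base
#' coverage (deterministically subsampled to at most `max_null_points`
#' values) and the tested statistic is the rounded short-window mean
#' coverage. With `null_on = "ratio"` the null is fitted to the rounded
#' retained ratios and the tested statistic is the rounded ratio.
#'
#' @param enrichment Output of [compute_enrichment()].
#' @param track The [coverage_track()] the enrichment was computed from
#'   (needed when `null_on = "coverage"`).
#' @param config A [peak_caller_config()].
#' @param max_null_points Subsample cap for the coverage null fit.
#' @return The enrichment data frame with `pvalue` and `padj` columns
#'   added; the fitted `nb_model` is attached as attribute `"null_model"`.
#' @export
score_enrichment <- function(enrichment, track = NULL,
                             config = peak_caller_config(),
                             max_null_points = 2e5) {
  retained <- enrichment$ratio >= config$ratio_threshold
  enrichment$pvalue <- rep(NA_real_, nrow(enrichment))
  enrichment$padj <- rep(NA_real_, nrow(enrichment))
  if (!any(retained)) return(enrichment)
  if (config$null_on == "coverage") {
    if (is.null(track))
      stop("score_enrichment: track required when null_on = 'coverage'")
    thin <- max(1L, ceiling(length(track$counts) / max_null_points))
    model <- fit_nb_null(track$counts[seq(1L, length(track$counts),
                                          by = thin)])
    stat <- enrichment$window_mean[retained]
  } else {
    model <- fit_nb_null(config$round_scale * enrichment$ratio[retained])
    stat <- config$round_scale * enrichment$ratio[retained]
  }
  p <- nb_tail_pvalue(stat, model)
  enrichment$pvalue[retained] <- p
  enrichment$padj[retained] <- bh_adjust(p)
  attr(enrichment, "null_model") <- model
  enrichment
}

#' Build an enrichment table (ratio + p-values) from a coverage track
#'
#' Convenience wrapper: [compute_enrichment()] then [score_enrichment()].
#'
#' @inheritParams score_enrichment
#' @param track A [coverage_track()].
#' @return Scored enrichment data frame.
#' @export
enrichment_table <- function(track, config = peak_caller_config(), ...) {
  score_enrichment(compute_enrichment(track, config), track = track,
                   config = config, ...)
}

#' Merge significant enrichment positions into peaks
#'
#' Positions that are significant (`padj <= alpha` and ratio at or above
#' the threshold) and lie within one `step` of each other are merged;
#' runs shorter than `min_consecutive` are discarded. A peak spans the
#' outermost short-window edges of its run and its summit is the position
#' with the maximum ratio.
#'
#' @param enrichment Scored enrichment table (sorted by position).
#' @param config A [peak_caller_config()].
#' @return Data frame of peaks: `replicon_id`, `start`, `end`, `summit`,
#'   `n_windows`, `max_ratio`, `min_padj` (plus placeholder columns filled
#'   in by [filter_vs_control()] and [annotate_peaks()]).
#' @export
call_peaks <- function(enrichment, config = peak_caller_config()) {
  empty <- data.frame(replicon_id = character(), start = integer(),
                      end = integer(), summit = integer(),
                      n_windows = integer(), max_ratio = numeric(),
                      min_padj = numeric(), stringsAsFactors = FALSE)
  sig <- !is.na(enrichment$padj) & enrichment$padj <= config$alpha &
    enrichment$ratio >= config$ratio_threshold
  if (!any(sig)) return(empty)
  e <- enrichment[sig, , drop = FALSE]
  e <- e[order(e$position), , drop = FALSE]
  grp <- cumsum(c(TRUE, diff(e$position) > config$step))
  half <- (config$window - 1L) %/% 2L
  peaks <- do.call(rbind, lapply(split(e, grp), function(run) {
    if (nrow(run) < config$min_consecutive) return(NULL)
    data.frame(replicon_id = run$replicon_id[1],
               start = min(run$position) - half,
               end = max(run$position) + half + 1L,
               summit = run$position[which.max(run$ratio)],
               n_windows = nrow(run),
               max_ratio = max(run$ratio),
               min_padj = min(run$padj),
               stringsAsFactors = FALSE)
  }))
  if (is.null(peaks)) return(empty)
  rownames(peaks) <- NULL
  peaks
}

#' Screen peaks against a control enrichment track
#'
#' A peak is retained if its maximum ratio divided by the control ratio
#' at the evaluated control position nearest its summit is at least
#' `control_fold`. If no control position lies within one `step` of the
#' summit, the peak is retained with fold `NA` and a warning.
#'
#' @param peaks Output of [call_peaks()].
#' @param control_enrichment [compute_enrichment()] of the control track,
#'   computed with the same configuration.
#' @param config A [peak_caller_config()].
#' @return Peaks with `control_ratio_at_summit` and `fold_vs_control`
#'   columns, filtered to the survivors.
#' @export
filter_vs_control <- function(peaks, control_enrichment,
                              config = peak_caller_config()) {
  if (nrow(peaks) == 0L) {
    peaks$control_ratio_at_summit <- numeric(0)
    peaks$fold_vs_control <- numeric(0)
    return(peaks)
  }
  cp <- control_enrichment$position
  idx <- vapply(peaks$summit, function(s) which.min(abs(cp - s)), 0L)
  dist <- abs(cp[idx] - peaks$summit)
  ctrl <- control_enrichment$ratio[idx]
  missing <- dist > config$step
  if (any(missing)) {
    warning("filter_vs_control: no control position within ", config$step,
            " nt of ", sum(missing), " summit(s); retained with fold NA")
    ctrl[missing] <- NA_real_
  }
  peaks$control_ratio_at_summit <- ctrl
  peaks$fold_vs_control <- peaks$max_ratio / ctrl
  keep <- is.na(peaks$fold_vs_control) |
    peaks$fold_vs_control >= config$control_fold
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate peaks with gene context
#'
#' Flags each peak as intergenic (summit inside no gene body), records the
#' nearest genes to the left and right of the summit, and lists candidate
#' target genes: genes whose own-strand start lies within
#' `candidate_window` bp downstream of the summit (a forward gene starting
#' at or after the summit, or a reverse gene starting -- in genomic
#' coordinates, ending -- at or before it). A peak between two divergent
#' gene starts therefore yields two candidates; one between convergent
#' gene ends yields none.
#'
#' @param peaks Peak data frame with a `summit` column.
#' @param genes A [gene_features()] data frame.
#' @param candidate_window Maximum summit-to-start distance in bp.
#' @return Peaks with `intergenic`, `left_gene`, `right_gene` and
#'   `candidate_targets` (comma-separated) columns.
#' @export
annotate_peaks <- function(peaks, genes, candidate_window = 500) {
  n <- nrow(peaks)
  peaks$intergenic <- logical(n)
  peaks$left_gene <- rep(NA_character_, n)
  peaks$right_gene <- rep(NA_character_, n)
  peaks$candidate_targets <- character(n)
  for (i in seq_len(n)) {
    s <- peaks$summit[i]
    g <- genes[genes$replicon_id == peaks$replicon_id[i], , drop = FALSE]
    inside <- g$start <= s & s < g$end
    peaks$intergenic[i] <- !any(inside)
    left <- g[g$end <= s, , drop = FALSE]
    if (nrow(left))
      peaks$left_gene[i] <- left$gene_id[which.max(left$end)]
    right <- g[g$start > s, , drop = FALSE]
    if (nrow(right))
      peaks$right_gene[i] <- right$gene_id[which.min(right$start)]
    fwd <- g$strand == "+" & g$start >= s & g$start - s <= candidate_window
    rev <- g$strand == "-" & g$end <= s & s - g$end <= candidate_window
    peaks$candidate_targets[i] <-
      paste(g$gene_id[fwd | rev], collapse = ",")
  }
  peaks
}

#' Call, screen and annotate peaks in one step
#'
#' The full caller: enrichment + NB p-values on the ChIP track, peak
#' construction, control screen, gene annotation.
#'
#' @param chip,control [coverage_track()] objects (control may be `NULL`
#'   to skip the control screen).
#' @param genes A [gene_features()] data frame (may be `NULL` to skip
#'   annotation).
#' @param config A [peak_caller_config()].
#' @return A list: `peaks` (annotated surviving peaks), `enrichment`
#'   (scored ChIP enrichment table), `control_enrichment` (or `NULL`).
#' @export
call_peak_set <- function(chip, control = NULL, genes = NULL,
                          config = peak_caller_config()) {
  enr <- enrichment_table(chip, config)
  peaks <- call_peaks(enr, config)
  ctrl_enr <- NULL
  if (!is.null(control)) {
    ctrl_enr <- compute_enrichment(control, config)
    peaks <- filter_vs_control(peaks, ctrl_enr, config)
  } else if (nrow(peaks)) {
    peaks$control_ratio_at_summit <- NA_real_
    peaks$fold_vs_control <- NA_real_
  }
  if (!is.null(genes)) peaks <- annotate_peaks(peaks, genes)
  list(peaks = peaks, enrichment = enr, control_enrichment = ctrl_enr)
}
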