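## Steady-state SPR analytics for a reusable DNA-capture (ReDCaT-style)
## chip: theoretical maximum response given the captured DNA, %Rmax
## normalisation, one-site Langmuir affinity fits, and classification of
## effector-ligand influence on binding.

#' SPR titration series
#'
#' One steady-state titration of an analyte (the protein, binding as
#' `stoichiometry` dimers by default) over a captured DNA ligand.
#' Concentration/response points are stored in increasing concentration
#' order.
#'
#' @param dna_id Identifier of the captured DNA oligomer.
#' @param ru_ligand Response units of captured DNA.
#' @param mw_ligand Molecular mass of the DNA ligand (Da).
#' @param mw_analyte_monomer Molecular mass of the analyte monomer (Da).
#' @param stoichiometry Analyte units bound per DNA (default 1 dimer).
#' @param concentrations Analyte concentrations (uM), unique and >= 0.
#' @param responses Steady-state responses (RU), one per concentration.
#' @param effector_concentration Effector-ligand concentration (uM) this
#'   series was measured at, or `NA`.
#' @return An object of class `spr_series`.
#' @export
spr_series <- function(dna_id, ru_ligand, mw_ligand, mw_analyte_monomer,
                       stoichiometry = 1, concentrations, responses,
                       effector_concentration = NA_real_) {
  stopifnot(ru_ligand > 0, mw_ligand > 0, mw_analyte_monomer > 0,
            stoichiometry > 0,
            length(concentrations) == length(responses),
            all(concentrations >= 0))
  if (anyDuplicated(concentrations))
    stop("spr_series: duplicate concentrations")
  ord <- order(concentrations)
  structure(list(dna_id = as.character(dna_id), ru_ligand = ru_ligand,
                 mw_ligand = mw_ligand,
                 mw_analyte_monomer = mw_analyte_monomer,
                 stoichiometry = stoichiometry,
                 concentrations = as.numeric(concentrations[ord]),
                 responses = as.numeric(responses[ord]),
                 effector_concentration = effector_concentration),
            class = "spr_series")
}

#' @export
print.spr_series <- function(x, ...) {
  cat(sprintf("<spr_series> %s: %d points, %g-%g uM%s\n", x$dna_id,
              length(x$concentrations), min(x$concentrations),
              max(x$concentrations),
              if (is.na(x$effector_concentration)) "" else
                sprintf(", effector %g uM", x$effector_concentration)))
  invisible(x)
}

#' Theoretical maximum SPR response
#'
#' `Rmax = stoichiometry * 2 * mw_analyte_monomer / mw_ligand * ru_ligand`
#' under the default assumption that one analyte unit is a dimer; with
#' `mass_is_total = TRUE` the factor 2 is dropped and
#' `mw_analyte_monomer` is read as the total analyte mass per bound unit.
#'
#' @param series An [spr_series()].
#' @param mass_is_total Is the analyte mass given as total mass per bound
#'   unit (rather than per monomer of a dimer)?
#' @return Theoretical Rmax in RU.
#' @export
theoretical_rmax <- function(series, mass_is_total = FALSE) {
  stopifnot(inherits(series, "spr_series"))
  if (series$mw_ligand <= 0 || series$mw_analyte_monomer <= 0)
    stop("theoretical_rmax: masses must be positive")
  mass <- if (mass_is_total) series$mw_analyte_monomer else
    2 * series$mw_analyte_monomer
  series$stoichiometry * mass / series$mw_ligand * series$ru_ligand
}

#' Response as a percentage of the theoretical maximum
#'
#' @param response Observed response(s), RU.
#' @param rmax Theoretical maximum response, RU (> 0).
#' @return `100 * response / rmax`.
#' @export
percent_rmax <- function(response, rmax) {
  if (!is.numeric(rmax) || length(rmax) != 1L || rmax <= 0)
    stop("percent_rmax: rmax must be a single positive number")
  100 * response / rmax
}

#' Fit a one-site steady-state (Langmuir) binding isotherm
#'
#' Least-squares fit of `R(C) = Rmax * C / (Kd + C)` with positivity
#' constraints on both parameters. Started from the half-saturation
#' heuristic (Rmax from the top response, Kd from the concentration
#' nearest half of it).
#'
#' @param series An [spr_series()] with at least 4 concentration points.
#' @return An object of class `affinity_fit`: `kd` (uM), `rmax_fitted`
#'   (RU), `residual_rms` (RU) and the underlying `fit` object.
#' @export
fit_steady_state <- function(series) {
  stopifnot(inherits(series, "spr_series"))
  C <- series$concentrations
  R <- series$responses
  if (length(C) < 4L)
    stop("fit_steady_state: need at least 4 concentration points")
  rmax0 <- max(R) * 1.2
  kd0 <- C[which.min(abs(R - rmax0 / 2))]
  if (kd0 <= 0) kd0 <- stats::median(C[C > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(R ~ rmax * C / (kd + C),
                      start = list(rmax = rmax0, kd = kd0),
                      lower = c(rmax = 1e-12, kd = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("fit_steady_state: fit did not converge (", conditionMessage(e),
           "); last start was rmax=", signif(rmax0, 4), ", kd=",
           signif(kd0, 4)))
  est <- stats::coef(fit)
  structure(list(kd = unname(est["kd"]), rmax_fitted = unname(est["rmax"]),
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 fit = fit),
            class = "affinity_fit")
}

#' @export
print.affinity_fit <- function(x, ...) {
  cat(sprintf("<affinity_fit> Kd = %.4g uM, Rmax = %.4g RU, RMS = %.3g RU\n",
              x$kd, x$rmax_fitted, x$residual_rms))
  invisible(x)
}

#' Predict the fitted isotherm at given concentrations
#'
#' @param object An `affinity_fit`.
#' @param concentrations Concentrations (uM) to evaluate at.
#' @param ... Unused.
#' @return Predicted responses (RU).
#' @export
predict.affinity_fit <- function(object, concentrations, ...) {
  object$rmax_fitted * concentrations / (object$kd + concentrations)
}

#' Classify the effect of an effector ligand on binding
#'
#' Compares a binding readout (typically %Rmax at one analyte
#' concentration) across increasing effector concentrations. The effect
#' is `"increases"`/`"decreases"` when every successive step moves in the
#' same direction and the total change exceeds `tolerance` times the
#' zero-effector baseline; otherwise `"none"`.
#'
#' @param responses Binding readout, one value per effector
#'   concentration.
#' @param effector_concentrations Effector concentrations (uM); must
#'   include 0 (the baseline) and at least 3 levels.
#' @param tolerance Relative change threshold (default 0.10).
#' @return `"increases"`, `"decreases"` or `"none"`.
#' @export
classify_effector <- function(responses, effector_concentrations,
                              tolerance = 0.10) {
  stopifnot(length(responses) == length(effector_concentrations))
  if (length(responses) < 3L)
    stop("classify_effector: need at least 3 effector concentrations")
  if (!any(effector_concentrations == 0))
    stop("classify_effector: missing 0-effector baseline")
  ord <- order(effector_concentrations)
  r <- responses[ord]
  baseline <- r[1]
  steps <- diff(r)
  total <- r[length(r)] - baseline
  if (all(steps > 0) && total > tolerance * baseline) return("increases")
  if (all(steps < 0) && -total > tolerance * baseline) return("decreases")
  "none"
}

#' Read SPR series from a TSV table
#'
#' Expected columns: `dna_id`, `ru_ligand`, `mw_ligand`, `mw_monomer`,
#' `stoichiometry`, `effector_conc`, `concentration`, `response`. Rows
#' are grouped into one [spr_series()] per (`dna_id`, `effector_conc`)
#' pair.
#'
#' @param path Path to the TSV file.
#' @return A list of [spr_series()] objects.
#' @export
read_spr_table <- function(path) {
  df <- read_tsv(path)
  need <- c("dna_id", "ru_ligand", "mw_ligand", "mw_monomer",
            "stoichiometry", "effector_conc", "concentration", "response")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_spr_table: missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(df$dna_id, df$effector_conc, sep = "\r")
  lapply(split(df, key), function(g)
    spr_series(dna_id = g$dna_id[1], ru_ligand = g$ru_ligand[1],
               mw_ligand = g$mw_ligand[1],
               mw_analyte_monomer = g$mw_monomer[1],
               stoichiometry = g$stoichiometry[1],
               concentrations = g$concentration, responses = g$response,
               effector_concentration = g$effector_conc[1]))
}

#' Write SPR series to a TSV table
#'
#' Inverse of [read_spr_table()].
#'
#' @param series_list A list of [spr_series()] objects (or one).
#' @param path Output path.
#' @export
write_spr_table <- function(series_list, path) {
  if (inherits(series_list, "spr_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s)
    data.frame(dna_id = s$dna_id, ru_ligand = s$ru_ligand,
               mw_ligand = s$mw_ligand, mw_monomer = s$mw_analyte_monomer,
               stoichiometry = s$stoichiometry,
               effector_conc = s$effector_concentration,
               concentration = s$concentrations, response = s$responses,
               stringsAsFactors = FALSE))
  write_tsv(do.call(rbind, rows), path)
}
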