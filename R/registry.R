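#' Measure registry
#'
#' The four tripartite measures are addressed by registry name:
#' `"pcorr"` (partial correlation; unique atoms only, tested as |PCorr|),
#' `"vp"` (variance partitioning), `"mmi_discrete"` and `"broja"` (discrete
#' PID from the empirical pmf), `"mmi_continuous"` (KSG-based PID).  The
#' registry records which atoms each measure reports, which variable kinds
#' it accepts, and that PID measures are never applied to the `mSum` model
#' (whose PID ground truth is contested).
#'
#' @return A tibble with one row per legal (measure, atom, kind) triple.
#' @export
#' @examples
#' measure_registry()
measure_registry <- function() {
  rows <- list(
    tidyr::expand_grid(measure = "pcorr", atom = c("unq_x", "unq_y"), kind = .kind_ids),
    tidyr::expand_grid(measure = "vp", atom = .atom_ids, kind = .kind_ids),
    tidyr::expand_grid(measure = "mmi_discrete", atom = .atom_ids, kind = "discrete"),
    tidyr::expand_grid(measure = "broja", atom = .atom_ids, kind = "discrete"),
    tidyr::expand_grid(measure = "mmi_continuous", atom = .atom_ids, kind = "continuous")
  )
  out <- dplyr::bind_rows(rows)
  out$pid <- out$measure %in% c("mmi_discrete", "broja", "mmi_continuous")
  out
}

#' Models a measure may be evaluated on
#'
#' PID measures exclude `mSum`; the linear measures accept all four models.
#'
#' @param measure Registry name.
#' @return Character vector of legal ground-truth model ids.
#' @export
legal_models <- function(measure) {
  measure <- match.arg(measure, .measure_ids)
  if (measure %in% c("mmi_discrete", "broja", "mmi_continuous")) {
    setdiff(.model_ids, "mSum")
  } else {
    .model_ids
  }
}

#' Compute the information atoms of one dataset under one measure
#'
#' Dispatches a triplet to the requested measure and returns its atoms as a
#' tidy table.  `pcorr` values are reported as magnitudes `|PCorr|` (the
#' two-sided test statistic used throughout the significance machinery);
#' [pcorr_atoms()] gives the signed values.
#'
#' @param data A `triplet` tibble.
#' @param measure Registry name (see [measure_registry()]).
#' @param k KSG neighbour count (continuous MMI only).
#' @param tol BROJA convergence tolerance in bits.
#' @return Tibble with columns `measure`, `atom`, `value`.
#' @export
#' @examples
#' s <- sample_ground_truth("mXOR", "discrete", 1000, seed = 1)
#' compute_atoms(s, "mmi_discrete")
compute_atoms <- function(data, measure, k = 3, tol = 1e-9) {
  measure <- match.arg(measure, .measure_ids)
  model <- attr(data, "model")
  if (!is.null(model) && !(model %in% legal_models(measure))) {
    abort(sprintf("measure '%s' is not applied to model '%s'", measure, model))
  }
  kind <- triplet_kind(data)
  if (measure %in% c("mmi_discrete", "broja") && kind != "discrete") {
    abort(sprintf("measure '%s' needs discrete data", measure))
  }
  if (measure == "mmi_continuous" && kind != "continuous") {
    abort("measure 'mmi_continuous' needs continuous data")
  }
  res <- switch(measure,
    pcorr = dplyr::mutate(pcorr_atoms(data), value = abs(.data$value)),
    vp = tidy(vp_atoms(data)),
    mmi_discrete = tidy(mmi_pid_discrete(empirical_pmf(data))),
    broja = tidy(broja_pid_discrete(empirical_pmf(data), tol = tol)),
    mmi_continuous = tidy(mmi_pid_continuous(data, k = k))
  )
  dplyr::mutate(res, measure = measure, .before = 1)
}

#' Build a scalar atom statistic for significance testing
#'
#' Returns a function of a triplet that evaluates one atom of one measure —
#' the test-statistic form consumed by [permutation_critical_value()] and
#' the adversarial searches.  For `pcorr` the statistic is the magnitude
#' `|PCorr|`.
#'
#' @inheritParams compute_atoms
#' @param atom One of `"unq_x"`, `"unq_y"`, `"red"`, `"syn"` (the unique
#'   atoms only, for `pcorr`).
#' @return A function `f(data) -> numeric(1)`.
#' @export
atom_statistic <- function(measure, atom, k = 3, tol = 1e-9) {
  measure <- match.arg(measure, .measure_ids)
  atom <- match.arg(atom, .atom_ids)
  reg <- measure_registry()
  if (!any(reg$measure == measure & reg$atom == atom)) {
    abort(sprintf("measure '%s' does not report atom '%s'", measure, atom))
  }
  force(k); force(tol)
  # direct dispatch (no tidy-table construction): this closure sits inside
  # every permutation and grid-search loop
  switch(measure,
    pcorr = if (atom == "unq_x") {
      function(data) abs(partial_correlation(data$x, data$y, data$z))
    } else {
      function(data) abs(partial_correlation(data$y, data$x, data$z))
    },
    vp = function(data) vp_atoms(data)$atoms[[atom]],
    mmi_discrete = function(data) mmi_pid_discrete(empirical_pmf(data))$atoms[[atom]],
    broja = function(data) broja_pid_discrete(empirical_pmf(data), tol = tol)$atoms[[atom]],
    mmi_continuous = function(data) mmi_pid_continuous(data, k = k)$atoms[[atom]]
  )
}
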