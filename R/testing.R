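#' Significance-testing configuration
#'
#' Bundles the testing parameters.  The `"paper"` profile matches the study
#' conditions (`alpha = 0.01`, data size `n_samples = 10000`, and `10000`
#' null and test repetitions); the `"desk"` profile keeps the data size but
#' reduces the repetitions to 500 each for interactive work, at the cost of
#' wider Monte-Carlo error on estimated fractions and critical values.
#'
#' @param profile `"paper"` or `"desk"`.
#' @param alpha Significance level in (0, 1).
#' @param n_samples Samples per generated dataset.
#' @param n_null Null (shuffle) repetitions for critical-value estimation.
#' @param n_test Test repetitions for significance fractions.
#' @param seed Root integer seed for the whole procedure.
#' @return A `test_config` list.
#' @export
test_config <- function(profile = c("paper", "desk"), alpha = 0.01,
                        n_samples = 10000, n_null = NULL, n_test = NULL,
                        seed = 0) {
  profile <- match.arg(profile)
  reps <- if (profile == "paper") 10000 else 500
  cfg <- list(
    profile = profile, alpha = alpha, n_samples = n_samples,
    n_null = n_null %||% reps, n_test = n_test %||% reps, seed = seed
  )
  stopifnot(
    cfg$alpha > 0, cfg$alpha < 1, cfg$n_samples >= 1,
    cfg$n_null >= 1, cfg$n_test >= 1
  )
  structure(cfg, class = "test_config")
}

#' Permute a triplet along the target variable
#'
#' Uniformly permutes `z` while leaving `x` and `y` untouched, destroying
#' any source-target relation but preserving the target's marginal and the
#' source correlation structure.  Target-only shuffling is more robust than
#' permuting all three variables because measure estimators can be sensitive
#' to source correlations.
#'
#' @param data A `triplet` tibble (n >= 2).
#' @param seed Integer seed.
#' @return A `triplet` of the same kind with `z` shuffled.
#' @export
permute_target <- function(data, seed = 0) {
  n <- nrow(data)
  stopifnot(n >= 2)
  out <- data
  out$z <- with_seed(derive_seed(seed, "perm"), data$z[sample.int(n)])
  out
}

# conservative empirical upper quantile: order statistic of rank
# ceil((1 - alpha) (m + 1)), capped at m
upper_quantile_rank <- function(m, alpha) min(ceiling((1 - alpha) * (m + 1)), m)

new_critical_value <- function(value, provenance, alpha, n_draws, context = list(),
                               argmax_noise = NULL, candidates = NULL) {
  structure(
    list(
      value = value, provenance = provenance, alpha = alpha,
      n_draws = n_draws, context = context, argmax_noise = argmax_noise,
      candidates = candidates
    ),
    class = "critical_value"
  )
}

#' @export
print.critical_value <- function(x, ...) {
  cat(sprintf(
    "Critical value %.6g (%s, alpha = %g, %d draws)\n",
    x$value, x$provenance, x$alpha, x$n_draws
  ))
  if (!is.null(x$argmax_noise)) {
    cat(sprintf(
      "  adversarial noise point: p_x = %.4g, p_y = %.4g, p_z = %.4g\n",
      x$argmax_noise$p_x, x$argmax_noise$p_y, x$argmax_noise$p_z
    ))
  }
  invisible(x)
}

#' @export
#' @method tidy critical_value
tidy.critical_value <- function(x, ...) {
  tibble(
    value = x$value, provenance = x$provenance, alpha = x$alpha,
    n_draws = x$n_draws,
    p_x = x$argmax_noise$p_x %||% NA_real_,
    p_y = x$argmax_noise$p_y %||% NA_real_,
    p_z = x$argmax_noise$p_z %||% NA_real_
  )
}

#' Permutation-test critical value of an atom statistic
#'
#' Estimates the `1 - alpha` upper quantile of the shuffled-null
#' distribution of an atom.  In the default `"resample"` mode each null draw
#' generates a fresh dataset from the generator and permutes its target
#' (matching the repeated simulate-and-shuffle procedure of the sweep
#' experiments); `"fixed"` mode permutes one fixed dataset `n_null` times,
#' the classical single-dataset permutation test.
#'
#' The quantile is the conservative order statistic of rank
#' `ceiling((1 - alpha) (n_null + 1))` (capped at `n_null`).  Critical
#' values depend on noise fractions and data size, so they are re-estimated
#' for every experimental context.
#'
#' @param generator Function `f(seed)` returning a fresh `triplet`
#'   (see [triplet_generator()]); in `"fixed"` mode, a single `triplet`.
#' @param statistic Function `f(data) -> numeric(1)`
#'   (see [atom_statistic()]).
#' @param cfg A [test_config()]; `n_null`, `alpha` and `seed` are used.
#' @param mode `"resample"` (fresh dataset per draw) or `"fixed"`.
#' @return A `critical_value` with provenance `"permutation"`.
#' @export
permutation_critical_value <- function(generator, statistic, cfg = test_config(),
                                       mode = c("resample", "fixed")) {
  mode <- match.arg(mode)
  if (cfg$n_null * cfg$alpha < 5) {
    warn("n_null * alpha < 5: the upper-quantile estimate is unstable")
  }
  vals <- vapply(seq_len(cfg$n_null), function(i) {
    s <- derive_seed(cfg$seed, paste0("null:", i))
    d <- if (mode == "resample") generator(s) else generator
    suppressWarnings(statistic(permute_target(d, seed = derive_seed(s, "shuffle"))))
  }, numeric(1))
  r <- upper_quantile_rank(cfg$n_null, cfg$alpha)
  new_critical_value(
    sort(vals)[r], "permutation", cfg$alpha, cfg$n_null,
    context = list(mode = mode)
  )
}

#' Fraction of significant atoms under a critical value
#'
#' Draws `n_test` fresh datasets from the generator, computes the atom
#' statistic for each, and counts strict exceedances of the critical value.
#' The count is compared against `Binomial(n_test, alpha)` with a one-sided
#' (greater) exact test; `above_chance` flags rejection at level 0.01 —
#' i.e. the atom is declared detectable above shuffle.
#'
#' @inheritParams permutation_critical_value
#' @param cv A `critical_value` (permutation or adjusted).
#' @return A `significance_summary`; `tidy()` gives a one-row tibble with
#'   `fraction_significant`, `n_test`, `binomial_p`, `above_chance`.
#' @export
fraction_significant <- function(generator, statistic, cv, cfg = test_config()) {
  vals <- vapply(seq_len(cfg$n_test), function(i) {
    suppressWarnings(statistic(generator(derive_seed(cfg$seed, paste0("test:", i)))))
  }, numeric(1))
  count <- sum(vals > cv$value)
  bt <- binom.test(count, cfg$n_test, p = cfg$alpha, alternative = "greater")
  structure(
    list(
      fraction_significant = count / cfg$n_test, n_test = cfg$n_test,
      binomial_p = bt$p.value, above_chance = bt$p.value < 0.01,
      values = vals, cv = cv$value, alpha = cfg$alpha
    ),
    class = "significance_summary"
  )
}

#' @export
#' @method tidy significance_summary
tidy.significance_summary <- function(x, ...) {
  tibble(
    fraction_significant = x$fraction_significant, n_test = x$n_test,
    binomial_p = x$binomial_p, above_chance = x$above_chance
  )
}

#' @export
print.significance_summary <- function(x, ...) {
  cat(sprintf(
    "Fraction significant: %.3f (n_test = %d, binomial p = %.3g, %s chance level)\n",
    x$fraction_significant, x$n_test, x$binomial_p,
    if (x$above_chance) "above" else "compatible with"
  ))
  invisible(x)
}

#' Conservative significance decision
#'
#' Declares an observed atom value significant iff it strictly exceeds the
#' critical value.  When `cv` is an adjusted (adversarial) critical value,
#' rejection means rejecting every model in the composite null set — not
#' merely the shuffled-data null.
#'
#' @param atom_value Observed atom value (finite scalar).
#' @param cv A `critical_value`.
#' @return Logical.
#' @export
conservative_test <- function(atom_value, cv) {
  stopifnot(is.finite(atom_value), is.finite(cv$value))
  atom_value > cv$value
}
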