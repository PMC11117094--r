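#' Adversarial model sets for the composite null
#'
#' For a given atom, the composite (adjusted) null is the set S of
#' ground-truth models whose true value of that atom is zero; the
#' conservative critical value is maximised over S.  The default membership
#' follows the single-atom construction of the models: `mRed` carries only
#' redundancy, `mUnq` only `unq_x`, `mXOR` only synergy, and `mSum` (two
#' purely unique relations under variance partitioning) enters only the VP
#' rows because its PID ground truth is contested.
#'
#' @param measure Registry name.
#' @param atom Atom id.
#' @return Character vector of adversarial ground-truth model ids.
#' @export
#' @examples
#' adversarial_set("mmi_discrete", "syn") # mRed, mUnq - but not mXOR
adversarial_set <- function(measure, atom) {
  measure <- match.arg(measure, .measure_ids)
  atom <- match.arg(atom, .atom_ids)
  base <- switch(atom,
    unq_x = c("mRed", "mXOR"),
    unq_y = c("mRed", "mUnq", "mXOR"),
    red = c("mUnq", "mXOR"),
    syn = c("mRed", "mUnq")
  )
  if (measure == "vp" && atom %in% c("red", "syn")) base <- c(base, "mSum")
  intersect(base, legal_models(measure))
}

# Noise fractions of a 1-D search line: "diag" is p_x = p_y = p_z = nu;
# "src" is p_x = p_y = nu with a noise-free target (p_z at the floor).
line_fractions <- function(line, nu, floor = 0) {
  nu <- max(nu, floor)
  switch(line,
    diag = tibble(p_x = nu, p_y = nu, p_z = nu),
    src = tibble(p_x = nu, p_y = nu, p_z = floor),
    abort(sprintf("unknown search line '%s'", line))
  )
}

# Screen a 1-D noise line for the noise fraction maximising the atom's
# upper-quantile critical value, then refine at the argmax.
search_line <- function(statistic, model, kind, line, n_samples, alpha, seed,
                        grid_steps, n_screen, n_refine, noise_floor) {
  nus <- seq(noise_floor, 1, length.out = grid_steps)
  screen <- vapply(seq_along(nus), function(i) {
    fr <- line_fractions(line, nus[i], noise_floor)
    gen <- triplet_generator(model, kind, n_samples, fr$p_x, fr$p_y, fr$p_z)
    vals <- vapply(seq_len(n_screen), function(j) {
      suppressWarnings(statistic(gen(derive_seed(seed, sprintf("scr:%s:%d:%d", line, i, j)))))
    }, numeric(1))
    sort(vals)[upper_quantile_rank(n_screen, alpha)]
  }, numeric(1))
  i_star <- which.max(screen)
  fr <- line_fractions(line, nus[i_star], noise_floor)
  gen <- triplet_generator(model, kind, n_samples, fr$p_x, fr$p_y, fr$p_z)
  vals <- vapply(seq_len(n_refine), function(j) {
    suppressWarnings(statistic(gen(derive_seed(seed, sprintf("ref:%s:%d", line, j)))))
  }, numeric(1))
  list(
    cv = sort(vals)[upper_quantile_rank(n_refine, alpha)],
    nu = nus[i_star], fractions = fr,
    screen = tibble(nu = nus, cv_screen = screen)
  )
}

adversarial_defaults <- function(cfg) {
  if (cfg$profile == "paper") {
    list(grid_steps = 100, n_screen = 200, n_refine = 10000)
  } else {
    list(grid_steps = 25, n_screen = 100, n_refine = 1000)
  }
}

#' Adjusted critical value for a unique information atom
#'
#' Unique-atom false positives under a redundant adversarial model grow
#' without bound when the noise fractions of the two sources are allowed to
#' differ arbitrarily, so the search is restricted to the equal-noise
#' subproblem: the diagonal `p_x = p_y = p_z = nu`.  The diagonal is split
#' into `grid_steps` equispaced points; at each point the atom is resampled
#' `n_screen` times and the `1 - alpha` upper percentile recorded; the
#' argmax point is then resampled `n_refine` times for a refined critical
#' value.  For continuous data all fractions are floored at `noise_floor`
#' (default 0.01) because the differential-MI estimators diverge as noise
#' vanishes.
#'
#' @inheritParams atom_statistic
#' @param adversarial_model A ground-truth model with zero true value of the
#'   atom (typically `"mRed"`).
#' @param kind `"discrete"` or `"continuous"`.
#' @param cfg A [test_config()]; supplies `n_samples`, `alpha`, `seed`, and
#'   profile-scaled search defaults.
#' @param grid_steps,n_screen,n_refine Search resolution overrides.
#' @param noise_floor Minimum noise fraction searched (`NULL`: 0 discrete,
#'   0.01 continuous).
#' @return A `critical_value` with provenance `"adjusted"` and the argmax
#'   noise point attached.
#' @export
adversarial_cv_unique <- function(measure, atom = "unq_x", adversarial_model = "mRed",
                                  kind = "discrete", cfg = test_config(),
                                  grid_steps = NULL, n_screen = NULL, n_refine = NULL,
                                  noise_floor = NULL, k = 3, tol = 1e-9) {
  if (!atom %in% c("unq_x", "unq_y")) {
    abort("adversarial_cv_unique is for unique atoms; use adversarial_cv_red_syn")
  }
  adversarial_model <- match.arg(adversarial_model, .model_ids)
  if (!(adversarial_model %in% adversarial_set(measure, atom))) {
    abort(sprintf(
      "model '%s' has a nonzero true %s atom and cannot serve as adversarial null",
      adversarial_model, atom
    ))
  }
  kind <- match.arg(kind, .kind_ids)
  d <- adversarial_defaults(cfg)
  grid_steps <- grid_steps %||% d$grid_steps
  n_screen <- n_screen %||% d$n_screen
  n_refine <- n_refine %||% d$n_refine
  noise_floor <- noise_floor %||% if (kind == "continuous") 0.01 else 0
  statistic <- atom_statistic(measure, atom, k = k, tol = tol)
  res <- search_line(
    statistic, adversarial_model, kind, "diag", cfg$n_samples, cfg$alpha,
    derive_seed(cfg$seed, paste("adv", measure, atom, adversarial_model, kind)),
    grid_steps, n_screen, n_refine, noise_floor
  )
  new_critical_value(
    res$cv, "adjusted", cfg$alpha, n_refine,
    context = list(
      measure = measure, atom = atom, model = adversarial_model,
      kind = kind, line = "diag", n_samples = cfg$n_samples
    ),
    argmax_noise = res$fractions,
    candidates = tibble(
      model = adversarial_model, line = "diag", argmax_nu = res$nu, cv = res$cv
    )
  )
}

#' Adjusted critical value for redundancy or synergy atoms
#'
#' False-positive redundant and synergistic atoms stay bounded under noise
#' asymmetry, but their worst case can sit either on the all-equal diagonal
#' `p_x = p_y = p_z` or on the source-noise line `p_x = p_y, p_z = 0`.  Both
#' candidate lines are searched for every adversarial model (screen plus
#' refine, as in [adversarial_cv_unique()]) — always searching both lines is
#' strictly more conservative than picking one by inspecting the noise
#' dependence — and the maximum critical value over all models and lines is
#' returned.
#'
#' @inheritParams adversarial_cv_unique
#' @param adversarial_models Nonempty character vector of zero-atom models
#'   (default [adversarial_set()]).
#' @return A `critical_value` with provenance `"adjusted"`; `candidates`
#'   holds the per-model, per-line critical values.
#' @export
adversarial_cv_red_syn <- function(measure, atom, adversarial_models = NULL,
                                   kind = "discrete", cfg = test_config(),
                                   grid_steps = NULL, n_screen = NULL, n_refine = NULL,
                                   noise_floor = NULL, k = 3, tol = 1e-9) {
  if (!atom %in% c("red", "syn")) {
    abort("adversarial_cv_red_syn is for red/syn atoms; use adversarial_cv_unique")
  }
  adversarial_models <- adversarial_models %||% adversarial_set(measure, atom)
  if (length(adversarial_models) == 0) abort("the adversarial model set is empty")
  bad <- setdiff(adversarial_models, adversarial_set(measure, atom))
  if (length(bad) > 0) {
    abort(sprintf(
      "model(s) %s have a nonzero true %s atom under measure '%s'",
      paste(bad, collapse = ", "), atom, measure
    ))
  }
  kind <- match.arg(kind, .kind_ids)
  d <- adversarial_defaults(cfg)
  grid_steps <- grid_steps %||% d$grid_steps
  n_screen <- n_screen %||% d$n_screen
  n_refine <- n_refine %||% d$n_refine
  noise_floor <- noise_floor %||% if (kind == "continuous") 0.01 else 0
  statistic <- atom_statistic(measure, atom, k = k, tol = tol)
  cand <- purrr::map_dfr(adversarial_models, function(model) {
    purrr::map_dfr(c("diag", "src"), function(line) {
      res <- search_line(
        statistic, model, kind, line, cfg$n_samples, cfg$alpha,
        derive_seed(cfg$seed, paste("adv", measure, atom, model, kind, line)),
        grid_steps, n_screen, n_refine, noise_floor
      )
      tibble(
        model = model, line = line, argmax_nu = res$nu, cv = res$cv,
        p_x = res$fractions$p_x, p_y = res$fractions$p_y, p_z = res$fractions$p_z
      )
    })
  })
  best <- cand[which.max(cand$cv), ]
  new_critical_value(
    best$cv, "adjusted", cfg$alpha, n_refine,
    context = list(
      measure = measure, atom = atom, model = best$model, kind = kind,
      line = best$line, n_samples = cfg$n_samples
    ),
    argmax_noise = tibble(p_x = best$p_x, p_y = best$p_y, p_z = best$p_z),
    candidates = cand
  )
}

#' Adjusted critical value for any atom
#'
#' Convenience dispatcher: unique atoms search the equal-noise diagonal
#' under each adversarial model ([adversarial_cv_unique()], maximised over
#' the set), redundancy/synergy atoms search both candidate lines
#' ([adversarial_cv_red_syn()]).
#'
#' @inheritParams adversarial_cv_red_syn
#' @return A `critical_value` with provenance `"adjusted"`.
#' @export
adversarial_cv <- function(measure, atom, adversarial_models = NULL,
                           kind = "discrete", cfg = test_config(), ...) {
  if (atom %in% c("unq_x", "unq_y")) {
    adversarial_models <- adversarial_models %||% adversarial_set(measure, atom)
    cvs <- purrr::map(adversarial_models, function(m) {
      adversarial_cv_unique(measure, atom, m, kind = kind, cfg = cfg, ...)
    })
    best <- cvs[[which.max(vapply(cvs, function(v) v$value, numeric(1)))]]
    best$candidates <- purrr::map_dfr(cvs, function(v) {
      dplyr::mutate(v$candidates,
        p_x = v$argmax_noise$p_x, p_y = v$argmax_noise$p_y, p_z = v$argmax_noise$p_z
      )
    })
    best
  } else {
    adversarial_cv_red_syn(measure, atom, adversarial_models, kind = kind, cfg = cfg, ...)
  }
}
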