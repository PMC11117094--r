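#' Specify a simulation sweep
#'
#' Describes a full simulation study: which ground-truth models, variable
#' kinds, noise strategies and measures to cross, over which noise-fraction
#' and data-size grids, under which [test_config()], and whether points are
#' tested against the permutation null, the adjusted (adversarial) null, or
#' both.  The default noise grid is 0 plus 30 log-spaced points on
#' `[0.001, 1]`, matching the decades over which false positives set on.
#'
#' Validation rejects empty grids and illegal measure-model pairings (PID
#' measures never run on `mSum`).
#'
#' @param models Character vector of ground-truth model ids.
#' @param kinds Character vector of variable kinds.
#' @param strategies Character vector of noise strategies.
#' @param measures Character vector of measure registry names.
#' @param noise_grid Numeric vector of noise fractions in `[0, 1]`.
#' @param size_grid Integer vector of data sizes (default 100 to 10000).
#' @param cfg A [test_config()].
#' @param mode `"permutation"`, `"adjusted"`, or `"both"`.
#' @return A validated `sweep_spec` list.
#' @export
sweep_spec <- function(models = "mRed", kinds = "discrete", strategies = "Noisy",
                       measures = "pcorr", noise_grid = default_noise_grid(),
                       size_grid = c(100, 300, 1000, 3000, 10000),
                       cfg = test_config(), mode = c("permutation", "adjusted", "both")) {
  mode <- match.arg(mode)
  models <- vapply(models, match.arg, "", choices = .model_ids)
  kinds <- vapply(kinds, match.arg, "", choices = .kind_ids)
  strategies <- vapply(strategies, match.arg, "", choices = .strategy_ids)
  measures <- vapply(measures, match.arg, "", choices = .measure_ids)
  if (length(noise_grid) == 0 || length(size_grid) == 0) abort("grids must be nonempty")
  if (any(noise_grid < 0 | noise_grid > 1)) abort("noise grid must lie in [0, 1]")
  if (any(size_grid < 1)) abort("size grid must be positive")
  illegal <- purrr::map_dfr(measures, function(m) {
    bad <- setdiff(models, legal_models(m))
    if (length(bad)) tibble(measure = m, model = bad) else tibble()
  })
  if (nrow(illegal) > 0) {
    abort(sprintf(
      "illegal measure-model pairs: %s",
      paste(sprintf("%s x %s", illegal$measure, illegal$model), collapse = ", ")
    ))
  }
  reg <- measure_registry()
  for (m in measures) {
    for (kd in kinds) {
      if (!any(reg$measure == m & reg$kind == kd)) {
        abort(sprintf("measure '%s' does not support kind '%s'", m, kd))
      }
    }
  }
  structure(
    list(
      models = unname(models), kinds = unname(kinds),
      strategies = unname(strategies), measures = unname(measures),
      noise_grid = sort(unique(noise_grid)), size_grid = sort(unique(size_grid)),
      cfg = cfg, mode = mode
    ),
    class = "sweep_spec"
  )
}

#' @rdname sweep_spec
#' @export
default_noise_grid <- function() {
  c(0, 10^seq(log10(0.001), 0, length.out = 30))
}

# all atoms of all measures in the spec, restricted to one kind
spec_measure_atoms <- function(spec, kind) {
  reg <- measure_registry()
  reg[reg$measure %in% spec$measures & reg$kind == kind, c("measure", "atom")]
}

# matrix of atom draws: n_draws x atoms, one fresh dataset per row
draw_atom_matrix <- function(gen, measure, n_draws, seed, permute = FALSE) {
  one <- function(i) {
    d <- gen(derive_seed(seed, paste0(if (permute) "null:" else "test:", i)))
    if (permute) d <- permute_target(d, seed = derive_seed(seed, paste0("shuf:", i)))
    res <- suppressWarnings(compute_atoms(d, measure))
    setNames(res$value, res$atom)
  }
  do.call(rbind, lapply(seq_len(n_draws), one))
}

# continuous information-theoretic estimates diverge at zero noise, so the
# continuous MMI measure floors every noise fraction at 1%
effective_fractions <- function(fr, measure, kind) {
  if (measure == "mmi_continuous" && kind == "continuous") {
    fr$p_x <- max(fr$p_x, 0.01); fr$p_y <- max(fr$p_y, 0.01); fr$p_z <- max(fr$p_z, 0.01)
  }
  fr
}

sweep_point <- function(model, kind, strategy, nu, n, measure, cfg, mode,
                        cv_adj_value, point_seed) {
  fr <- effective_fractions(strategy_to_fractions(strategy, nu), measure, kind)
  gen <- triplet_generator(model, kind, n, fr$p_x, fr$p_y, fr$p_z)
  out <- tryCatch(
    {
      atoms <- colnames(draw_atom_matrix(gen, measure, 1, point_seed))
      nulls <- if (mode %in% c("permutation", "both")) {
        draw_atom_matrix(gen, measure, cfg$n_null, derive_seed(point_seed, "nulls"),
          permute = TRUE
        )
      }
      tests <- draw_atom_matrix(gen, measure, cfg$n_test, derive_seed(point_seed, "tests"))
      r <- upper_quantile_rank(cfg$n_null, cfg$alpha)
      purrr::map_dfr(atoms, function(at) {
        vals <- tests[, at]
        cv_p <- if (!is.null(nulls)) sort(nulls[, at])[r] else NA_real_
        fs_p <- if (!is.null(nulls)) mean(vals > cv_p) else NA_real_
        bp <- if (!is.null(nulls)) {
          binom.test(sum(vals > cv_p), length(vals), cfg$alpha, "greater")$p.value
        } else {
          NA_real_
        }
        cv_a <- cv_adj_value[[at]] %||% NA_real_
        tibble(
          atom = at,
          atom_mean = mean(vals),
          atom_q01 = unname(quantile(vals, 0.01, type = 1)),
          atom_q99 = unname(quantile(vals, 0.99, type = 1)),
          cv_perm = cv_p, cv_adj = cv_a,
          fraction_sig_perm = fs_p,
          fraction_sig_adj = if (is.na(cv_a)) NA_real_ else mean(vals > cv_a),
          binomial_p = bp, status = "ok"
        )
      })
    },
    error = function(e) {
      tibble(
        atom = NA_character_, atom_mean = NA_real_, atom_q01 = NA_real_,
        atom_q99 = NA_real_, cv_perm = NA_real_, cv_adj = NA_real_,
        fraction_sig_perm = NA_real_, fraction_sig_adj = NA_real_,
        binomial_p = NA_real_, status = conditionMessage(e)
      )
    }
  )
  dplyr::mutate(out,
    model = model, kind = kind, strategy = strategy, nu = nu,
    p_x = fr$p_x, p_y = fr$p_y, p_z = fr$p_z, n = n, measure = measure,
    seed = point_seed, .before = 1
  )
}

# adjusted CVs for every (measure, atom) of the spec at data size n
adjusted_cv_table <- function(spec, kind, n) {
  cfg <- spec$cfg
  cfg$n_samples <- n
  ma <- spec_measure_atoms(spec, kind)
  purrr::map2(ma$measure, ma$atom, function(m, at) {
    adversarial_cv(m, at, kind = kind, cfg = cfg)$value
  }) |>
    setNames(paste(ma$measure, ma$atom, sep = ":"))
}

run_sweep_grid <- function(spec, grid, out_file = NULL) {
  rows <- list()
  for (kind in spec$kinds) {
    # adjusted CVs are re-estimated per data size (they shrink slowly with n)
    cv_cache <- list()
    for (g in seq_len(nrow(grid))) {
      nu <- grid$nu[g]; n <- grid$n[g]
      if (spec$mode %in% c("adjusted", "both")) {
        key <- as.character(n)
        if (is.null(cv_cache[[key]])) cv_cache[[key]] <- adjusted_cv_table(spec, kind, n)
      }
      for (model in spec$models) {
        for (strategy in spec$strategies) {
          for (measure in spec$measures) {
            cv_adj_value <- if (spec$mode %in% c("adjusted", "both")) {
              ma <- spec_measure_atoms(spec, kind)
              at_ids <- ma$atom[ma$measure == measure]
              setNames(
                lapply(at_ids, function(at) {
                  cv_cache[[as.character(n)]][[paste(measure, at, sep = ":")]]
                }),
                at_ids
              )
            } else {
              list()
            }
            point_seed <- derive_seed(
              spec$cfg$seed,
              paste("pt", model, kind, strategy, signif(nu, 10), n, measure)
            )
            row <- sweep_point(
              model, kind, strategy, nu, n, measure, spec$cfg,
              spec$mode, cv_adj_value, point_seed
            )
            rows[[length(rows) + 1]] <- row
            if (!is.null(out_file)) {
              readr::write_csv(row, out_file,
                append = file.exists(out_file),
                col_names = !file.exists(out_file)
              )
            }
          }
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("triplet_sweep", class(out))
  out
}

#' Run a noise-fraction sweep
#'
#' Crosses the spec's models, kinds, strategies and measures over the noise
#' grid at fixed data size (`cfg$n_samples`), producing one tidy row per
#' grid point and atom: the atom's mean and 1%/99% quantiles over `n_test`
#' fresh datasets, the permutation and/or adjusted critical values, the
#' significant fractions against each, and the one-sided binomial p-value of
#' the permutation fraction against `alpha`.  Deterministic given the spec's
#' seed; per-point estimation failures are recorded in the `status` column
#' and the sweep continues.
#'
#' @param spec A [sweep_spec()].
#' @param out_file Optional CSV path; rows are flushed incrementally so an
#'   interrupted sweep keeps its finished points.
#' @return A `triplet_sweep` tibble.
#' @export
run_noise_sweep <- function(spec, out_file = NULL) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- tibble(nu = spec$noise_grid, n = spec$cfg$n_samples)
  run_sweep_grid(spec, grid, out_file)
}

#' Run a data-size sweep
#'
#' As [run_noise_sweep()], but varying the data size over the spec's size
#' grid at a fixed noise fraction.
#'
#' @inheritParams run_noise_sweep
#' @param nu Fixed noise fraction (default 0.25).
#' @return A `triplet_sweep` tibble.
#' @export
run_size_sweep <- function(spec, nu = 0.25, out_file = NULL) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- tibble(nu = nu, n = spec$size_grid)
  run_sweep_grid(spec, grid, out_file)
}

#' Significance sketch at one noise fraction
#'
#' Extracts the measure-by-model significance matrix at a single noise
#' fraction of a sweep: for each measure (rows) and ground-truth model
#' (columns), the fraction of significant draws of every atom, under the
#' permutation and (when available) adjusted critical values.
#'
#' @param rows A `triplet_sweep` table.
#' @param nu Noise fraction to slice at (matched within 1e-9).
#' @param kind Optional kind filter.
#' @return Tibble with columns `measure`, `model`, `kind`, `atom`,
#'   `fraction_sig_perm`, `fraction_sig_adj`.
#' @export
summarize_sketch <- function(rows, nu, kind = NULL) {
  sl <- rows[!is.na(rows$nu) & abs(rows$nu - nu) < 1e-9, ]
  if (!is.null(kind)) sl <- sl[sl$kind == kind, ]
  if (nrow(sl) == 0) {
    abort(sprintf("no sweep rows at noise fraction %g", nu))
  }
  sl |>
    dplyr::group_by(.data$measure, .data$model, .data$kind, .data$atom) |>
    dplyr::summarise(
      fraction_sig_perm = mean(.data$fraction_sig_perm),
      fraction_sig_adj = mean(.data$fraction_sig_adj),
      .groups = "drop"
    )
}

#' Conservative critical-value table
#'
#' For every legal (measure, atom, adversarial model) triple at the given
#' kind, runs the adversarial search and reports the adjusted critical value
#' with its argmax noise point; the row-wise maximum per (measure, atom) is
#' flagged `operative` — that is the conservative threshold to use against
#' real data.  Unique atoms are searched on the equal-noise diagonal only;
#' redundancy/synergy atoms on both candidate lines (the table keeps the
#' better line per model).
#'
#' @param measures Character vector of registry names.
#' @param kind `"discrete"` or `"continuous"`.
#' @param cfg A [test_config()] (`n_samples` defaults to 10000).
#' @param ... Passed to the adversarial searches (e.g. `grid_steps`).
#' @return Tibble with columns `measure`, `atom`, `kind`,
#'   `adversarial_model`, `line`, `argmax_nu`, `p_x`, `p_y`, `p_z`,
#'   `n_samples`, `alpha`, `cv`, `provenance`, `operative`.
#' @export
build_cv_table <- function(measures = .measure_ids, kind = "discrete",
                           cfg = test_config(), ...) {
  kind <- match.arg(kind, .kind_ids)
  reg <- measure_registry()
  reg <- reg[reg$measure %in% measures & reg$kind == kind, ]
  out <- purrr::map2_dfr(reg$measure, reg$atom, function(m, at) {
    models <- adversarial_set(m, at)
    purrr::map_dfr(models, function(md) {
      cvo <- if (at %in% c("unq_x", "unq_y")) {
        adversarial_cv_unique(m, at, md, kind = kind, cfg = cfg, ...)
      } else {
        adversarial_cv_red_syn(m, at, md, kind = kind, cfg = cfg, ...)
      }
      tibble(
        measure = m, atom = at, kind = kind, adversarial_model = md,
        line = cvo$context$line,
        argmax_nu = max(cvo$argmax_noise$p_x, cvo$argmax_noise$p_z),
        p_x = cvo$argmax_noise$p_x, p_y = cvo$argmax_noise$p_y,
        p_z = cvo$argmax_noise$p_z,
        n_samples = cfg$n_samples, alpha = cfg$alpha, cv = cvo$value,
        provenance = cvo$provenance
      )
    })
  })
  out |>
    dplyr::group_by(.data$measure, .data$atom) |>
    dplyr::mutate(operative = .data$cv == max(.data$cv)) |>
    dplyr::ungroup()
}
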