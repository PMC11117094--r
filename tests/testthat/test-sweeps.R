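desk_cfg <- function(seed = 1, n_samples = 500) {
  test_config("desk", n_samples = n_samples, n_null = 40, n_test = 40, seed = seed)
}

test_that("sweep specs validate grids and measure-model pairings", {
  expect_error(sweep_spec(noise_grid = numeric(0)), "nonempty")
  expect_error(sweep_spec(noise_grid = c(0.5, 2)), "\\[0, 1\\]")
  expect_error(sweep_spec(models = "mSum", measures = "broja"), "illegal")
  expect_error(sweep_spec(models = "mSum", measures = "mmi_discrete"), "illegal")
  expect_error(sweep_spec(measures = "mmi_continuous", kinds = "discrete"), "kind")
  expect_silent(sweep_spec(models = "mSum", measures = "vp"))
  expect_equal(length(default_noise_grid()), 31)
})

test_that("noise sweeps emit one validated row per point and atom, deterministically", {
  spec <- sweep_spec(
    models = "mUnq", kinds = "discrete", strategies = "PureSrc",
    measures = "vp", noise_grid = seq(0, 0.8, length.out = 5),
    cfg = desk_cfg(seed = 11)
  )
  rows <- suppressWarnings(run_noise_sweep(spec))
  expect_equal(nrow(rows), 5 * 4) # 5 grid points x 4 vp atoms
  expect_true(all(c(
    "model", "kind", "strategy", "nu", "p_x", "p_y", "p_z", "n", "measure",
    "atom", "atom_mean", "atom_q01", "atom_q99", "cv_perm", "cv_adj",
    "fraction_sig_perm", "fraction_sig_adj", "binomial_p", "seed", "status"
  ) %in% names(rows)))
  ok <- rows[rows$status == "ok", ]
  expect_true(all(ok$fraction_sig_perm >= 0 & ok$fraction_sig_perm <= 1))
  expect_true(all(ok$atom_q01 <= ok$atom_q99))
  expect_true(all(ok$binomial_p >= 0 & ok$binomial_p <= 1))

  rows2 <- suppressWarnings(run_noise_sweep(spec))
  expect_identical(rows, rows2)

  # incremental flush keeps finished rows on disk
  out <- withr::local_tempfile(fileext = ".csv")
  suppressWarnings(run_noise_sweep(spec, out_file = out))
  disk <- readr::read_csv(out, show_col_types = FALSE)
  expect_equal(nrow(disk), nrow(rows))
  expect_equal(disk$fraction_sig_perm, rows$fraction_sig_perm)
})

test_that("size sweeps cover the smallest data sizes with finite results", {
  spec <- sweep_spec(
    models = "mRed", kinds = "discrete", strategies = "Noisy",
    measures = "pcorr", size_grid = c(100, 400),
    cfg = desk_cfg(seed = 12)
  )
  rows <- suppressWarnings(run_size_sweep(spec, nu = 0.25))
  expect_equal(nrow(rows), 2 * 2)
  expect_true(all(rows$status == "ok"))
  expect_true(all(is.finite(rows$atom_mean)))
  expect_true(all(rows$n %in% c(100, 400)))
  # permutation CV shrinks with data size while the biased atom persists
  cv100 <- mean(rows$cv_perm[rows$n == 100])
  cv400 <- mean(rows$cv_perm[rows$n == 400])
  expect_gt(cv100, cv400)
})

test_that("the sketch slice is consistent with its raw rows", {
  spec <- sweep_spec(
    models = c("mRed", "mUnq"), kinds = "discrete", strategies = "Noisy",
    measures = "pcorr", noise_grid = c(0.1, 0.25),
    cfg = desk_cfg(seed = 13, n_samples = 1000)
  )
  rows <- suppressWarnings(run_noise_sweep(spec))
  sk <- summarize_sketch(rows, 0.25)
  expect_equal(nrow(sk), 2 * 2) # 2 models x 2 pcorr atoms
  slice <- rows[rows$nu == 0.25 & rows$model == "mRed" & rows$atom == "unq_x", ]
  expect_equal(
    sk$fraction_sig_perm[sk$model == "mRed" & sk$atom == "unq_x"],
    slice$fraction_sig_perm
  )
  # the noisy copy model shows the spurious unique atoms
  expect_true(all(sk$fraction_sig_perm[sk$model == "mRed"] > 0.9))
  expect_error(summarize_sketch(rows, 0.77), "no sweep rows")
})

test_that("the conservative CV table flags one operative maximum per measure and atom", {
  tab <- build_cv_table(
    measures = c("pcorr", "vp"), kind = "discrete",
    cfg = test_config("desk", n_samples = 400, seed = 14),
    grid_steps = 5, n_screen = 30, n_refine = 100
  )
  expect_true(all(c(
    "measure", "atom", "kind", "adversarial_model", "line", "argmax_nu",
    "p_x", "p_y", "p_z", "n_samples", "alpha", "cv", "provenance", "operative"
  ) %in% names(tab)))
  counts <- dplyr::count(dplyr::filter(tab, .data$operative), .data$measure, .data$atom)
  expect_true(all(counts$n == 1))
  # pcorr rows expose only unique atoms; mSum appears only in VP rows
  expect_setequal(unique(tab$atom[tab$measure == "pcorr"]), c("unq_x", "unq_y"))
  expect_false(any(tab$adversarial_model == "mSum" & tab$measure != "vp"))
  expect_true(any(tab$adversarial_model == "mSum" & tab$measure == "vp"))
  expect_true(all(tab$provenance == "adjusted"))
})

test_that("sweep and atom plots build without evaluation errors", {
  spec <- sweep_spec(
    models = "mUnq", kinds = "discrete", strategies = "PureSrc",
    measures = "vp", noise_grid = c(0.1, 0.3),
    cfg = desk_cfg(seed = 15)
  )
  rows <- suppressWarnings(run_noise_sweep(spec))
  p1 <- ggplot2::ggplot_build(autoplot(rows))
  expect_s3_class(p1$plot, "ggplot")
  p2 <- ggplot2::ggplot_build(plot_sketch(summarize_sketch(rows, 0.3)))
  expect_s3_class(p2$plot, "ggplot")
  p3 <- ggplot2::ggplot_build(autoplot(mmi_pid_discrete(exact_pmf("mXOR"))))
  expect_s3_class(p3$plot, "ggplot")
  p4 <- ggplot2::ggplot_build(autoplot(vp_atoms(sample_ground_truth("mSum", "continuous", 100, 1))))
  expect_s3_class(p4$plot, "ggplot")
})

test_that("the command-line front end simulates and measures a triplet", {
  cli <- system.file("cli", "tripartite.R", package = "tripartite")
  out_dir <- withr::local_tempdir()
  # the spawned Rscript must see the same library paths as this session
  withr::local_envvar(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep))
  res <- system2("Rscript", c(
    cli, "simulate", "--model", "mXOR", "--kind", "discrete",
    "--strategy", "PureSrc", "--nu", "0.1", "--n", "200", "--seed", "7",
    "--out-dir", out_dir
  ), stdout = TRUE, stderr = TRUE)
  csv <- file.path(out_dir, "triplet_mXOR_PureSrc_0.1.csv")
  expect_true(file.exists(csv))
  expect_true(file.exists(paste0(csv, ".json")))
  d <- read_triplet(csv)
  expect_equal(nrow(d), 200)
  res2 <- system2("Rscript", c(
    cli, "measure", "--in", csv, "--measure", "mmi_discrete",
    "--out-dir", out_dir
  ), stdout = TRUE, stderr = TRUE)
  atoms <- readr::read_csv(file.path(out_dir, "atoms_mmi_discrete.csv"),
    show_col_types = FALSE
  )
  expect_setequal(atoms$atom, c("unq_x", "unq_y", "red", "syn"))
  expect_true(file.exists(file.path(out_dir, "run-manifest.json")))
})
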