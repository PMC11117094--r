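test_that("target permutation preserves the z multiset and the sources", {
  d <- sample_ground_truth("mUnq", "discrete", 1000, seed = 1)
  p <- permute_target(d, seed = 2)
  expect_identical(sort(p$z), sort(d$z))
  expect_identical(p$x, d$x)
  expect_identical(p$y, d$y)
  expect_identical(permute_target(d, seed = 2), p) # deterministic

  big <- sample_ground_truth("mUnq", "continuous", 10000, seed = 3)
  pb <- permute_target(big, seed = 4)
  expect_lt(abs(cor(pb$x, pb$z)), 3 / sqrt(10000))
})

test_that("permutation critical value is the conservative upper order statistic", {
  # degenerate null: a constant statistic pins the critical value
  gen_const <- function(seed) {
    as_triplet(data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1), z = c(1, 1, 1, 1)), "discrete")
  }
  cv <- suppressWarnings(permutation_critical_value(
    gen_const, function(d) 0.7,
    test_config("desk", n_null = 50, seed = 1)
  ))
  expect_equal(cv$value, 0.7)
  expect_identical(cv$provenance, "permutation")

  # i.i.d. uniform(0, 1) null: the 1% upper quantile sits near 0.99.
  # Each draw carries its value in a constant z column, so the statistic is
  # deterministic and survives the shuffle untouched.
  gen_unif <- function(seed) {
    u <- withr::with_seed(seed, runif(1))
    as_triplet(data.frame(x = rnorm(3), y = rnorm(3), z = rep(u, 3)), "continuous")
  }
  cvu <- permutation_critical_value(
    gen_unif, function(d) d$z[1],
    test_config("paper", n_null = 10000, seed = 2)
  )
  expect_equal(cvu$value, 0.99, tolerance = 0.005)

  # monotone in alpha: stricter level, larger critical value
  cv_strict <- permutation_critical_value(
    gen_unif, function(d) d$z[1],
    test_config("paper", n_null = 2000, alpha = 0.005, seed = 3)
  )
  cv_loose <- suppressWarnings(permutation_critical_value(
    gen_unif, function(d) d$z[1],
    test_config("paper", n_null = 2000, alpha = 0.05, seed = 3)
  ))
  expect_gte(cv_strict$value, cv_loose$value)

  expect_warning(
    permutation_critical_value(gen_unif, function(d) d$z[1],
      test_config("desk", n_null = 100, seed = 4)),
    "unstable"
  )
})

test_that("significance fractions are counted strictly and tested binomially", {
  gen <- triplet_generator("mUnq", "discrete", 300)
  st <- atom_statistic("pcorr", "unq_x")
  cfg <- test_config("desk", n_null = 60, n_test = 60, seed = 5)

  # a huge critical value silences everything
  high <- suppressWarnings(permutation_critical_value(gen, st, cfg))
  high$value <- 2
  fs <- fraction_significant(gen, st, high, cfg)
  expect_equal(fs$fraction_significant, 0)
  expect_false(fs$above_chance)

  # strict exceedance: equality is not significant
  expect_false(conservative_test(0.5, high))
  expect_false(conservative_test(2, high))
  expect_true(conservative_test(2.0001, high))

  # a true unique relation is detected essentially always
  cv <- suppressWarnings(permutation_critical_value(gen, st, cfg))
  fs2 <- fraction_significant(gen, st, cv, cfg)
  expect_gt(fs2$fraction_significant, 0.9)
  expect_true(fs2$above_chance)

  # reproducibility, bit for bit
  cv_b <- suppressWarnings(permutation_critical_value(gen, st, cfg))
  fs_b <- fraction_significant(gen, st, cv_b, cfg)
  expect_identical(cv$value, cv_b$value)
  expect_identical(fs2$values, fs_b$values)
})

test_that("the permutation test is calibrated under independent triplets", {
  # independent triplet generator: full switching noise on a copy model
  gen <- triplet_generator("mRed", "discrete", 1000, 1, 1, 1)
  cfg <- test_config("desk", n_null = 300, n_test = 300, seed = 6)
  for (ms in c("pcorr", "vp")) {
    for (at in if (ms == "pcorr") "unq_x" else c("red", "syn")) {
      st <- atom_statistic(ms, at)
      cv <- suppressWarnings(permutation_critical_value(gen, st, cfg))
      fs <- fraction_significant(gen, st, cv, cfg)
      # compatible with alpha: within 3 binomial standard errors
      expect_lte(
        fs$fraction_significant,
        cfg$alpha + 3 * sqrt(cfg$alpha * (1 - cfg$alpha) / cfg$n_test)
      )
    }
  }
})

test_that("adversarial searches return diagonal argmax points and dominate the shuffle null", {
  cfg <- test_config("desk", n_samples = 2000, seed = 7)
  cv <- adversarial_cv_unique("pcorr", "unq_x", "mRed", "discrete", cfg,
    grid_steps = 10, n_screen = 50, n_refine = 300
  )
  expect_identical(cv$provenance, "adjusted")
  expect_equal(cv$argmax_noise$p_x, cv$argmax_noise$p_y)
  expect_equal(cv$argmax_noise$p_x, cv$argmax_noise$p_z)

  # noise-induced bias: the adjusted CV clears the zero-noise critical value
  gen0 <- triplet_generator("mRed", "discrete", 2000, 0, 0, 0)
  st <- atom_statistic("pcorr", "unq_x")
  cv0 <- suppressWarnings(permutation_critical_value(
    gen0, st, test_config("desk", n_null = 300, seed = 8)
  ))
  expect_gt(cv$value, cv0$value)

  # ... and dominates the permutation null under the adversarial model itself
  # (majority over three independent runs)
  wins <- sum(vapply(1:3, function(r) {
    genA <- triplet_generator(
      "mRed", "discrete", 2000,
      cv$argmax_noise$p_x, cv$argmax_noise$p_y, cv$argmax_noise$p_z
    )
    cvp <- suppressWarnings(permutation_critical_value(
      genA, st, test_config("desk", n_null = 300, seed = 100 + r)
    ))
    cv$value >= cvp$value
  }, logical(1)))
  expect_gte(wins, 2)

  expect_error(
    adversarial_cv_unique("pcorr", "unq_x", "mUnq", "discrete", cfg),
    "nonzero true"
  )
  expect_error(
    adversarial_cv_unique("pcorr", "red", "mRed", "discrete", cfg),
    "unique"
  )
})

test_that("red/syn adversarial CV is the maximum over models and both search lines", {
  cfg <- test_config("desk", n_samples = 1000, seed = 9)
  full <- adversarial_cv_red_syn("vp", "red",
    kind = "discrete", cfg = cfg,
    grid_steps = 6, n_screen = 40, n_refine = 200
  )
  expect_setequal(unique(full$candidates$model), adversarial_set("vp", "red"))
  expect_setequal(unique(full$candidates$line), c("diag", "src"))
  expect_equal(full$value, max(full$candidates$cv))

  # per-model searches with the same seeds reproduce the same maximum
  per <- vapply(adversarial_set("vp", "red"), function(m) {
    adversarial_cv_red_syn("vp", "red", m,
      kind = "discrete", cfg = cfg,
      grid_steps = 6, n_screen = 40, n_refine = 200
    )$value
  }, numeric(1))
  expect_equal(full$value, max(per))

  expect_error(
    adversarial_cv_red_syn("vp", "syn", "mXOR", kind = "discrete", cfg = cfg),
    "nonzero true"
  )
  expect_error(
    adversarial_cv_red_syn("vp", "syn", character(0), kind = "discrete", cfg = cfg),
    "empty"
  )
})

test_that("the adversarial-set registry follows the single-atom model design", {
  expect_setequal(adversarial_set("mmi_discrete", "syn"), c("mRed", "mUnq"))
  expect_setequal(adversarial_set("broja", "red"), c("mUnq", "mXOR"))
  expect_setequal(adversarial_set("vp", "red"), c("mUnq", "mXOR", "mSum"))
  expect_setequal(adversarial_set("vp", "syn"), c("mRed", "mUnq", "mSum"))
  # mSum is VP-only
  expect_false("mSum" %in% adversarial_set("mmi_continuous", "syn"))
  expect_setequal(adversarial_set("pcorr", "unq_x"), c("mRed", "mXOR"))
})
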