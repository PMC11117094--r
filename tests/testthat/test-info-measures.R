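test_that("empirical pmf tabulates on the declared alphabet and normalises", {
  d <- as_triplet(data.frame(x = rep(0, 9), y = rep(0, 9), z = rep(0, 9)),
    "discrete",
    alphabet = c(2, 2, 2)
  )
  p <- empirical_pmf(d)
  expect_equal(p$table[1, 1, 1], 1)
  expect_equal(sum(p$table), 1)

  # balanced XOR-consistent states -> four cells of 1/4
  xs <- c(0, 0, 1, 1)
  ys <- c(0, 1, 0, 1)
  d2 <- as_triplet(
    data.frame(x = rep(xs, 25), y = rep(ys, 25), z = rep(as.numeric(xs != ys), 25)),
    "discrete"
  )
  p2 <- empirical_pmf(d2)
  expect_equal(sort(as.numeric(p2$table)), c(rep(0, 4), rep(0.25, 4)))

  cont <- sample_ground_truth("mUnq", "continuous", 10, seed = 1)
  expect_error(empirical_pmf(cont), "discrete")
})

test_that("exact pmf matches hand-enumerated laws and the empirical pmf converges to it", {
  xo <- exact_pmf("mXOR")
  consistent <- c(xo$table[1, 1, 1], xo$table[1, 2, 2], xo$table[2, 1, 2], xo$table[2, 2, 1])
  expect_equal(consistent, rep(0.25, 4))
  expect_equal(sum(xo$table), 1)

  rd <- exact_pmf("mRed")
  expect_equal(rd$table[1, 1, 1], 0.5)
  expect_equal(rd$table[2, 2, 2], 0.5)

  expect_equal(as.numeric(exact_pmf("mRed", 1, 1, 1)$table), rep(1 / 8, 8))

  # total-variation convergence of the empirical pmf, three model/noise points
  cases <- list(
    list("mRed", c(0.25, 0.25, 0.25)), list("mXOR", c(0.1, 0.1, 0.1)),
    list("mSum", c(0, 0, 0.3))
  )
  for (cs in cases) {
    ex <- exact_pmf(cs[[1]], cs[[2]][1], cs[[2]][2], cs[[2]][3])
    gen <- triplet_generator(cs[[1]], "discrete", 10000, cs[[2]][1], cs[[2]][2], cs[[2]][3])
    em <- empirical_pmf(gen(99))
    expect_lte(0.5 * sum(abs(ex$table - em$table)), 0.02)
  }
})

test_that("Shannon mutual information matches direct evaluation", {
  unif <- joint_pmf(array(1 / 8, c(2, 2, 2)))
  expect_equal(shannon_mi(unif, "x"), 0)
  expect_equal(shannon_mi(unif, "xy"), 0)

  rd <- exact_pmf("mRed")
  expect_equal(shannon_mi(rd, "x"), 1)
  expect_equal(shannon_mi(rd, "xy"), 1)

  xo <- exact_pmf("mXOR")
  expect_equal(shannon_mi(xo, "x"), 0)
  expect_equal(shannon_mi(xo, "xy"), 1) # H(Z) = 1, H(Z | X, Y) = 0
})

test_that("pmf JSON serialisation round trips", {
  p <- exact_pmf("mSum", 0.1, 0.2, 0.3)
  q <- pmf_from_json(pmf_to_json(p))
  expect_equal(q$table, p$table)
  expect_identical(q$alphabet, c(2L, 2L, 3L))
})

test_that("discrete MMI atoms conserve total information and synergy stays nonnegative on exact laws", {
  withr::with_seed(123, {
    for (i in 1:20) {
      p <- random_pmf_222(sparse = i %% 3 == 0)
      a <- mmi_pid_discrete(p)
      expect_equal(sum(a$atoms), a$total_mi, tolerance = 1e-9)
      # I(XY:Z) >= max(I(X:Z), I(Y:Z)) makes MMI synergy nonnegative
      expect_gte(a$atoms[["syn"]], -1e-12)
      expect_gte(a$atoms[["red"]], -1e-12)
    }
  })
})

test_that("BROJA agrees with the brute-force polytope oracle and with MMI on corner models", {
  # AND gate: frozen oracle values 0/0/0.311/0.5 bits
  and_tab <- array(0, c(2, 2, 2))
  and_tab[1, 1, 1] <- and_tab[1, 2, 1] <- and_tab[2, 1, 1] <- and_tab[2, 2, 2] <- 0.25
  a <- broja_pid_discrete(joint_pmf(and_tab))
  expect_equal(a$atoms[["unq_x"]], 0, tolerance = 1e-3)
  expect_equal(a$atoms[["unq_y"]], 0, tolerance = 1e-3)
  expect_equal(a$atoms[["red"]], 0.3112781, tolerance = 1e-3)
  expect_equal(a$atoms[["syn"]], 0.5, tolerance = 1e-3)

  withr::with_seed(7, {
    for (i in 1:6) {
      p <- random_pmf_222(sparse = i > 4)
      got <- broja_pid_discrete(p)
      want <- oracle_broja_222(p$table)
      for (at in c("unq_x", "unq_y", "red", "syn")) {
        expect_equal(got$atoms[[at]], want[[at]], tolerance = 1e-3)
      }
      expect_equal(sum(got$atoms), got$total_mi, tolerance = 1e-9)
    }
  })

  # noiseless corner models: BROJA and MMI coincide exactly
  for (m in c("mXOR", "mRed", "mUnq")) {
    b <- broja_pid_discrete(exact_pmf(m))
    mm <- mmi_pid_discrete(exact_pmf(m))
    expect_equal(unname(b$atoms), unname(mm$atoms), tolerance = 1e-9)
  }

  # zero-information law
  delta <- array(0, c(2, 2, 2))
  delta[1, 1, 1] <- 1
  d <- broja_pid_discrete(joint_pmf(delta))
  expect_equal(unname(d$atoms), rep(0, 4), tolerance = 1e-12)
})

test_that("KSG estimator matches the Gaussian closed form and is symmetric", {
  n <- 5000
  rho <- 0.8
  xy <- withr::with_seed(20, {
    x <- rnorm(n)
    list(x = x, y = rho * x + sqrt(1 - rho^2) * rnorm(n))
  })
  want <- -0.5 * log2(1 - rho^2) # 0.737 bits
  got <- ksg_mi(xy$x, xy$y, k = 3)
  expect_equal(got, want, tolerance = 0.05)
  expect_equal(ksg_mi(xy$y, xy$x, k = 3), got, tolerance = 1e-6)

  ind <- withr::with_seed(21, list(a = rnorm(2000), b = rnorm(2000)))
  expect_lt(abs(ksg_mi(ind$a, ind$b, k = 3)), 0.03)

  expect_error(ksg_mi(rnorm(5), rnorm(5), k = 5), "smaller")
})

test_that("continuous MMI PID resolves the sign-XOR model and guards degenerate input", {
  s <- sample_ground_truth("mXOR", "continuous", 5000, seed = 30)
  # sign(Z) carries exactly 1 bit about the source signs; marginal MIs vanish.
  # The joint-space kNN bias grows with k, so the tight check uses k = 1 and
  # the default k = 3 gets a wider band.
  a1 <- mmi_pid_continuous(s, k = 1)
  expect_equal(a1$atoms[["syn"]], 1, tolerance = 0.1)
  a <- mmi_pid_continuous(s, k = 3)
  expect_equal(a$atoms[["syn"]], 1, tolerance = 0.2)
  expect_lt(abs(a$atoms[["unq_x"]]) + abs(a$atoms[["unq_y"]]), 0.1)
  expect_equal(sum(a$atoms), a$total_mi, tolerance = 1e-6)

  # unique model with 1% source noise: strongly asymmetric unique atoms
  u <- apply_noise(sample_ground_truth("mUnq", "continuous", 3000, seed = 31),
    0.01, 0.01, 0.01,
    seed = 32
  )
  au <- mmi_pid_continuous(u)
  expect_gt(au$atoms[["unq_x"]], au$atoms[["unq_y"]] + 1)
  expect_lt(abs(au$atoms[["red"]]), 0.1)

  deg <- tibble::tibble(x = rnorm(100), y = rnorm(100), z = rep(1, 100))
  expect_error(mmi_pid_continuous(as_triplet(deg, "continuous")), "noise")
  expect_error(mmi_pid_continuous(sample_ground_truth("mRed", "discrete", 100, 1)), "continuous")
})
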