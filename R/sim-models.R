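#' Triplet samples
#'
#' A triplet sample is a tibble with numeric columns `x`, `y`, `z` holding
#' aligned draws of the two source variables and the target variable, plus a
#' `kind` attribute (`"discrete"` or `"continuous"`) and, for discrete data,
#' an `alphabet` attribute with the three alphabet sizes.  All measures and
#' tests in the package consume this shape; user data can be adopted with
#' [as_triplet()].
#'
#' @param df Data frame with columns `x`, `y`, `z` (no missing values).
#' @param kind `"discrete"` (integer-coded from 0) or `"continuous"`.
#' @param alphabet Integer vector of length 3 giving the declared alphabet
#'   sizes of x, y, z.  Defaults to the observed support (`max + 1`) for
#'   discrete data; ignored for continuous data.
#' @return A `triplet` tibble.
#' @export
#' @examples
#' as_triplet(data.frame(x = c(0, 1), y = c(1, 0), z = c(1, 1)), "discrete")
as_triplet <- function(df, kind = c("continuous", "discrete"), alphabet = NULL) {
  kind <- match.arg(kind)
  if (!all(c("x", "y", "z") %in% names(df))) {
    abort("triplet data must have columns x, y, z")
  }
  out <- tibble::as_tibble(df[, c("x", "y", "z")])
  if (anyNA(out)) abort("triplet data must not contain missing values")
  if (!all(vapply(out, is.numeric, logical(1)))) {
    abort("triplet columns must be numeric")
  }
  if (kind == "discrete") {
    vals <- unlist(out)
    if (any(vals != round(vals)) || any(vals < 0)) {
      abort("discrete triplet values must be nonnegative integers coded from 0")
    }
    if (is.null(alphabet)) {
      alphabet <- vapply(out, function(v) as.integer(max(v)) + 1L, integer(1))
    }
    alphabet <- as.integer(alphabet)
    stopifnot(length(alphabet) == 3, all(alphabet >= 1))
    if (any(vapply(seq_len(3), function(i) max(out[[i]]) + 1 > alphabet[i], logical(1)))) {
      abort("observed discrete values exceed the declared alphabet")
    }
    attr(out, "alphabet") <- alphabet
  } else {
    if (!all(is.finite(unlist(out)))) abort("continuous triplet values must be finite")
  }
  attr(out, "kind") <- kind
  class(out) <- c("triplet", class(out))
  out
}

#' @export
#' @rdname as_triplet
triplet_kind <- function(df) attr(df, "kind") %||% "continuous"

#' @export
#' @rdname as_triplet
triplet_alphabet <- function(df) {
  attr(df, "alphabet") %||%
    vapply(df[, c("x", "y", "z")], function(v) as.integer(max(v)) + 1L, integer(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal fast path: simulator outputs are valid by construction, so skip
# the per-element validation of as_triplet()
new_triplet <- function(x, y, z, kind, alphabet = NULL, model = NULL) {
  out <- tibble::new_tibble(
    list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)),
    nrow = length(x)
  )
  attr(out, "kind") <- kind
  if (!is.null(alphabet)) attr(out, "alphabet") <- as.integer(alphabet)
  if (!is.null(model)) attr(out, "model") <- model
  class(out) <- c("triplet", class(out))
  out
}

#' Sample a ground-truth triplet model
#'
#' Draws `n` i.i.d. samples of the noiseless variables (X*, Y*, Z*) from one
#' of four generative models, each constructed to carry exactly one
#' information atom:
#'
#' * `mRed`  — X* = Y* = Z* (purely redundant copy model);
#' * `mUnq`  — Z* = X*, with Y* an independent distractor (purely unique);
#' * `mXOR`  — discrete: Z* = XOR(X*, Y*); continuous: the sign-XOR model
#'   Z* = |T_z| sign(X*) sign(Y*), so all marginals stay standard normal but
#'   the sign of Z* is the product of the source signs (purely synergistic);
#' * `mSum`  — Z* = X* + Y* (used for validating variance partitioning only;
#'   PID measures refuse it because its atom ground truth is contested).
#'
#' Continuous latents are independent standard normals; discrete latents are
#' independent Bernoulli(0.5).  The discrete `mSum` target takes values in
#' \{0, 1, 2\}.
#'
#' @param model One of `"mRed"`, `"mUnq"`, `"mXOR"`, `"mSum"`.
#' @param kind `"discrete"` or `"continuous"`.
#' @param n Number of samples (>= 1).
#' @param seed Integer seed; identical arguments give identical samples.
#' @return A `triplet` tibble with `n` rows.
#' @export
#' @examples
#' sample_ground_truth("mXOR", "discrete", 5, seed = 1)
sample_ground_truth <- function(model, kind, n, seed) {
  model <- match.arg(model, .model_ids)
  kind <- match.arg(kind, .kind_ids)
  stopifnot(n >= 1)
  lat <- with_seed(derive_seed(seed, "latents"), {
    if (kind == "continuous") {
      list(tx = rnorm(n), ty = rnorm(n), tz = rnorm(n))
    } else {
      list(tx = rbinom(n, 1, 0.5), ty = rbinom(n, 1, 0.5), tz = rbinom(n, 1, 0.5))
    }
  })
  x <- lat$tx
  y <- switch(model, mRed = lat$tx, lat$ty)
  z <- switch(model,
    mRed = lat$tx,
    mUnq = lat$tx,
    mXOR = if (kind == "continuous") {
      abs(lat$tz) * sign0(lat$tx) * sign0(lat$ty)
    } else {
      as.numeric(xor(lat$tx == 1, lat$ty == 1))
    },
    mSum = lat$tx + lat$ty
  )
  alphabet <- if (kind == "discrete") c(2L, 2L, if (model == "mSum") 3L else 2L)
  new_triplet(x, y, z, kind, alphabet, model)
}

# sign with sign(0) := +1 (probability-zero event for the normal latents)
sign0 <- function(v) ifelse(v >= 0, 1, -1)

#' Corrupt a ground-truth triplet into observables
#'
#' Applies the observation-noise model, per variable, with noise fractions
#' `p_x`, `p_y`, `p_z` in `[0, 1]`:
#'
#' * continuous: `X = (1 - p) X* + p nu` with `nu ~ N(0, 1)` (amplitude
#'   mixing, not variance mixing — see [nominal_noise_fraction()] for the
#'   variance-share diagnostic);
#' * discrete: each sample keeps its ground-truth value with probability
#'   `1 - p` and is replaced by an independent Bernoulli(0.5) draw otherwise
#'   (switching noise).
#'
#' The input is not modified.  `p = 0` returns the variable unchanged;
#' `p = 1` replaces it by pure noise.
#'
#' @param data A `triplet` tibble (see [as_triplet()]).
#' @param p_x,p_y,p_z Noise fractions in `[0, 1]`.
#' @param seed Integer seed (switching and noise draws use separate derived
#'   streams).
#' @return A `triplet` tibble of the same kind and size.
#' @export
#' @examples
#' gt <- sample_ground_truth("mRed", "discrete", 100, seed = 1)
#' apply_noise(gt, p_x = 0.25, p_y = 0.25, p_z = 0.25, seed = 2)
apply_noise <- function(data, p_x = 0, p_y = 0, p_z = 0, seed = 0) {
  p <- c(p_x, p_y, p_z)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("noise fractions must lie in [0, 1]")
  }
  kind <- triplet_kind(data)
  n <- nrow(data)
  out <- data
  if (kind == "continuous") {
    nu <- with_seed(derive_seed(seed, "noise"), {
      list(rnorm(n), rnorm(n), rnorm(n))
    })
    for (i in 1:3) {
      out[[i]] <- (1 - p[i]) * data[[i]] + p[i] * nu[[i]]
    }
  } else {
    sw <- with_seed(derive_seed(seed, "switch"), {
      list(rbinom(n, 1, p[1]), rbinom(n, 1, p[2]), rbinom(n, 1, p[3]))
    })
    nu <- with_seed(derive_seed(seed, "noise"), {
      list(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
    })
    for (i in 1:3) {
      v <- data[[i]]
      hit <- sw[[i]] == 1
      v[hit] <- nu[[i]][hit]
      out[[i]] <- v
    }
  }
  out
}

#' Map a single-parameter noise strategy to per-variable fractions
#'
#' The sweep experiments collapse the three per-variable noise fractions to a
#' single parameter `nu` through one of three strategies:
#' `PureSrc` (only the target is noisy: `(0, 0, nu)`),
#' `NoisyX` (primary source and target noisy: `(nu, 0, nu)`),
#' `Noisy` (all three noisy: `(nu, nu, nu)`).
#'
#' @param strategy One of `"PureSrc"`, `"NoisyX"`, `"Noisy"`.
#' @param nu Noise fraction in `[0, 1]`.
#' @return One-row tibble with columns `p_x`, `p_y`, `p_z`.
#' @export
#' @examples
#' strategy_to_fractions("PureSrc", 0.3)
strategy_to_fractions <- function(strategy, nu) {
  strategy <- match.arg(strategy, .strategy_ids)
  if (!is.finite(nu) || nu < 0 || nu > 1) abort("nu must lie in [0, 1]")
  switch(strategy,
    PureSrc = tibble(p_x = 0, p_y = 0, p_z = nu),
    NoisyX = tibble(p_x = nu, p_y = 0, p_z = nu),
    Noisy = tibble(p_x = nu, p_y = nu, p_z = nu)
  )
}

#' Variance-share noise fraction of a mixing parameter
#'
#' The continuous observable `X = (1 - p) X* + p nu` has unexplained variance
#' share `p^2 / (p^2 + (1 - p)^2)`; this diagnostic converts the amplitude
#' mixing parameter `p` into that share.  For discrete switching noise the
#' switching probability itself is the noise fraction (it equals the mean of
#' the switching variable), so `p` is returned unchanged.
#'
#' @param p Mixing parameter in `[0, 1]`.
#' @param kind `"discrete"` or `"continuous"`.
#' @return The nominal noise fraction in `[0, 1]`.
#' @export
#' @examples
#' nominal_noise_fraction(0.5, "continuous") # 0.5
#' nominal_noise_fraction(0.2, "continuous") # 0.0588...
nominal_noise_fraction <- function(p, kind = c("continuous", "discrete")) {
  kind <- match.arg(kind)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) abort("p must lie in [0, 1]")
  if (kind == "discrete") p else p^2 / (p^2 + (1 - p)^2)
}

#' Build a deterministic triplet generator
#'
#' Packages a (model, kind, n, noise) context into a function of a single
#' integer seed, the form consumed by the significance-testing routines.
#'
#' @inheritParams sample_ground_truth
#' @inheritParams apply_noise
#' @return A function `f(seed)` returning a fresh observable `triplet`.
#' @export
#' @examples
#' gen <- triplet_generator("mRed", "discrete", 500, p_x = 0.25, p_y = 0.25, p_z = 0.25)
#' head(gen(1))
triplet_generator <- function(model, kind, n, p_x = 0, p_y = 0, p_z = 0) {
  model <- match.arg(model, .model_ids)
  kind <- match.arg(kind, .kind_ids)
  force(n); force(p_x); force(p_y); force(p_z)
  function(seed) {
    gt <- sample_ground_truth(model, kind, n, seed = derive_seed(seed, "gt"))
    apply_noise(gt, p_x, p_y, p_z, seed = derive_seed(seed, "obs"))
  }
}
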