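#' Partial correlation between two variables controlling a third
#'
#' Pearson correlation between the residuals of `x` and `z` after each has
#' been fit by least squares (with intercept) on the control variable `y`.
#' `partial_correlation(y, x, z)` gives the symmetric role swap
#' PCorr(Y, Z | X).
#'
#' If either residual vector has variance below `1e-12` times the variance of
#' the corresponding raw variable (e.g. the degenerate noiseless copy model
#' where X = Y = Z), the convention value 0 is returned with a warning.
#'
#' @param x,z Numeric sample vectors whose conditional association is sought.
#' @param y Numeric control vector of the same length.
#' @return A single value in `[-1, 1]`.
#' @export
#' @examples
#' s <- sample_ground_truth("mUnq", "continuous", 1000, seed = 1)
#' partial_correlation(s$x, s$y, s$z) # ~ 1: z = x exactly, y independent
partial_correlation <- function(x, y, z) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  if (n < 4) abort("partial correlation needs at least 4 samples")
  x <- x - mean(x); y <- y - mean(y); z <- z - mean(z)
  syy <- sum(y * y)
  rx <- if (syy > 0) x - y * (sum(x * y) / syy) else x
  rz <- if (syy > 0) z - y * (sum(z * y) / syy) else z
  vx <- sum(rx * rx); vz <- sum(rz * rz)
  tol_x <- 1e-12 * max(sum(x * x), .Machine$double.eps)
  tol_z <- 1e-12 * max(sum(z * z), .Machine$double.eps)
  if (vx <= tol_x || vz <= tol_z) {
    warn("degenerate input: residual variance is (near) zero; returning 0")
    return(0)
  }
  max(-1, min(1, sum(rx * rz) / sqrt(vx * vz)))
}

#' Partial R-squared of nested least-squares models
#'
#' Difference between the residual sum of squares of a reduced model and of
#' the full model containing it.  For genuinely nested least-squares fits the
#' difference is nonnegative; rounding-scale negatives are clipped to zero.
#'
#' @param ssr_reduced,ssr_full Nonnegative residual sums of squares.
#' @return `max(ssr_reduced - ssr_full, 0)`.
#' @export
pr_squared <- function(ssr_reduced, ssr_full) {
  if (!is.finite(ssr_reduced) || !is.finite(ssr_full) ||
    ssr_reduced < 0 || ssr_full < 0) {
    abort("residual sums of squares must be finite and nonnegative")
  }
  max(ssr_reduced - ssr_full, 0)
}

# SSR of z on the design columns in `m` (already centered), by minimum-norm
# least squares from the cross-moment matrix; robust to collinear designs.
ssr_subset <- function(G, zz, idx) {
  if (length(idx) == 0) return(zz)
  M <- G[idx, idx, drop = FALSE]
  cvec <- G[idx, 4]
  s <- svd(M)
  pos <- s$d > max(s$d[1], 0) * 1e-12
  if (!any(pos)) return(zz)
  beta <- s$v[, pos, drop = FALSE] %*% ((t(s$u[, pos, drop = FALSE]) %*% cvec) / s$d[pos])
  max(zz - sum(cvec * beta), 0)
}

#' Variance partitioning of a quadratic interaction model
#'
#' Decomposes the explained sum of squares of the centered quadratic model
#' `Z ~ aX + bY + cXY` into four atoms via partial R-squared:
#'
#' * `unq_x` — explained variance lost when the `aX` term is dropped;
#' * `unq_y` — likewise for `bY`;
#' * `syn`   — likewise for the interaction term `cXY`;
#' * `red`   — the classical commonality of the two linear predictors,
#'   `SST - SSR(X) - SSR(Y) + SSR(X, Y)`.
#'
#' All four are normalised by the total sum of squares of Z, giving
#' dimensionless values.  Variables (including the product column) are
#' centered before fitting; reduced models are re-fit from scratch; collinear
#' designs are handled by minimum-norm least squares.  Unique and synergy
#' atoms are nonnegative by model nesting; the redundancy commonality can be
#' genuinely negative in-sample (suppression) and only rounding-scale
#' negatives (below `1e-12` of SST) are clipped.
#'
#' @param data A data frame with columns `x`, `y`, `z` (e.g. a `triplet`).
#' @return A `vp_fit` object; use [tidy()] for a tibble of atoms and
#'   [glance()] for a one-row summary.
#' @export
#' @examples
#' s <- sample_ground_truth("mSum", "continuous", 2000, seed = 1)
#' tidy(vp_atoms(s)) # unq_x and unq_y each ~ 0.5
vp_atoms <- function(data) {
  x <- data$x; y <- data$y; z <- data$z
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  if (n < 6) abort("variance partitioning needs at least 6 samples")
  x <- x - mean(x); y <- y - mean(y); z <- z - mean(z)
  w <- x * y; w <- w - mean(w)
  D <- cbind(x, y, w, z)
  G <- crossprod(D)
  sst <- G[4, 4]
  if (sst <= 1e-12 * max(1, sum(data$z^2))) {
    warn("degenerate input: target has (near) zero variance; all atoms 0")
    atoms <- setNames(rep(0, 4), .atom_ids)
    return(new_vp_fit(atoms, sst, c(a = NA_real_, b = NA_real_, c = NA_real_), n))
  }
  ssr_full <- ssr_subset(G, sst, 1:3)
  ssr_no_a <- ssr_subset(G, sst, 2:3)
  ssr_no_b <- ssr_subset(G, sst, c(1, 3))
  ssr_no_c <- ssr_subset(G, sst, 1:2)
  ssr_x <- ssr_subset(G, sst, 1)
  ssr_y <- ssr_subset(G, sst, 2)
  ssr_xy <- ssr_subset(G, sst, 1:2)
  red_raw <- sst - ssr_x - ssr_y + ssr_xy
  atoms <- c(
    unq_x = pr_squared(ssr_no_a, ssr_full),
    unq_y = pr_squared(ssr_no_b, ssr_full),
    red = red_raw,
    syn = pr_squared(ssr_no_c, ssr_full)
  ) / sst
  clip <- abs(atoms) < 1e-12
  atoms[clip] <- 0
  # full-model coefficients (minimum-norm under collinearity)
  s <- svd(G[1:3, 1:3])
  pos <- s$d > max(s$d[1], 0) * 1e-12
  beta <- if (any(pos)) {
    drop(s$v[, pos, drop = FALSE] %*% ((t(s$u[, pos, drop = FALSE]) %*% G[1:3, 4]) / s$d[pos]))
  } else {
    rep(0, 3)
  }
  new_vp_fit(atoms, sst, setNames(beta, c("a", "b", "c")), n)
}

new_vp_fit <- function(atoms, sst, coefs, n) {
  structure(
    list(atoms = atoms, sst = sst, coefficients = coefs, n = n),
    class = "vp_fit"
  )
}

#' @export
#' @method tidy vp_fit
tidy.vp_fit <- function(x, ...) {
  tibble(atom = .atom_ids, value = unname(x$atoms[.atom_ids]))
}

#' @export
#' @method glance vp_fit
glance.vp_fit <- function(x, ...) {
  tibble(
    unq_x = x$atoms[["unq_x"]], unq_y = x$atoms[["unq_y"]],
    red = x$atoms[["red"]], syn = x$atoms[["syn"]],
    sst = x$sst, a = x$coefficients[["a"]], b = x$coefficients[["b"]],
    c = x$coefficients[["c"]], n = x$n
  )
}

#' @export
print.vp_fit <- function(x, ...) {
  cat("Variance partitioning (quadratic interaction model), n =", x$n, "\n")
  cat(sprintf(
    "  unq_x = %.4f  unq_y = %.4f  red = %.4f  syn = %.4f  (SST = %.4g)\n",
    x$atoms[["unq_x"]], x$atoms[["unq_y"]], x$atoms[["red"]], x$atoms[["syn"]], x$sst
  ))
  invisible(x)
}

#' Partial-correlation atoms of a triplet
#'
#' Evaluates both directed partial correlations of a triplet: `unq_x` is
#' PCorr(X, Z | Y) and `unq_y` is PCorr(Y, Z | X).  Partial correlation
#' conflates unique and synergistic association, so only these two unique
#' atoms are exposed; redundancy and synergy are not defined for it.
#'
#' @param data A data frame with columns `x`, `y`, `z`.
#' @return Tibble with columns `atom`, `value` (signed partial correlations).
#' @export
pcorr_atoms <- function(data) {
  tibble(
    atom = c("unq_x", "unq_y"),
    value = c(
      partial_correlation(data$x, data$y, data$z),
      partial_correlation(data$y, data$x, data$z)
    )
  )
}
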