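#' Partial information decomposition results
#'
#' All PID estimators return a `pid_atoms` object holding the four
#' information atoms in bits — `unq_x` = U(X -> Z | Y), `unq_y` =
#' U(Y -> Z | X), `red` = R(X : Y -> Z), `syn` = S(X : Y -> Z) — together
#' with the total mutual information `I(X, Y : Z)` they sum to, and the name
#' of the estimator.  Use [tidy()] / [glance()] for tibble views.
#'
#' @name pid_atoms
NULL

new_pid_atoms <- function(atoms, total_mi, estimator, details = list()) {
  structure(
    list(
      atoms = atoms[.atom_ids], total_mi = total_mi,
      estimator = estimator, details = details
    ),
    class = "pid_atoms"
  )
}

#' @export
#' @method tidy pid_atoms
tidy.pid_atoms <- function(x, ...) {
  tibble(atom = .atom_ids, value = unname(x$atoms[.atom_ids]))
}

#' @export
#' @method glance pid_atoms
glance.pid_atoms <- function(x, ...) {
  tibble(
    unq_x = x$atoms[["unq_x"]], unq_y = x$atoms[["unq_y"]],
    red = x$atoms[["red"]], syn = x$atoms[["syn"]],
    total_mi = x$total_mi, estimator = x$estimator
  )
}

#' @export
print.pid_atoms <- function(x, ...) {
  cat(sprintf("PID atoms (%s), bits:\n", x$estimator))
  cat(sprintf(
    "  unq_x = %.4f  unq_y = %.4f  red = %.4f  syn = %.4f  [I(X,Y:Z) = %.4f]\n",
    x$atoms[["unq_x"]], x$atoms[["unq_y"]], x$atoms[["red"]], x$atoms[["syn"]],
    x$total_mi
  ))
  invisible(x)
}

#' Minimal-mutual-information PID of a discrete pmf
#'
#' The MMI decomposition defines redundancy as the smaller of the two
#' source-target mutual informations, `red = min(I(X:Z), I(Y:Z))`; the other
#' atoms follow from the conservation identity
#' `unq_x + unq_y + red + syn = I(X, Y : Z)`.
#'
#' @param pmf A `joint_pmf`.
#' @return A `pid_atoms` object (estimator `"mmi_discrete"`).
#' @export
#' @examples
#' mmi_pid_discrete(exact_pmf("mXOR")) # pure synergy: 1 bit
mmi_pid_discrete <- function(pmf) {
  ix <- shannon_mi(pmf, "x")
  iy <- shannon_mi(pmf, "y")
  ixy <- shannon_mi(pmf, "xy")
  red <- min(ix, iy)
  atoms <- c(
    unq_x = ix - red, unq_y = iy - red, red = red,
    syn = ixy - ix - iy + red
  )
  new_pid_atoms(atoms, ixy, "mmi_discrete", list(i_x = ix, i_y = iy, i_xy = ixy))
}

#' BROJA PID of a discrete pmf
#'
#' Unique information in the Bertschinger/BROJA sense: `unq_x` is the minimum
#' of `I_Q(X : Z | Y)` over all joint laws Q that preserve the pairwise
#' (X, Z) and (Y, Z) marginals of the input pmf; `unq_y` is the symmetric
#' quantity, and `red`/`syn` follow from conservation.  Over that polytope
#' minimising either conditional mutual information is equivalent to
#' minimising `I_Q(X, Y : Z)` (the pairwise terms are fixed), so a single
#' convex program yields all four atoms.
#'
#' The program is solved by cyclic exact line searches along the elementary
#' transport moves of each z-slice of Q (each move shifts mass around a
#' 2 x 2 cell rectangle, preserving all fixed marginals); the objective is
#' convex and smooth on the polytope, so the sweeps converge to the global
#' optimum.
#'
#' @param pmf A `joint_pmf`.
#' @param tol Convergence tolerance on the objective decrease per sweep, in
#'   bits (default `1e-9`).
#' @param max_sweeps Iteration cap; exceeding it raises an error carrying the
#'   last objective gap.
#' @return A `pid_atoms` object (estimator `"broja"`); `details` carries the
#'   optimal coupling, sweep count and final objective.
#' @export
#' @examples
#' # AND gate: no unique information, red ~ 0.311, syn = 0.5 bits
#' and_tab <- array(0, c(2, 2, 2))
#' and_tab[1, 1, 1] <- and_tab[1, 2, 1] <- and_tab[2, 1, 1] <- and_tab[2, 2, 2] <- 0.25
#' broja_pid_discrete(joint_pmf(and_tab))
broja_pid_discrete <- function(pmf, tol = 1e-9, max_sweeps = 1000) {
  stopifnot(tol > 0)
  ix <- shannon_mi(pmf, "x")
  iy <- shannon_mi(pmf, "y")
  ixy <- shannon_mi(pmf, "xy")
  opt <- broja_minimise(pmf$table, tol = tol, max_sweeps = max_sweeps)
  f_star <- opt$value # min over polytope of I_Q(X,Y:Z), bits
  # conservation holds exactly by construction of the remaining atoms
  unq_x <- f_star - iy
  unq_y <- f_star - ix
  atoms <- c(
    unq_x = unq_x, unq_y = unq_y,
    red = ix + iy - f_star, syn = ixy - f_star
  )
  new_pid_atoms(
    atoms, ixy, "broja",
    list(
      q_opt = opt$q, sweeps = opt$sweeps, objective = f_star,
      converged = opt$converged, i_x = ix, i_y = iy, i_xy = ixy
    )
  )
}

# Minimise I_Q(X,Y:Z) over joint laws Q with the (X,Z) and (Y,Z) marginals of
# `tab`.  Slice-wise the feasible set is a transportation polytope (fixed row
# and column sums); slices couple only through the Q(x,y) marginal term of
# the objective.  Returns the optimum in bits.
broja_minimise <- function(tab, tol = 1e-9, max_sweeps = 1000) {
  a <- dim(tab)
  pz <- apply(tab, 3, sum)
  # start from the conditional-independence coupling Q(x,y,z) = P(x|z)P(y|z)P(z)
  q <- array(0, dim = a)
  for (k in seq_len(a[3])) {
    if (pz[k] <= 0) next
    r <- apply(tab[, , k, drop = FALSE], 1, sum)
    cl <- apply(tab[, , k, drop = FALSE], 2, sum)
    q[, , k] <- outer(r, cl) / pz[k]
  }
  nl <- function(v) {
    pos <- v > 0
    sum(v[pos] * log(v[pos]))
  }
  # objective in nats up to the constant -sum pz log pz
  obj <- function(q) nl(q) - nl(apply(q, c(1, 2), sum))
  # binary sources: one free parameter per z-slice with box constraints, a
  # smooth convex program solved jointly (coordinate sweeps can zigzag
  # between coupled slices, so the quasi-Newton pass does the heavy lifting
  # and the sweep below only verifies convergence)
  if (a[1] == 2 && a[2] == 2) {
    q <- broja_lbfgs_binary(tab, q, pz, nl)
  }
  cur <- obj(q)
  converged <- FALSE
  sweeps <- 0
  pairs_x <- if (a[1] >= 2) utils::combn(a[1], 2, simplify = FALSE) else list()
  pairs_y <- if (a[2] >= 2) utils::combn(a[2], 2, simplify = FALSE) else list()
  for (s in seq_len(max_sweeps)) {
    sweeps <- s
    prev <- cur
    qxy <- apply(q, c(1, 2), sum)
    for (k in seq_len(a[3])) {
      if (pz[k] <= 0) next
      for (px in pairs_x) {
        for (py in pairs_y) {
          x1 <- px[1]; x2 <- px[2]; y1 <- py[1]; y2 <- py[2]
          q11 <- q[x1, y1, k]; q12 <- q[x1, y2, k]
          q21 <- q[x2, y1, k]; q22 <- q[x2, y2, k]
          lo <- -min(q11, q22); hi <- min(q12, q21)
          if (hi - lo <= 0) next
          m11 <- qxy[x1, y1]; m12 <- qxy[x1, y2]
          m21 <- qxy[x2, y1]; m22 <- qxy[x2, y2]
          # move: +t at (x1,y1),(x2,y2); -t at (x1,y2),(x2,y1)
          g <- function(t) {
            nl(c(q11 + t, q22 + t, q12 - t, q21 - t)) -
              nl(c(m11 + t, m22 + t, m12 - t, m21 - t))
          }
          o <- optimize(g, c(lo, hi), tol = 1e-11)
          t_opt <- o$minimum
          # prefer exact boundary when the optimizer hugs it
          if (t_opt - lo < 1e-10 && g(lo) <= o$objective) t_opt <- lo
          if (hi - t_opt < 1e-10 && g(hi) <= o$objective) t_opt <- hi
          if (g(t_opt) < g(0)) {
            q[x1, y1, k] <- q11 + t_opt; q[x2, y2, k] <- q22 + t_opt
            q[x1, y2, k] <- q12 - t_opt; q[x2, y1, k] <- q21 - t_opt
            qxy[x1, y1] <- m11 + t_opt; qxy[x2, y2] <- m22 + t_opt
            qxy[x1, y2] <- m12 - t_opt; qxy[x2, y1] <- m21 - t_opt
          }
        }
      }
    }
    cur <- obj(q)
    if (prev - cur < tol * log(2)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(sprintf(
      "BROJA optimisation did not converge within %d sweeps (last objective decrease %.3e bits)",
      max_sweeps, (prev - cur) / log(2)
    ))
  }
  value <- (nl(q) - nl(apply(q, c(1, 2), sum)) - nl(pz)) / log(2)
  list(value = max(value, 0), q = q, sweeps = sweeps, converged = converged)
}

# Joint quasi-Newton solve of the binary-source program: free parameter
# t_k = Q(x=0, y=0, z=k), bounds from cell nonnegativity (shrunk by a hair
# so the log-gradient stays finite; the objective error from the shrink is
# far below any reported precision).
broja_lbfgs_binary <- function(tab, q0, pz, nl) {
  K <- dim(tab)[3]
  r1 <- vapply(seq_len(K), function(k) sum(tab[1, , k]), numeric(1))
  c1 <- vapply(seq_len(K), function(k) sum(tab[, 1, k]), numeric(1))
  lo <- pmax(0, r1 + c1 - pz)
  hi <- pmin(r1, c1)
  free <- which(pz > 0 & hi - lo > 1e-13)
  if (length(free) == 0) return(q0)
  eps <- 1e-12 * pmax(pz[free], 1e-6)
  lo_f <- lo[free] + eps
  hi_f <- hi[free] - eps
  build_q <- function(t) {
    q <- q0
    for (j in seq_along(free)) {
      k <- free[j]
      q[1, 1, k] <- t[j]
      q[1, 2, k] <- r1[k] - t[j]
      q[2, 1, k] <- c1[k] - t[j]
      q[2, 2, k] <- pz[k] - r1[k] - c1[k] + t[j]
    }
    q
  }
  fn <- function(t) {
    q <- build_q(t)
    nl(q) - nl(apply(q, c(1, 2), sum))
  }
  gr <- function(t) {
    q <- build_q(t)
    m <- apply(q, c(1, 2), sum)
    lg <- function(v) log(pmax(v, 1e-300))
    vapply(seq_along(free), function(j) {
      k <- free[j]
      (lg(q[1, 1, k]) - lg(q[1, 2, k]) - lg(q[2, 1, k]) + lg(q[2, 2, k])) -
        (lg(m[1, 1]) - lg(m[1, 2]) - lg(m[2, 1]) + lg(m[2, 2]))
    }, numeric(1))
  }
  t0 <- pmin(pmax(vapply(free, function(k) q0[1, 1, k], numeric(1)), lo_f), hi_f)
  fit <- tryCatch(
    stats::optim(t0, fn, gr,
      method = "L-BFGS-B", lower = lo_f, upper = hi_f,
      control = list(maxit = 500, factr = 10)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !all(is.finite(fit$par))) return(q0)
  build_q(pmin(pmax(fit$par, lo_f), hi_f))
}

#' MMI PID of a continuous triplet via nearest-neighbour MI estimates
#'
#' Applies the MMI combination rules to Kraskov (KSG) estimates of
#' `I(X:Z)`, `I(Y:Z)` and `I(X,Y:Z)` (see [ksg_mi()]).  Atoms may come out
#' slightly negative from estimator noise and are reported unclipped.
#' Differential mutual information diverges for deterministic relations, so
#' each variable must have nonzero sample variance — in practice add at
#' least 1% observation noise to every variable (see [apply_noise()]).
#'
#' @param data A continuous `triplet`.
#' @param k Neighbour count of the KSG estimator (default 3).
#' @return A `pid_atoms` object (estimator `"mmi_continuous"`).
#' @export
mmi_pid_continuous <- function(data, k = 3) {
  if (triplet_kind(data) != "continuous") {
    abort("mmi_pid_continuous needs a continuous triplet")
  }
  v <- vapply(data[, c("x", "y", "z")], var, numeric(1))
  if (any(v <= 1e-12)) {
    abort(paste(
      "a variable has (near) zero variance; the differential-MI estimator",
      "diverges for deterministic relations - add >= 1% observation noise",
      "to every variable before estimating continuous atoms"
    ))
  }
  ix <- ksg_mi(data$x, data$z, k = k)
  iy <- ksg_mi(data$y, data$z, k = k)
  ixy <- ksg_mi(cbind(data$x, data$y), data$z, k = k)
  red <- min(ix, iy)
  atoms <- c(
    unq_x = ix - red, unq_y = iy - red, red = red,
    syn = ixy - ix - iy + red
  )
  new_pid_atoms(atoms, ixy, "mmi_continuous", list(i_x = ix, i_y = iy, i_xy = ixy, k = k))
}
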