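# Independent oracles used across tests.  These deliberately avoid the
# package's optimisation and MI code paths: entropies are computed directly
# from probability tables and the BROJA program is solved by zoomed grid
# search over the feasible polytope.

# base-2 mutual information of a 2-d joint probability table
oracle_mi2 <- function(j) {
  pa <- rowSums(j)
  pb <- colSums(j)
  s <- 0
  for (i in seq_along(pa)) {
    for (k in seq_along(pb)) {
      if (j[i, k] > 0) s <- s + j[i, k] * log2(j[i, k] / (pa[i] * pb[k]))
    }
  }
  s
}

# Brute-force BROJA atoms for a 2 x 2 x 2 pmf: the marginal-preserving
# polytope has one free parameter t_k = Q(0,0,k) per z slice; minimise
# I_Q(X,Y : Z) by grid search with iterative zooming.
oracle_broja_222 <- function(tab, pts = 41, rounds = 4) {
  stopifnot(all(dim(tab) == c(2, 2, 2)))
  pz <- apply(tab, 3, sum)
  pxz <- apply(tab, c(1, 3), sum)
  pyz <- apply(tab, c(2, 3), sum)
  ixz <- oracle_mi2(pxz)
  iyz <- oracle_mi2(pyz)
  ixy_z <- oracle_mi2(matrix(tab, nrow = 4))
  r1 <- pxz[1, ]
  c1 <- pyz[1, ]
  lo <- pmax(0, r1 + c1 - pz)
  hi <- pmin(r1, c1)
  q_of <- function(t) {
    q <- array(0, c(2, 2, 2))
    for (k in 1:2) {
      q[1, 1, k] <- t[k]
      q[1, 2, k] <- r1[k] - t[k]
      q[2, 1, k] <- c1[k] - t[k]
      q[2, 2, k] <- pz[k] - r1[k] - c1[k] + t[k]
    }
    q
  }
  f <- function(t) {
    q <- q_of(t)
    q[q < 0] <- 0
    oracle_mi2(matrix(q, nrow = 4))
  }
  ctr <- (lo + hi) / 2
  wid <- (hi - lo) / 2
  best <- c(f(ctr), ctr)
  for (r in seq_len(rounds)) {
    g1 <- seq(max(lo[1], best[2] - wid[1]), min(hi[1], best[2] + wid[1]), length.out = pts)
    g2 <- seq(max(lo[2], best[3] - wid[2]), min(hi[2], best[3] + wid[2]), length.out = pts)
    for (t1 in g1) {
      for (t2 in g2) {
        v <- f(c(t1, t2))
        if (v < best[1]) best <- c(v, t1, t2)
      }
    }
    wid <- wid * (2.5 / pts)
  }
  f_star <- best[1]
  list(
    unq_x = f_star - iyz, unq_y = f_star - ixz,
    red = ixz + iyz - f_star, syn = ixy_z - f_star
  )
}

# random 2 x 2 x 2 pmf; occasionally sparse to exercise boundary optima
random_pmf_222 <- function(sparse = FALSE) {
  w <- rexp(8)
  if (sparse) w[sample.int(8, 3)] <- 0
  joint_pmf(array(w / sum(w), c(2, 2, 2)))
}
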