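#' Joint probability mass function over a triplet alphabet
#'
#' Container for an exact or empirical probability table over the finite
#' alphabet of a discrete triplet: a 3-d array indexed `[x, y, z]` with
#' nonnegative entries summing to one.  This is the substrate of the discrete
#' PID measures.
#'
#' @param table Numeric 3-d array of probabilities (states coded from 0, so
#'   entry `[i, j, k]` is `P(X = i-1, Y = j-1, Z = k-1)`).
#' @return A `joint_pmf` object.
#' @export
joint_pmf <- function(table) {
  table <- as.array(table)
  if (length(dim(table)) != 3) abort("a joint pmf needs a 3-d probability table")
  if (any(table < -1e-15)) abort("probabilities must be nonnegative")
  table[table < 0] <- 0
  if (abs(sum(table) - 1) > 1e-12) abort("probabilities must sum to 1 (within 1e-12)")
  structure(list(table = table, alphabet = dim(table)), class = "joint_pmf")
}

#' @export
print.joint_pmf <- function(x, ...) {
  cat(sprintf(
    "Joint pmf over %d x %d x %d states (x, y, z)\n",
    x$alphabet[1], x$alphabet[2], x$alphabet[3]
  ))
  invisible(x)
}

#' Empirical joint pmf of a discrete triplet
#'
#' Tabulates relative frequencies on the declared alphabet (taken from the
#' triplet's `alphabet` attribute, not from the observed support, so states
#' that never occur keep probability zero cells).
#'
#' @param data A discrete `triplet` (see [as_triplet()]).
#' @return A `joint_pmf`.
#' @export
#' @examples
#' s <- sample_ground_truth("mXOR", "discrete", 1000, seed = 1)
#' empirical_pmf(s)
empirical_pmf <- function(data) {
  if (triplet_kind(data) != "discrete") {
    abort("empirical_pmf needs a discrete triplet; use the KSG-based continuous measures instead")
  }
  a <- triplet_alphabet(data)
  idx <- data$x + a[1] * data$y + a[1] * a[2] * data$z + 1
  counts <- tabulate(idx, nbins = prod(a))
  joint_pmf(array(counts / nrow(data), dim = a))
}

#' Exact joint pmf of a discrete observable model
#'
#' Closed-form law of the noisy observables (X, Y, Z) for a discrete
#' ground-truth model under switching noise, obtained by summing over latent
#' and switching configurations.  Serves as the infinite-data oracle for the
#' sampled models.
#'
#' @inheritParams sample_ground_truth
#' @inheritParams apply_noise
#' @return A `joint_pmf` (alphabet 2 x 2 x 2, or 2 x 2 x 3 for `mSum`).
#' @export
#' @examples
#' exact_pmf("mXOR") # uniform over the four XOR-consistent triples
exact_pmf <- function(model, p_x = 0, p_y = 0, p_z = 0) {
  model <- match.arg(model, .model_ids)
  p <- c(p_x, p_y, p_z)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("noise fractions must lie in [0, 1]")
  }
  a <- c(2L, 2L, if (model == "mSum") 3L else 2L)
  tab <- array(0, dim = a)
  # switching noise kernel: keep w.p. 1-p, else Bernoulli(0.5) on {0, 1}
  kern <- function(obs, g, pv) (1 - pv) * (obs == g) + pv * 0.5 * (obs <= 1)
  for (tx in 0:1) {
    for (ty in 0:1) {
      gx <- tx
      gy <- if (model == "mRed") tx else ty
      gz <- switch(model,
        mRed = tx, mUnq = tx,
        mXOR = as.numeric(xor(tx == 1, ty == 1)),
        mSum = tx + ty
      )
      for (ox in 0:(a[1] - 1)) {
        for (oy in 0:(a[2] - 1)) {
          for (oz in 0:(a[3] - 1)) {
            tab[ox + 1, oy + 1, oz + 1] <- tab[ox + 1, oy + 1, oz + 1] +
              0.25 * kern(ox, gx, p[1]) * kern(oy, gy, p[2]) * kern(oz, gz, p[3])
          }
        }
      }
    }
  }
  joint_pmf(tab)
}

# xlogx with 0 log 0 := 0
xlx <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Shannon mutual information from a joint pmf
#'
#' Base-2 mutual information between a grouping of the sources and the
#' target: `I(X : Z)`, `I(Y : Z)`, or the joint `I(X, Y : Z)`.
#'
#' @param pmf A `joint_pmf`.
#' @param grouping `"x"`, `"y"`, or `"xy"`.
#' @return Mutual information in bits.
#' @export
#' @examples
#' shannon_mi(exact_pmf("mXOR"), "xy") # 1 bit
#' shannon_mi(exact_pmf("mXOR"), "x") # 0 bits
shannon_mi <- function(pmf, grouping = c("xy", "x", "y")) {
  grouping <- match.arg(grouping)
  t3 <- pmf$table
  pz <- apply(t3, 3, sum)
  joint <- switch(grouping,
    x = apply(t3, c(1, 3), sum),
    y = apply(t3, c(2, 3), sum),
    xy = {
      m <- apply(t3, c(1, 2, 3), sum)
      dim(m) <- c(prod(dim(t3)[1:2]), dim(t3)[3])
      m
    }
  )
  pa <- rowSums(joint)
  sum(xlx(joint)) - sum(xlx(pa)) - sum(xlx(pz))
}

#' Serialise a joint pmf to JSON
#'
#' Writes/reads the interchange form `{"shape": [a_x, a_y, a_z],
#' "probs": [...]}` with probabilities in row-major order (x fastest).
#'
#' @param pmf A `joint_pmf`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
pmf_to_json <- function(pmf, path = NULL) {
  obj <- list(shape = as.integer(pmf$alphabet), probs = as.numeric(pmf$table))
  js <- jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA)
  if (is.null(path)) {
    as.character(js)
  } else {
    writeLines(as.character(js), path)
    invisible(path)
  }
}

#' @rdname pmf_to_json
#' @param json JSON string or file path produced by [pmf_to_json()].
#' @export
pmf_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  joint_pmf(array(obj$probs, dim = obj$shape))
}
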