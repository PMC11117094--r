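#' Derive a child seed from a root seed
#'
#' Every stochastic routine in the package takes an explicit integer seed.
#' Experiments split one root seed into independent child seeds for the
#' latent draws, the noise draws, the permutations and each grid point, so a
#' whole sweep is reproducible from a single integer.  The derivation is a
#' small multiplicative hash of the root seed and a string key; results stay
#' below 2^31 so they are valid R integer seeds.
#'
#' @param seed Integer root seed.
#' @param key Character or integer label of the stream (e.g. `"noise"`,
#'   `"perm:17"`).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "noise")
#' derive_seed(1, "noise") == derive_seed(1L, "noise")
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  m <- 2147483629 # largest prime < 2^31
  h <- as.numeric(seed) %% m
  bytes <- utf8ToInt(paste0(as.character(key)))
  for (b in bytes) {
    h <- (h * 131 + b) %% m
  }
  # one extra scramble round so consecutive roots decorrelate
  h <- (h * 48271) %% m
  as.integer(h)
}

# Run `expr` under `seed` without touching the caller's RNG stream.  The
# save/restore is done directly (rather than via withr) because this sits in
# every Monte-Carlo inner loop.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  }
  on.exit(
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  )
  set.seed(as.integer(seed))
  expr
}
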