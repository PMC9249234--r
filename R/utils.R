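# Internal helpers: RNG bookkeeping, Adam optimizer state, seed derivation.

# Save / restore the global RNG state so that explicitly seeded operations
# do not perturb the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Minimal Adam state for a matrix-shaped parameter.
adam_init <- function(shape, lr = 1e-2, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(m = array(0, dim = shape), v = array(0, dim = shape),
       t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

# One Adam step for gradient `g`; returns the updated state and the
# increment `delta` to subtract from the parameter.
adam_step <- function(opt, g) {
  opt$t <- opt$t + 1L
  opt$m <- opt$beta1 * opt$m + (1 - opt$beta1) * g
  opt$v <- opt$beta2 * opt$v + (1 - opt$beta2) * g^2
  mhat <- opt$m / (1 - opt$beta1^opt$t)
  vhat <- opt$v / (1 - opt$beta2^opt$t)
  list(opt = opt, delta = opt$lr * mhat / (sqrt(vhat) + opt$eps))
}

#' Derive a child seed from a master seed
#'
#' A documented counter scheme: child `k` of master seed `s` is
#' `(s * 7919 + k * 104729) mod (2^31 - 1)`, kept within the 32-bit integer
#' range expected by [set.seed()].  Distinct `(seed, k)` pairs used by the
#' package's experiment drivers map to distinct child seeds in practice.
#'
#' @param seed master seed (integer).
#' @param k child index (integer, `>= 0`).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %%
               2147483647)
}
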