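#' @keywords internal
"_PACKAGE"

#' @importFrom stats as.formula binomial coef dnorm glm glm.fit lm.fit
#'   logLik pchisq plogis pnorm predict qnorm rbinom rlnorm
#'   rnorm runif setNames uniroot var
#' @importFrom utils read.csv write.csv head combn
NULL

# Derive a reproducible integer sub-seed from a master seed and a stream name,
# so that independent pipeline stages draw from independent substreams.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647L)
}

# Evaluate a block with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Probability-weighted grid over the latent severity axis, used to solve the
# per-site intercepts and the global prevalence offset by quadrature.
severity_grid <- function(sd, n = 241L, width = 6) {
  z <- seq(-width * sd, width * sd, length.out = n)
  w <- dnorm(z, sd = sd)
  w <- w / sum(w)
  list(z = z, w = w)
}

# Sample from a discrete distribution through a Gaussian copula tied to the
# standardized latent severity (rho > 0 pushes high categories at high severity).
copula_categorical <- function(z_std, probs, values, rho) {
  n <- length(z_std)
  t <- rho * z_std + sqrt(1 - rho^2) * rnorm(n)
  u <- pnorm(t)
  brk <- cumsum(probs) / sum(probs)
  idx <- findInterval(u, brk, rightmost.closed = TRUE) + 1L
  idx[idx > length(values)] <- length(values)
  values[idx]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
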