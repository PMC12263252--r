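#' @keywords internal
"_PACKAGE"

#' Derive a per-operation random seed from a master seed
#'
#' Every stochastic operation in the package draws its own stream from the
#' master seed through this splitting rule, so adding one simulation to a
#' pipeline does not perturb the draws of another.
#'
#' @param seed Master seed (single integer).
#' @param stream Operation label (character) or integer stream index.
#' @return A single integer seed in `[0, 2^31 - 1)`.
#' @export
deriveSeed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (is.character(stream)) {
    stream <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  }
  m <- 2147483647  # 2^31 - 1, Mersenne prime modulus (Park-Miller)
  s <- (as.numeric(seed) %% m) + 1
  s <- (s * 48271) %% m
  s <- (s + 2654435769 * (as.numeric(stream) %% 1000003)) %% m
  as.integer(s)
}

# trim leading/trailing whitespace and collapse internal runs to one space;
# the only name normalisation applied anywhere (no fuzzy matching)
normalizeTaxon <- function(x) {
  gsub("[[:space:]]+", " ", trimws(as.character(x)))
}

# (1 - exp(-a * dt)) / a with the a -> 0 limit handled analytically
expIntegral <- function(a, dt) {
  out <- ifelse(abs(a) < 1e-12, dt, -expm1(-a * dt) / a)
  out
}

#' Small-sample Akaike information criterion
#'
#' @param logLik Maximised log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of observations (tips).
#' @return AICc value; requires `n > k + 1`.
#' @export
aicc <- function(logLik, k, n) {
  if (any(n <= k + 1)) stop("AICc undefined: n must exceed k + 1")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# cheap data fingerprint used to refuse comparing fits on different data
dataFingerprint <- function(tree, y) {
  paste(length(y), paste(sort(names(y)), collapse = "|"),
        format(sum(y), digits = 15), format(sum(y^2), digits = 15),
        format(sum(tree$edge.length), digits = 15), sep = "#")
}
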