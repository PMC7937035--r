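# internal helpers

# Deterministic 31-ary string hash folded into [0, 2^31-2]; combined with a
# user seed it gives each recording its own reproducible RNG substream,
# independent of processing order.
.hashSeed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (v in utf8ToInt(as.character(key))) {
    h <- (h * 31 + v) %% 2147483647
  }
  as.integer(h)
}

# Truncated-normal draw by rejection; errors after maxTries misses so a
# misconfigured interval fails loudly rather than looping forever.
.rtruncnorm1 <- function(mean, sd, lo, hi, maxTries = 100L) {
  for (i in seq_len(maxTries)) {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  stop("could not draw a value in [", lo, ", ", hi, "] after ",
       maxTries, " tries")
}

.isWholeNumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}
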