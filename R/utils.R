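# Internal helpers shared across modules.

# Derive n reproducible child seeds from one master seed without touching the
# caller's RNG state. Values stay below 2^31 so they are valid R integers.
derive_seeds <- function(master_seed, n) {
  withr::with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Symmetric Hann window (sums are normalized by callers as needed).
hann_window <- function(n) {
  if (n <= 1) return(rep(1, max(n, 1)))
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# Raised-cosine fade of `n` samples applied in place at both ends of x.
apply_ramps <- function(x, n) {
  if (n < 1) return(x)
  n <- min(n, floor(length(x) / 2))
  ramp <- 0.5 - 0.5 * cos(pi * seq(0, 1, length.out = n))
  x[seq_len(n)] <- x[seq_len(n)] * ramp
  x[seq(length(x) - n + 1, length(x))] <- x[seq(length(x) - n + 1, length(x))] * rev(ramp)
  x
}

amp_to_db <- function(a) 20 * log10(a)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)),
          class = "roundsound_argument_error")
  }
  invisible(x)
}

# Greatest common divisor, for rational resampling ratios.
gcd <- function(a, b) {
  while (b != 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}
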