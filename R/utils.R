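# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without touching the caller's RNG
# state. All package randomness flows through this; no function relies on
# the global seed.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion", .rng_sample_kind = "Rejection")
}

# Derive a child seed from a parent seed and a stream label, keeping the
# result inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)

# Linear voxel index helpers for (X, Y, Z) grids in column-major order.
voxel_count <- function(dims) prod(dims)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
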