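# Small shared helpers: seeded sub-stream derivation and array plumbing.

# Derive a reproducible 31-bit sub-seed from a master seed and a sequence of
# integer/string tags. Keeps every derived seed in [1, 2^31 - 2].
derive_seed <- function(master, ...) {
  tags <- list(...)
  s <- as.numeric(master) %% 2147483629
  for (tg in tags) {
    if (is.character(tg)) tg <- sum(utf8ToInt(tg)) * 131
    s <- (s * 69069 + as.numeric(tg) * 2654435 + 1013904223) %% 2147483629
  }
  as.integer(s + 1)
}

# Concatenate feature maps along the channel axis. Inputs are H x W x C arrays
# (or H x W matrices, treated as one channel).
abind_ch <- function(a, b) {
  a <- as_chw(a); b <- as_chw(b)
  stopifnot(dim(a)[1] == dim(b)[1], dim(a)[2] == dim(b)[2])
  array(c(a, b), c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

as_chw <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

# Channel slice that never drops dimensions.
ch_slice <- function(x, idx) {
  array(x[, , idx, drop = FALSE], c(dim(x)[1], dim(x)[2], length(idx)))
}

clip01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
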