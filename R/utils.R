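# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.  seed = NULL means "use the current stream".
with_seed_local <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Half-away-from-zero decimal rounding (base round() is banker's).
round_half_away <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

gcd2 <- function(a, b) {
  a <- abs(as.integer(a)); b <- abs(as.integer(b))
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

# Best small-integer rational p/q approximating `ratio` (continued fractions).
rational_approx <- function(ratio, max_den = 1000L) {
  if (abs(ratio - round(ratio)) < 1e-12) return(c(p = round(ratio), q = 1L))
  h0 <- 0L; h1 <- 1L; k0 <- 1L; k1 <- 0L; x <- ratio
  for (i in 1:64) {
    a <- floor(x)
    h2 <- a * h1 + h0; k2 <- a * k1 + k0
    if (k2 > max_den) break
    h0 <- h1; h1 <- h2; k0 <- k1; k1 <- k2
    if (abs(h1 / k1 - ratio) < 1e-12) break
    fr <- x - a
    if (fr < 1e-15) break
    x <- 1 / fr
  }
  c(p = as.integer(h1), q = as.integer(k1))
}

# Cosine window of the requested kind; L >= 1.
window_vec <- function(kind = c("hamming", "hann", "rect"), L) {
  kind <- match.arg(kind)
  if (L == 1L) return(1)
  n <- seq_len(L) - 1L
  switch(kind,
    hamming = 0.54 - 0.46 * cos(2 * pi * n / (L - 1)),
    hann    = 0.5 - 0.5 * cos(2 * pi * n / (L - 1)),
    rect    = rep(1, L))
}

# RMS level in dBFS with a floor (default -80 dB).
db_level <- function(rms, floor_db = -80) {
  pmax(20 * log10(pmax(rms, 0)), floor_db)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
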