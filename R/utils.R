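# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a named substream seed from a master seed. Keeps results < 2^31 and
# makes every stage's randomness a pure function of (master seed, name).
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(as.character(name)) * seq_along(utf8ToInt(as.character(name))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587) + 1L
}

# Population-sd (denominator n) standard deviation of a vector.
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Column-wise standardisation using train-set statistics (StandardScaler
# semantics: mean 0, population sd 1; constant columns are left centred).
scaler_fit <- function(x) {
  m <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2L, m)^2))
  s[s < 1e-12] <- 1
  list(center = m, scale = s)
}

scaler_apply <- function(scaler, x) {
  sweep(sweep(x, 2L, scaler$center), 2L, scaler$scale, "/")
}

stop_if_na <- function(x, what) {
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("%s contains missing or non-finite values", what))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
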