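# Internal helpers: seeded RNG streams and small validators.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Stable sub-stream seed from (seed, name): polynomial string hash folded
# with the master seed, kept in [1, 2^31 - 2]. Adding outcomes must not
# perturb the streams of existing ones, so the hash depends only on the name.
stream_seed <- function(seed, name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- 2147483647  # 2^31 - 1 (prime)
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% m
  out <- (h + 1103515245 * (as.numeric(seed) %% 1024) + as.numeric(seed)) %% m
  as.integer(out %% (m - 2L) + 1L)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}
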