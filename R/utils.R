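# Internal utilities: deterministic seed fan-out and field smoothing.

#' Derive a reproducible sub-stream seed
#'
#' Hashes a master seed together with an arbitrary key (stage, species,
#' family, replicate id, ...) into a 32-bit seed, so that every stochastic
#' stage draws from its own named stream of one master seed.
#'
#' @param master integer master seed.
#' @param ... key components (coerced to character).
#' @return a single integer seed in `[1, 2^31 - 20]`.
#' @export
fan_seed <- function(master, ...) {
  key <- paste(c(format(master), vapply(list(...), format, "")), collapse = "/")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483629
  as.integer(h + 1)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Shift a matrix by (di, dj), padding with NA.
shift_matrix <- function(m, di, dj) {
  d <- dim(m)
  out <- matrix(NA_real_, d[1], d[2])
  src_r <- seq_len(d[1]) + di
  src_c <- seq_len(d[2]) + dj
  ok_r <- src_r >= 1 & src_r <= d[1]
  ok_c <- src_c >= 1 & src_c <= d[2]
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# Separable Gaussian smoothing with edge renormalisation.
smooth_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  K <- max(1L, ceiling(3 * sigma))
  w <- dnorm(-K:K, sd = sigma)
  sweep_1d <- function(mat, along_rows) {
    acc <- matrix(0, nrow(mat), ncol(mat))
    wt <- matrix(0, nrow(mat), ncol(mat))
    for (k in seq_along(w)) {
      off <- k - K - 1L
      s <- if (along_rows) shift_matrix(mat, 0L, off) else shift_matrix(mat, off, 0L)
      ok <- !is.na(s)
      acc[ok] <- acc[ok] + w[k] * s[ok]
      wt[ok] <- wt[ok] + w[k]
    }
    acc / wt
  }
  sweep_1d(sweep_1d(m, TRUE), FALSE)
}
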