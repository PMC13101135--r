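#' @keywords internal
"_PACKAGE"

#' Derive a deterministic sub-stream seed
#'
#' Fans a base seed out into named, replicate-indexed RNG streams so that each
#' pipeline stage (and each permutation / bootstrap replicate within a stage)
#' draws from an independent, reproducible stream. The result is always a
#' positive 31-bit integer, safe for `set.seed()`.
#'
#' @param seed base integer seed.
#' @param label character stream label, e.g. `"perm"` or `"boot"`.
#' @param index replicate index within the stream (default 0).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, label, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  h <- (h * 2654435 + as.numeric(index) * 40503 + 1) %% m
  as.integer(h %% (m - 2) + 1)
}

# Run `expr` under `set.seed(seed)` without disturbing the caller's RNG state.
with_stream <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Population (divisor n) column standard deviations.
col_sd_pop <- function(x) {
  mu <- colMeans(x)
  sqrt(colMeans(x^2) - mu^2)
}

# Shared argument checks ------------------------------------------------------

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name, closed_upper = TRUE) {
  hi_ok <- if (closed_upper) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !hi_ok) {
    stop(sprintf("`%s` must be a probability in [0, %s", name,
                 if (closed_upper) "1]" else "1)"), call. = FALSE)
  }
  invisible(as.numeric(x))
}
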