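# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
cp_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cortiphys_error", "error")))
}

cp_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "cortiphys_warning", "warning")))
}

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards.  seed = NULL runs in the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# centered boxcar moving average; width in samples (forced odd); edges use
# the partial window so the output has the same length as x
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1L) return(x)
  if (width %% 2L == 0L) width <- width + 1L
  n <- length(x)
  h <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# significance stars at the conventional thresholds
p_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
    ifelse(p <= 0.001, "***",
      ifelse(p <= 0.01, "**",
        ifelse(p <= 0.05, "*", ""))))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)
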