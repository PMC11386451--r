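#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a master seed and a stream name.
# Keeps results independent of the order in which pipeline stages consume
# randomness. The hash stays below 2^31 - 1 so it is a valid R integer seed.
sub_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state; the caller's stream is restored
# afterwards (or left untouched if none existed yet).
with_seed <- function(seed, code) {
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
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_input("%s is missing required column(s): %s", what,
               paste(miss, collapse = ", "))
  }
  invisible(df)
}
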