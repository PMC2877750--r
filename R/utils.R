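# Shared helpers: typed error conditions and seed handling.

ms_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "methylskin_error"),
                      call = call))
}

#' @noRd
input_error <- function(msg) ms_error(msg, "methylskin_input_error")

#' @noRd
config_error <- function(msg) ms_error(msg, "methylskin_config_error")

#' @noRd
stat_error <- function(msg) ms_error(msg, "methylskin_stat_error")

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    input_error(sprintf("`%s` must be a single value in [0, 1], got %s",
                        name, paste(format(x), collapse = ", ")))
  x
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    input_error("`seed` must be a single integer")
  as.integer(seed %% .Machine$integer.max)
}

# Derive a stream-specific child seed from one user-facing seed; keeps every
# sub-generator reproducible and independent while staying below 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- sum(as.integer(charToRaw(stream)) * seq_along(charToRaw(stream)))
  as.integer((as.numeric(check_seed(seed)) + 1000003 * h) %%
               .Machine$integer.max)
}

# Evaluate `code` under `seed` and restore the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(check_seed(seed))
  force(code)
}
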