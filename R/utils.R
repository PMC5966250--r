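# internal helpers: validation and seeded evaluation

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config("'%s' must be a single probability in [0, 1], got %s",
                name, paste(format(x), collapse = ","))
  x
}

check_pos <- function(x, name, int = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_config("'%s' must be a single positive number", name)
  if (int && x != round(x))
    stop_config("'%s' must be a positive integer", name)
  x
}

is_wholenumber <- function(x, tol = sqrt(.Machine$double.eps)) {
  is.finite(x) & abs(x - round(x)) < tol
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
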