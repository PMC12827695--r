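# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_edgedyn <- function(fmt, ..., class = "edgedyn_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. Keeps cohort generation / permutation seeding from
# clobbering user RNG streams.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# round-half-away-from-zero; base round() is banker's rounding and would make
# edge counts platform-ambiguous at exact .5 ties.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min)
    stop_edgedyn("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (if (strict) x <= 0 else x < 0))
    stop_edgedyn("'%s' must be a single %s number", name,
                 if (strict) "positive" else "non-negative")
  as.numeric(x)
}
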