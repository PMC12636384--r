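## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; screening-table projection uses
#' commercial rounding (0.5 always rounds up in magnitude) so that expected
#' case counts on the reference population are reproducible integers.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

## checks a scalar probability-like value
assert_fraction <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) stop_config("`%s` must be a single value in %s, got %s",
                       name, if (open) "(0,1)" else "[0,1]",
                       paste(format(x), collapse = ","))
  invisible(x)
}

## deterministic child seed streams: one base seed fans out to named
## sub-streams without the streams overlapping in practice
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000000L) * 2017L + (h %% 2011L)
}
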