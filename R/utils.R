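# Shared internal helpers.

#' Derive a reproducible sub-stream seed
#'
#' All stochastic stages of the simulator draw from sub-streams derived from a
#' single global integer seed, so one knob controls full reproducibility.
#'
#' @param seed Integer master seed.
#' @param offset Integer stream identifier (each simulator stage uses its own).
#' @return An integer seed below 2^31.
#' @keywords internal
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.double(seed)) * 7919 + as.double(offset) * 104729) %% 2147483629)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# significance stars: * p<0.05, ** p<0.01, *** p<0.001
stars_for_p <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "NS")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

# Format doubles so a write -> read cycle restores them exactly.
format_num <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
  # trim trailing zeros introduced by %.17g for short decimals is unsafe; keep as-is
  out
}
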