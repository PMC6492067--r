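#' Round half away from zero
#'
#' Reported population figures are rounded with the conventional
#' "half-up" rule rather than R's banker's rounding, so that e.g.
#' 742.5 reports as 743.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(742.857)  # 743
#' round_half_up(0.5)      # 1 (round() would give 0)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards. With seed = NULL the
# expression runs against the ambient RNG. All stochastic functions in
# the package route their randomness through this helper so a single
# integer seed makes a whole run reproducible without touching global
# state.
with_rng <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Scalar validators used by the constructors.
assert_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          integerish = FALSE, strict_lower = FALSE,
                          strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  ok_up <- if (strict_upper) x < upper else x <= upper
  if (!ok_low || !ok_up) {
    stop(sprintf(
      "`%s` = %g is outside the admissible range %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ), call. = FALSE)
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop(sprintf("`%s` must be a whole number", name), call. = FALSE)
  }
  invisible(x)
}

# Percentile interval helper (type 7 quantiles, NA dropped).
percentile_interval <- function(x, level) {
  a <- (1 - level) / 2
  unname(stats::quantile(x, c(a, 1 - a), na.rm = TRUE, names = FALSE))
}

# Largest-remainder rounding of non-negative reals to integers with a
# fixed total; used when a weighted degree distribution has to be
# materialised as whole population counts.
round_preserving_sum <- function(x, total) {
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    idx <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  fl
}
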