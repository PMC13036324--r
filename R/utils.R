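# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves going up (the
#' convention used for the printed percentages in catalog reports),
#' unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(0.125, 2)  # 0.13, where round() gives 0.12
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a denominator
#'
#' @param num numerator count.
#' @param den denominator count, > 0.
#' @param digits decimal places for half-up rounding (default 2).
#' @return numeric percentage on the 0-100 scale.
#' @export
#' @examples
#' percent(5374, 6233)      # 86.22
#' percent(9420, 13696, 1)  # 68.8
percent <- function(num, den, digits = 2) {
  if (any(den <= 0)) stop("denominator must be positive", call. = FALSE)
  round_half_up(100 * num / den, digits)
}

# derive a per-artifact RNG seed (< 2^31) from the master seed and a
# stream name, so each generator owns one documented stream
derive_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

# evaluate `code` under a deterministic stream seed, restoring the
# caller's RNG state afterwards
with_stream <- function(seed, stream, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(derive_seed(seed, stream))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_cols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  invisible(df)
}
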