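# internal helpers shared across modules

#' Round half away from zero
#'
#' Commercial ("school") rounding: ties go away from zero, unlike base
#' [round()], which rounds half to even. All displayed percentages in the
#' package use this rule (23.53 -> 24, 2.5 -> 3, -2.5 -> -3).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_away(c(23.53, 17.65, 1.47), 0)
#' round_half_away(75.862, 1)
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

stop_validation <- function(...) {
  stop(structure(
    class = c("genorisk_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_validation(...)
  invisible(TRUE)
}

# Deterministic per-artifact RNG stream: a small string hash folded with the
# master seed, so each generated artifact has its own reproducible stream and
# adding a new generator never perturbs existing ones.
artifact_seed <- function(seed, name) {
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

with_stream <- function(seed, name, code) {
  withr::with_seed(artifact_seed(seed, name), code)
}

# largest-remainder apportionment of `total` into parts proportional to
# `weights` (integer result sums to total, each part <= cap when quotas do)
apportion <- function(total, weights) {
  if (total == 0 || sum(weights) == 0) return(integer(length(weights)))
  quota <- total * weights / sum(weights)
  parts <- floor(quota)
  short <- total - sum(parts)
  if (short > 0) {
    take <- order(quota - parts, decreasing = TRUE)[seq_len(short)]
    parts[take] <- parts[take] + 1
  }
  as.integer(parts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
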