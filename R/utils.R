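#' Default measurement schedule
#'
#' Weeks of age at which body weight is recorded: biweekly from week 6 to
#' week 16, then monthly to week 48 (14 timepoints).
#'
#' @return Integer vector of length 14.
#' @export
#' @examples
#' defaultSchedule()
defaultSchedule <- function() {
  c(6L, 8L, 10L, 12L, 14L, 16L, 20L, 24L, 28L, 32L, 36L, 40L, 44L, 48L)
}

#' Derive a reproducible child seed from a root seed and a key
#'
#' A documented stream-splitting scheme: the child seed is a polynomial
#' rolling hash of the key string, seeded by the root. Streams keyed by
#' line/mouse identity are therefore stable under the addition of new lines
#' or mice: existing draws never reshuffle.
#'
#' @param root Integer root seed.
#' @param key Character scalar naming the substream.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
childSeed <- function(root, key) {
  stopifnot(length(root) == 1L, is.finite(root), length(key) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(root) %% m
  for (b in utf8ToInt(as.character(key))) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

## classed conditions so callers can distinguish contract violations
ccwStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "ccweight_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

checkScheduleWeeks <- function(weeks, what = "schedule") {
  if (length(weeks) < 2L || any(!is.finite(weeks)) || any(diff(weeks) <= 0)) {
    ccwStop("ccweight_invalid_config",
            "%s must be a strictly increasing vector of weeks", what)
  }
  invisible(as.integer(weeks))
}
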