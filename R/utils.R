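#' @importFrom rlang %||%
#' @importFrom stats cor quantile rnorm runif rgamma rbinom sd setNames
#' @importFrom utils head tail
NULL

#' Derive a child seed from a root seed
#'
#' A single root seed deterministically spawns per-pixel, per-stage seeds so
#' that one knob controls all randomness in a run. The mixing is a fixed
#' linear-congruential fold kept below 2^31.
#'
#' @param seed integer root seed.
#' @param ... integers or short strings identifying the consumer
#'   (e.g. pixel id, stage name).
#' @return a single integer seed.
#' @export
spawn_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p))
    h <- (h * 48271 + as.double(p) * 16807 + 1) %% 2147483647
  }
  as.integer(h)
}

# first day of the calendar month containing each date
month_floor <- function(dates) {
  as.Date(format(dates, "%Y-%m-01"))
}

# calendar month number 1..12
month_of <- function(dates) {
  as.integer(format(dates, "%m"))
}

# stop with the name of the first non-finite field in a named list/vector
check_finite <- function(x, what) {
  vals <- unlist(x, use.names = TRUE)
  bad <- !is.finite(vals)
  if (any(bad)) {
    stop(sprintf("non-finite value in %s field '%s'", what,
                 names(vals)[which(bad)[1]]), call. = FALSE)
  }
  invisible(TRUE)
}

# split a vector of indices by the calendar month of `dates`, in time order
split_by_month <- function(dates) {
  key <- format(dates, "%Y-%m")
  split(seq_along(dates), factor(key, levels = unique(key)))
}
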