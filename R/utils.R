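# Internal helpers: condition signalling, validation, seed management.

tme_error <- function(message, class = "tme_invalid_input") {
  cond <- structure(
    class = c(class, "tme_error", "error", "condition"),
    list(message = message, call = NULL)
  )
  stop(cond)
}

tme_config_error <- function(field, detail) {
  tme_error(sprintf("invalid configuration: field '%s' %s", field, detail),
            class = "tme_config_error")
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) &&
    (if (strict_lower) x > lower else x >= lower) && x <= upper
  if (!ok) {
    tme_config_error(field, sprintf(
      "must be a single number in %s%s, %s]", if (strict_lower) "(" else "[",
      format(lower), format(upper)))
  }
  invisible(x)
}

check_fraction <- function(x, field) check_number(x, field, 0, 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the global random seed for the duration of `code` and restores the
#' previous RNG state afterwards, so library calls do not perturb the
#' caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible substream seed from a root seed and a counter.
# Edits to one patient's stream never reshuffle another's.
derive_seed <- function(seed, counter, salt = 0L) {
  s <- (abs(as.double(seed)) * 48271 + as.double(counter) * 7919 +
          as.double(salt) * 104729) %% 2147483629
  as.integer(s) + 1L
}

euclid2 <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)
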