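#' Run code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded helpers do not perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Round half away from zero
#'
#' Unlike [base::round()] (banker's rounding), 0.05 at one decimal becomes
#' 0.1. Used for printed percentages so that reported precision matches
#' conventional table formatting.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stopifnot-style check with a formatted message
.check <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

# geometric mean of strictly positive values
.geomean <- function(x) exp(mean(log(x)))

#' Inverse of the trigamma function
#'
#' Newton iteration on `trigamma(y) = x`, needed when moment-matching the
#' scaled inverse-chi-square prior of the moderated variance model.
#'
#' @param x Positive numeric vector.
#' @return `y` such that `trigamma(y) = x`; `Inf` where `x <= 0`.
#' @keywords internal
trigamma_inverse <- function(x) {
  out <- rep(NA_real_, length(x))
  out[x <= 0] <- Inf
  idx <- which(x > 0)
  if (!length(idx)) return(out)
  xv <- x[idx]
  y <- 0.5 + 1 / xv  # good starting value for both tails
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / xv) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  out[idx] <- y
  out
}
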