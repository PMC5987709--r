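# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so generators never leak global RNG
#' state; every exported generator routes its randomness through this.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  expr
}

# wrap angle (degrees) into (-180, 180]
wrap_deg <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

# Welch two-sample two-sided p-value, robust to zero-variance groups:
# identical constant groups give p = 1, constant groups with different
# means give p = 0 (t.test() errors on "essentially constant" data).
welch_p <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  nx <- length(x)
  ny <- length(y)
  if (nx < 2L || ny < 2L) return(NA_real_)
  vx <- var(x)
  vy <- var(y)
  se2 <- vx / nx + vy / ny
  d <- mean(x) - mean(y)
  if (se2 <= 0) return(if (d == 0) 1 else 0)
  tstat <- d / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(tstat), df)
}

# one-sample two-sided t-test p-value against mu, same degenerate handling
one_sample_p <- function(x, mu = 0) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  s <- sd(x)
  d <- mean(x) - mu
  if (s == 0) return(if (d == 0) 1 else 0)
  2 * pt(-abs(d / (s / sqrt(n))), n - 1)
}

# standard error of the mean
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  sd(x) / sqrt(length(x))
}

stop_bad <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_finite_num <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_bad("%s must be finite numeric", what)
  }
  invisible(x)
}
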