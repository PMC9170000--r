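# internal helpers shared across modules

#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

# fold a derived seed back into the valid integer range (R seeds are 32-bit)
seed_mod <- function(x) as.integer(as.numeric(x) %% 2147483629)

# evaluate `code` under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# one draw from Inverse-Gamma(shape, rate) parameterised so that
# x ~ IG(a, b)  <=>  1/x ~ Gamma(shape = a, rate = b)
rinvgamma1 <- function(shape, rate) 1 / stats::rgamma(1L, shape = shape, rate = rate)

# draw from N(mean, solve(precision)) given the precision matrix
rmvnorm_prec <- function(precision, location) {
  R <- chol(precision)                       # R'R = precision
  z <- stats::rnorm(length(location))
  location + backsolve(R, z)
}

# solve precision %*% x = b via the same Cholesky factor
solve_prec <- function(precision, b) {
  R <- chol(precision)
  backsolve(R, backsolve(R, b, transpose = TRUE))
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
    abort(sprintf("`%s` must be a single positive integer, got %s.",
                  name, deparse(x)),
          class = "subwaypm_config_error")
  }
  invisible(as.integer(x))
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be strictly positive and finite.", name),
          class = "subwaypm_config_error")
  }
  invisible(x)
}

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
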