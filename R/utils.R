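# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so
#' generators are deterministic without clobbering the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# deterministic per-stage / per-replicate seed derivation; stays < 2^31
derive_seed <- function(seed, offset) {
  s <- (as.numeric(seed) + 7919 * as.numeric(offset)) %% 2147483629
  as.integer(s) + 1L
}

#' Clamp beta values to [0,1], tolerating only float dust
#'
#' Violations of the unit interval by at most `tol` are clamped; anything
#' larger aborts, since it indicates inputs that are not beta values.
#' @noRd
clamp01 <- function(x, tol = 1e-6, what = "beta values") {
  bad <- which(x < -tol | x > 1 + tol)
  if (length(bad) > 0L) {
    stop(sprintf("%s outside [0,1] beyond tolerance %g (%d value(s), e.g. %g)",
                 what, tol, length(bad), x[bad[1]]), call. = FALSE)
  }
  pmin(pmax(x, 0), 1)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  assert_scalar_number(x, name)
  if (x < min || x != floor(x)) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# truncated normal via inverse-CDF so draws are deterministic and vectorized
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

is_beta_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && !is.null(rownames(x)) && !is.null(colnames(x))
}

assert_beta_matrix <- function(x, name = "betas") {
  if (!is_beta_matrix(x)) {
    stop(sprintf(
      "'%s' must be a numeric matrix with CpG ids as rownames and sample ids as colnames",
      name), call. = FALSE)
  }
  invisible(x)
}
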