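#' Validate GMO-EE parameters
#'
#' The GMO-EE distribution is indexed by four parameters: a tilt parameter
#' `alpha` and a mixing parameter `lambda`, both in (0, 1], a rate `theta > 0`
#' (units 1/time) and an exponentiation (shape) parameter `beta > 0`.
#' Setting `lambda = 1` recovers the Marshall-Olkin exponentiated exponential;
#' `alpha = lambda = 1` recovers the exponentiated exponential EE(theta, beta);
#' additionally `beta = 1` gives the exponential with rate `theta`.
#'
#' @param alpha,lambda,theta,beta Numeric scalars.
#' @return A named numeric vector `c(alpha, lambda, theta, beta)`, invisibly
#'   usable anywhere a parameter vector is expected.
#' @examples
#' gmoee_params(0.4, 0.8, 1, 0.5)
#' @export
gmoee_params <- function(alpha, lambda, theta, beta) {
  check_gmoee_params(alpha, lambda, theta, beta)
  c(alpha = alpha, lambda = lambda, theta = theta, beta = beta)
}

check_gmoee_params <- function(alpha, lambda, theta, beta, call = rlang::caller_env()) {
  for (nm in c("alpha", "lambda", "theta", "beta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite numeric value.", nm), call = call)
    }
  }
  if (alpha <= 0 || alpha > 1) {
    abort("`alpha` must lie in (0, 1].", call = call)
  }
  if (lambda <= 0 || lambda > 1) {
    abort("`lambda` must lie in (0, 1].", call = call)
  }
  if (theta <= 0) abort("`theta` must be positive.", call = call)
  if (beta <= 0) abort("`beta` must be positive.", call = call)
  invisible(TRUE)
}

# coerce a length-4 vector / list to the four parameters
as_param_list <- function(eta) {
  if (is.list(eta)) eta <- unlist(eta)
  if (length(eta) != 4L) abort("a GMO-EE parameter vector has four components.")
  nm <- names(eta)
  if (!is.null(nm) && all(c("alpha", "lambda", "theta", "beta") %in% nm)) {
    eta <- eta[c("alpha", "lambda", "theta", "beta")]
  }
  list(alpha = unname(eta[[1]]), lambda = unname(eta[[2]]),
       theta = unname(eta[[3]]), beta = unname(eta[[4]]))
}

param_names <- c("alpha", "lambda", "theta", "beta")

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
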