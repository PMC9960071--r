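#' Construct a fit result
#'
#' Lightweight container shared by all fitting routines: fitted parameters,
#' Jacobian-based standard errors, residual sum of squares, a convergence flag
#' and the number of points fitted. A fit flagged `converged = FALSE` should
#' not be consumed downstream without explicit override.
#'
#' @param params named numeric vector of fitted parameters.
#' @param stderr named numeric vector of standard errors (may be `Inf` when
#'   the covariance is singular).
#' @param residual_norm residual sum of squares.
#' @param converged logical convergence flag.
#' @param n_points number of data points used.
#' @param model short model label ("hill", "ghk", "boltzmann", "multiexp", ...).
#' @param extra optional named list of model-specific extras.
#' @return An object of class `ko_fit`.
#' @export
fit_result <- function(params, stderr, residual_norm, converged, n_points,
                       model = "model", extra = list()) {
  stopifnot(is.numeric(params), length(params) >= 1)
  if (!is.null(names(stderr)) && all(names(params) %in% names(stderr))) {
    stderr <- stderr[names(params)]
  }
  names(stderr) <- names(params)
  stderr[!is.finite(stderr)] <- Inf
  if (any(stderr < 0, na.rm = TRUE)) stop("negative standard error")
  structure(
    c(list(params = params, stderr = stderr,
           residual_norm = as.numeric(residual_norm),
           converged = isTRUE(converged), n_points = as.integer(n_points),
           model = model), extra),
    class = "ko_fit")
}

#' @export
print.ko_fit <- function(x, ...) {
  cat(sprintf("<ko_fit: %s>  n = %d, RSS = %.4g, converged: %s\n",
              x$model, x$n_points, x$residual_norm, x$converged))
  tab <- data.frame(estimate = x$params, std.error = x$stderr)
  print(tab, digits = 4)
  invisible(x)
}

#' Extract coefficients from a fit result
#' @param object a `ko_fit`.
#' @param ... unused.
#' @export
coef.ko_fit <- function(object, ...) object$params

# Shared nonlinear least-squares driver (Levenberg-Marquardt with box
# bounds); returns params/stderr/rss/converged or NULL on hard failure.
.nls_fit <- function(fn, start, y, lower = NULL, upper = NULL,
                     maxiter = 200) {
  resid_fn <- function(par) y - fn(par)
  res <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(res)) return(NULL)
  par <- res$par
  rss <- sum(res$fvec^2)
  dof <- length(y) - length(par)
  stderr <- rep(Inf, length(par))
  names(stderr) <- names(par)
  ok_cov <- FALSE
  if (dof > 0) {
    sigma2 <- rss / dof
    cov <- tryCatch(sigma2 * solve(res$hessian), error = function(e) NULL)
    if (!is.null(cov)) {
      dg <- diag(cov)
      if (all(is.finite(dg)) && all(dg >= -1e-12)) {
        stderr <- sqrt(pmax(dg, 0))
        names(stderr) <- names(par)
        ok_cov <- TRUE
      }
    }
  }
  converged <- res$info %in% 1:4 && ok_cov
  list(params = unlist(par), stderr = stderr, rss = rss,
       converged = converged, niter = res$niter)
}
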