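#' Maximum a posteriori optimization
#'
#' Maximizes the log joint over the unconstrained vector with BFGS using
#' the model's analytic gradient, optionally polished by a second BFGS run
#' from the first solution. Returns the constrained point estimate with the
#' achieved log joint and the gradient norm at the solution.
#'
#' @param model a [joint_posterior].
#' @param init unconstrained start (defaults to the model's init point).
#' @param max_iterations BFGS iteration budget.
#' @param tol relative convergence tolerance passed to [stats::optim].
#' @return list with `par` (constrained values, named list), `z`
#'   (unconstrained optimum), `log_joint`, `grad_norm`, and `converged`.
#' @export
map_optimize <- function(model, init = NULL, max_iterations = 500L,
                         tol = 1e-10) {
  z0 <- if (is.null(init)) model$init else init
  nll <- function(z) -model$log_density(z)
  gnll <- function(z) -model$grad(z)$grad
  fit <- stats::optim(z0, nll, gnll, method = "BFGS",
                      control = list(maxit = max_iterations, reltol = tol))
  # polish: restart once from the solution (BFGS resets its Hessian)
  fit2 <- stats::optim(fit$par, nll, gnll, method = "BFGS",
                       control = list(maxit = max_iterations, reltol = tol))
  if (fit2$value < fit$value) fit <- fit2
  g <- model$grad(fit$par)
  list(par = model$constrain(fit$par), z = fit$par,
       log_joint = -fit$value, grad_norm = sqrt(sum(g$grad^2)),
       converged = fit$convergence == 0L)
}
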