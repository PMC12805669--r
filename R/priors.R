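#' Prior distribution library
#'
#' Small set of priors used by the joint posterior, each providing a log
#' density and its gradient with respect to the constrained value (and any
#' hyperparameter the model also samples). Constructors return `prior`
#' objects with `log_density(x)` and `grad(x)` (`grad` returns `d_x`).
#'
#' @param mean,sd,meanlog,sdlog,shape,rate,alpha usual distribution
#'   parameters.
#' @name priors
NULL

new_prior <- function(name, logd, grad) {
  structure(list(name = name, log_density = logd, grad = grad), class = "prior")
}

#' @rdname priors
#' @export
prior_normal <- function(mean = 0, sd = 1) {
  new_prior("normal",
            function(x) sum(stats::dnorm(x, mean, sd, log = TRUE)),
            function(x) -(x - mean) / sd^2)
}

#' @rdname priors
#' @export
prior_lognormal <- function(meanlog = 0, sdlog = 1) {
  new_prior("lognormal",
            function(x) sum(stats::dlnorm(x, meanlog, sdlog, log = TRUE)),
            function(x) -(log(x) - meanlog) / (sdlog^2 * x) - 1 / x)
}

#' @rdname priors
#' @export
prior_gamma <- function(shape, rate) {
  new_prior("gamma",
            function(x) sum(stats::dgamma(x, shape = shape, rate = rate, log = TRUE)),
            function(x) (shape - 1) / x - rate)
}

#' @rdname priors
#' @export
prior_dirichlet <- function(alpha) {
  new_prior("dirichlet",
            function(x) {
              sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
            },
            function(x) (alpha - 1) / x)
}

#' @rdname priors
#' @export
prior_oneontau <- function() {
  # improper 1/x prior occasionally useful for scale parameters
  new_prior("oneonx", function(x) -sum(log(x)), function(x) -1 / x)
}

#' Bayesian bridge log-density
#'
#' Density `alpha / (2 tau Gamma(1/alpha)) * exp(-|eps/tau|^alpha)` applied
#' independently to each component of `eps`. This is the original bridge
#' formulation used as a shrinkage prior on nonreversible substitution-rate
#' random effects; `alpha = 2` recovers a Gaussian kernel with normalizer
#' `1/(tau sqrt(pi))`, `alpha = 1` a Laplace density.
#'
#' @param eps real vector of random effects.
#' @param tau_b positive global scale.
#' @param alpha exponent in (0, 1] (or up to 2 for the Gaussian limit).
#' @return total log-density over components.
#' @export
bridge_log_density <- function(eps, tau_b, alpha) {
  if (tau_b <= 0) stop("bridge_log_density: tau_b must be positive")
  if (alpha <= 0 || alpha > 2) stop("bridge_log_density: alpha must be in (0, 2]")
  n <- length(eps)
  n * (log(alpha) - log(2 * tau_b) - lgamma(1 / alpha)) - sum(abs(eps / tau_b)^alpha)
}

# gradient w.r.t. eps and tau_b (undefined at eps = 0 for alpha < 1; the
# subgradient 0 is used there, matching the symmetric density)
bridge_log_density_grad <- function(eps, tau_b, alpha) {
  n <- length(eps)
  a <- abs(eps / tau_b)
  d_eps <- ifelse(eps == 0, 0,
                  -alpha * a^(alpha - 1) * sign(eps) / tau_b)
  d_tau <- -n / tau_b + alpha * sum(a^alpha) / tau_b
  list(value = n * (log(alpha) - log(2 * tau_b) - lgamma(1 / alpha)) -
         sum(a^alpha),
       d_eps = d_eps, d_tau = d_tau)
}
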