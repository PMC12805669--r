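#' Gaussian toy posteriors for validating inference engines
#'
#' Small closed-form targets: a conjugate normal-normal model (known
#' observation sd), a plain multivariate standard normal, and a 1-d Gaussian
#' mixture. Each is a full [joint_posterior], so every inference engine can
#' be exercised against analytic answers.
#'
#' @param prior_mean,prior_sd prior on the latent mean.
#' @param obs_sd known observation standard deviation.
#' @param data observed values.
#' @return a [joint_posterior]; conjugate models also carry
#'   `$posterior_mean`, `$posterior_sd`, and `$log_evidence`.
#' @export
toy_conjugate_model <- function(prior_mean = 0, prior_sd = 1, obs_sd = 1,
                                data = numeric(0)) {
  lik <- list(
    params = "likelihood",
    value = function(x) sum(stats::dnorm(data, x$mu, obs_sd, log = TRUE)),
    grad = function(x) list(
      value = sum(stats::dnorm(data, x$mu, obs_sd, log = TRUE)),
      grads = list(mu = sum(data - x$mu) / obs_sd^2))
  )
  model <- joint_posterior(
    list(param_block("mu", make_transform("identity", 1L),
                     prior = prior_normal(prior_mean, prior_sd))),
    if (length(data)) list(lik) else list())
  n <- length(data)
  post_prec <- 1 / prior_sd^2 + n / obs_sd^2
  model$posterior_sd <- sqrt(1 / post_prec)
  model$posterior_mean <- (prior_mean / prior_sd^2 + sum(data) / obs_sd^2) / post_prec
  # marginal likelihood: y ~ N(prior_mean, obs_sd^2 I + prior_sd^2 J)
  if (n > 0) {
    S <- diag(obs_sd^2, n) + prior_sd^2
    model$log_evidence <- as.numeric(
      -0.5 * (n * log(2 * pi) + determinant(S)$modulus +
                t(data - prior_mean) %*% solve(S, data - prior_mean)))
  }
  model
}

#' @rdname toy_conjugate_model
#' @param d dimension.
#' @export
toy_standard_normal <- function(d = 1L) {
  joint_posterior(list(param_block(
    "z", make_transform("identity", d), prior = prior_normal(0, 1))))
}

#' @rdname toy_conjugate_model
#' @param means,sds,weights mixture component parameters.
#' @export
toy_mixture_model <- function(means = c(-3, 3), sds = c(1, 1),
                              weights = c(0.5, 0.5)) {
  weights <- weights / sum(weights)
  mix <- list(
    params = "mixture",
    value = function(x) {
      log(sum(weights * stats::dnorm(x$z, means, sds)))
    },
    grad = function(x) {
      comp <- weights * stats::dnorm(x$z, means, sds)
      dens <- sum(comp)
      list(value = log(dens),
           grads = list(z = sum(comp * (means - x$z) / sds^2) / dens))
    }
  )
  joint_posterior(list(param_block("z", make_transform("identity", 1L))),
                  list(mix))
}
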