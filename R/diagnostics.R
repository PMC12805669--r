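#' Coefficient-of-variation convergence series
#'
#' Tracks how fast an approximation settles by comparing the running
#' coefficient of variation at each checkpoint with its final value. For
#' variational inference the running mean and variance are the cumulative
#' averages of the per-checkpoint variational moments,
#' `CV(t_i) = sqrt(mean(sigma^2_{1..i})) / mean(mu_{1..i})`; for MCMC,
#' `CV(t_i)` is the sample sd over sample mean of draws `1..i`.
#'
#' @param means per-checkpoint variational means `mu(t_j)`.
#' @param variances per-checkpoint variational variances `sigma^2(t_j)`.
#' @param checkpoints optional checkpoint labels (e.g. iteration numbers,
#'   every 1000 iterations by convention).
#' @return an object of class `cv_series`: data.frame with `checkpoint`,
#'   `cv`, and `sq_deviation` = `(CV(t_i) - CV(t_M))^2`.
#' @export
cv_series_vi <- function(means, variances, checkpoints = seq_along(means)) {
  if (length(means) != length(variances)) {
    stop("cv_series_vi: means and variances differ in length")
  }
  i <- seq_along(means)
  mu_bar <- cumsum(means) / i
  var_bar <- cumsum(variances) / i
  if (any(mu_bar == 0)) stop("cv_series_vi: running mean is zero; CV undefined")
  cv <- sqrt(var_bar) / mu_bar
  out <- data.frame(checkpoint = checkpoints, cv = cv,
                    sq_deviation = (cv - cv[length(cv)])^2)
  class(out) <- c("cv_series", "data.frame")
  out
}

#' @rdname cv_series_vi
#' @param samples ordered MCMC draws of one parameter.
#' @param every evaluate CV at checkpoints `every, 2*every, ...`.
#' @export
cv_series_mcmc <- function(samples, every = 1000L) {
  n <- length(samples)
  cks <- seq(every, n, by = every)
  if (length(cks) == 0L || cks[length(cks)] != n) cks <- c(cks, n)
  cks <- cks[cks >= 2L]
  cv <- vapply(cks, function(i) {
    m <- mean(samples[seq_len(i)])
    if (m == 0) stop("cv_series_mcmc: running mean is zero; CV undefined")
    stats::sd(samples[seq_len(i)]) / m
  }, 0)
  out <- data.frame(checkpoint = cks, cv = cv,
                    sq_deviation = (cv - cv[length(cv)])^2)
  class(out) <- c("cv_series", "data.frame")
  out
}

#' Savage-Dickey Bayes factor for a point-null hypothesis
#'
#' For a null value nested at 0, `BF10 = prior(0) / posterior(0)`: a
#' posterior that moves density away from 0 yields a Bayes factor favoring
#' the unrestricted (e.g. nonreversible) model. The posterior marginal can
#' be a fitted Gaussian (`mean`, `sd`) or a set of samples evaluated by a
#' Gaussian kernel density estimate at 0.
#'
#' @param prior_at_0 prior density at the null point (positive).
#' @param posterior_mean,posterior_sd Gaussian posterior marginal.
#' @param samples posterior draws (alternative to the Gaussian marginal).
#' @return an object of class `bayes_factor`: list with `log_bf10`,
#'   `prior_at_0`, `posterior_at_0`, `method`.
#' @export
savage_dickey_bf <- function(prior_at_0, posterior_mean = NULL,
                             posterior_sd = NULL, samples = NULL) {
  if (prior_at_0 <= 0) stop("savage_dickey_bf: prior density must be positive")
  if (!is.null(samples)) {
    if (length(samples) < 10L) stop("savage_dickey_bf: need at least 10 samples")
    bw <- stats::bw.nrd0(samples)
    post0 <- mean(stats::dnorm(0, samples, bw))
    method <- "kde"
  } else {
    if (is.null(posterior_mean) || is.null(posterior_sd) || posterior_sd <= 0) {
      stop("savage_dickey_bf: need posterior mean and positive sd, or samples")
    }
    post0 <- stats::dnorm(0, posterior_mean, posterior_sd)
    method <- "gaussian_marginal"
  }
  structure(list(log_bf10 = log(prior_at_0) - log(post0),
                 prior_at_0 = prior_at_0, posterior_at_0 = post0,
                 method = method),
            class = "bayes_factor")
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat(sprintf("Savage-Dickey log BF10 = %.4g (%s; prior0 = %.4g, post0 = %.4g)\n",
              x$log_bf10, x$method, x$prior_at_0, x$posterior_at_0))
  invisible(x)
}

#' Marginal bridge prior density at zero
#'
#' Monte-Carlo estimate of the prior density at 0 of a single bridge random
#' effect and of the difference of two independent effects, marginalized
#' over the global scale `tau_b` with `tau_b^(-alpha) ~ Gamma(delta,
#' scale = theta_s)`. Conditional on `tau_b` the single-effect density at 0
#' is the bridge normalizer `alpha / (2 tau_b Gamma(1/alpha))` and the
#' difference density at 0 is `2^(-1/alpha)` times it, so the closed forms
#' `alpha theta_s^(1/alpha) Gamma(delta + 1/alpha) / (2 Gamma(1/alpha)
#' Gamma(delta))` (single) and its `2^(-1/alpha)` multiple (difference) are
#' also returned for cross-checking.
#'
#' @param alpha bridge exponent.
#' @param delta,theta_s gamma hyperprior shape and scale on `tau_b^(-alpha)`.
#' @param n_mc Monte-Carlo draws.
#' @return list with `single_mc`, `single_exact`, `difference_mc`,
#'   `difference_exact`, and the Monte-Carlo standard errors.
#' @export
bridge_difference_prior_at_zero <- function(alpha = 0.25, delta = 1,
                                            theta_s = 2, n_mc = 1e6) {
  nu <- stats::rgamma(n_mc, shape = delta, scale = theta_s)
  tau <- nu^(-1 / alpha)
  base <- alpha / (2 * tau * gamma(1 / alpha))
  single_exact <- alpha * theta_s^(1 / alpha) * gamma(delta + 1 / alpha) /
    (2 * gamma(1 / alpha) * gamma(delta))
  list(single_mc = mean(base),
       single_se = stats::sd(base) / sqrt(n_mc),
       single_exact = single_exact,
       difference_mc = mean(2^(-1 / alpha) * base),
       difference_se = stats::sd(2^(-1 / alpha) * base) / sqrt(n_mc),
       difference_exact = 2^(-1 / alpha) * single_exact)
}

#' Posterior summaries (median, mean, sd, 50% and 95% intervals)
#'
#' For matrices of posterior draws, columnwise empirical quantiles; for a
#' fitted Gaussian variational family, closed-form Gaussian quantiles on
#' the unconstrained scale pushed through each block's transform when that
#' transform is monotone per coordinate (identity, log, logistic), and
#' Monte-Carlo draws otherwise (simplex, height ratios).
#'
#' @param x a samples matrix (columns = parameters) or a `vi_family`.
#' @param model required when `x` is a family: the [joint_posterior] whose
#'   blocks define the transforms.
#' @param n_mc Monte-Carlo draws for non-monotone blocks.
#' @return data.frame with one row per parameter.
#' @export
summarize_posterior <- function(x, model = NULL, n_mc = 4000L) {
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    if (nrow(x) < 10L) stop("summarize_posterior: need at least 10 samples")
    out <- data.frame(
      parameter = colnames(x) %||% paste0("p", seq_len(ncol(x))),
      mean = colMeans(x), sd = apply(x, 2, stats::sd),
      t(apply(x, 2, stats::quantile, probs = qs, names = FALSE)))
    names(out)[4:8] <- c("q2.5", "q25", "median", "q75", "q97.5")
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(inherits(x, "vi_family"), !is.null(model))
  monotone <- c("identity", "log_positive", "logistic_unit")
  rows <- list()
  for (b in model$blocks) {
    idx <- model$offsets[b$name] + seq_len(model$dims[b$name])
    if (b$kind == "transform" && b$transform$kind %in% monotone &&
        x$kind == "mean_field") {
      mu <- x$mu[idx]; sd <- exp(x$log_sigma[idx])
      push <- switch(b$transform$kind, identity = identity,
                     log_positive = exp, logistic_unit = stats::plogis)
      qmat <- matrix(vapply(qs, function(p) push(stats::qnorm(p, mu, sd)),
                            numeric(length(idx))), nrow = length(idx))
      mean_ <- switch(b$transform$kind,
                      identity = mu,
                      log_positive = exp(mu + sd^2 / 2),
                      logistic_unit = NA_real_)
      sd_ <- switch(b$transform$kind,
                    identity = sd,
                    log_positive = sqrt((exp(sd^2) - 1)) * exp(mu + sd^2 / 2),
                    logistic_unit = NA_real_)
      rows[[b$name]] <- data.frame(
        parameter = if (length(idx) == 1L) b$name else
          paste0(b$name, ".", seq_along(idx)),
        mean = mean_, sd = sd_,
        q2.5 = qmat[, 1], q25 = qmat[, 2], median = qmat[, 3],
        q75 = qmat[, 4], q97.5 = qmat[, 5])
    } else {
      zs <- vi_sample(x, n_mc)$z
      vals <- t(apply(zs, 1, function(z) {
        v <- model$constrain(z)[[b$name]]
        v
      }))
      cn <- if (ncol(vals) == 1L) b$name else
        paste0(b$name, ".", seq_len(ncol(vals)))
      qmat <- t(apply(vals, 2, stats::quantile, probs = qs, names = FALSE))
      rows[[b$name]] <- data.frame(
        parameter = cn, mean = colMeans(vals), sd = apply(vals, 2, stats::sd),
        q2.5 = qmat[, 1], q25 = qmat[, 2], median = qmat[, 3],
        q75 = qmat[, 4], q97.5 = qmat[, 5])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
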