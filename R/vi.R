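#' Variational families over the unconstrained parameter vector
#'
#' Gaussian approximations on the unconstrained scale: `mean_field` is a
#' fully factorized Gaussian with parameters (mu, log_sigma); `full_rank`
#' is a multivariate Gaussian N(mu, L L') with the Cholesky factor's
#' diagonal stored on the log scale. Both expose sampling by the
#' reparameterization trick, their own log-density, the score
#' (gradient of log q w.r.t. the variational parameters phi), and packing
#' helpers used by the optimizer.
#'
#' @param d dimension of the unconstrained space.
#' @param mu initial mean.
#' @param log_sigma initial per-coordinate log standard deviations.
#' @return an object of class `vi_family`.
#' @export
mean_field_gaussian <- function(d, mu = numeric(d), log_sigma = rep(-1, d)) {
  fam <- list(kind = "mean_field", d = d, mu = mu, log_sigma = log_sigma)
  class(fam) <- "vi_family"
  fam
}

#' @rdname mean_field_gaussian
#' @param L lower-triangular Cholesky factor (diagonal > 0).
#' @export
full_rank_gaussian <- function(d, mu = numeric(d), L = diag(exp(-1), d)) {
  fam <- list(kind = "full_rank", d = d, mu = mu, L = L)
  class(fam) <- "vi_family"
  fam
}

#' Initialize a full-rank family from a fitted mean-field one
#'
#' Off-diagonal covariances start at 0, so the full-rank family is exactly
#' the optimized mean-field distribution at initialization.
#'
#' @param mf a fitted `mean_field` family.
#' @export
full_rank_from_mean_field <- function(mf) {
  stopifnot(mf$kind == "mean_field")
  full_rank_gaussian(mf$d, mu = mf$mu, L = diag(exp(mf$log_sigma), mf$d))
}

# ---- family primitives -------------------------------------------------

vi_sample <- function(fam, n = 1L) {
  eps <- matrix(stats::rnorm(n * fam$d), n, fam$d)
  z <- if (fam$kind == "mean_field") {
    sweep(eps, 2, exp(fam$log_sigma), `*`) + rep(fam$mu, each = n)
  } else {
    eps %*% t(fam$L) + rep(fam$mu, each = n)
  }
  list(z = z, eps = eps)
}

vi_log_density <- function(fam, z) {
  if (is.null(dim(z))) z <- matrix(z, 1L)
  if (fam$kind == "mean_field") {
    sig <- exp(fam$log_sigma)
    apply(z, 1, function(r) sum(stats::dnorm(r, fam$mu, sig, log = TRUE)))
  } else {
    apply(z, 1, function(r) {
      a <- forwardsolve(fam$L, r - fam$mu)
      -0.5 * sum(a^2) - sum(log(diag(fam$L))) - fam$d / 2 * log(2 * pi)
    })
  }
}

# score function: gradient of log q(z; phi) w.r.t. packed phi, one row per z
vi_score <- function(fam, z) {
  if (is.null(dim(z))) z <- matrix(z, 1L)
  n <- nrow(z)
  if (fam$kind == "mean_field") {
    sig2 <- exp(2 * fam$log_sigma)
    d_mu <- sweep(z, 2, fam$mu, `-`) / rep(sig2, each = n)
    d_ls <- sweep(z, 2, fam$mu, `-`)^2 / rep(sig2, each = n) - 1
    cbind(d_mu, d_ls)
  } else {
    t(vapply(seq_len(n), function(i) {
      a <- forwardsolve(fam$L, z[i, ] - fam$mu)
      d_mu <- backsolve(t(fam$L), a)
      G <- t(solve(fam$L)) %*% (a %o% a - diag(fam$d))
      G[upper.tri(G)] <- 0
      diag(G) <- diag(G) * diag(fam$L)   # chain rule for log-diagonal
      c(d_mu, G[lower.tri(G, diag = TRUE)])
    }, numeric(vi_n_params(fam))))
  }
}

vi_n_params <- function(fam) {
  if (fam$kind == "mean_field") 2L * fam$d else fam$d + fam$d * (fam$d + 1L) / 2L
}

vi_pack <- function(fam) {
  if (fam$kind == "mean_field") c(fam$mu, fam$log_sigma) else {
    L <- fam$L
    diag(L) <- log(diag(L))
    c(fam$mu, L[lower.tri(L, diag = TRUE)])
  }
}

vi_unpack <- function(fam, phi) {
  if (fam$kind == "mean_field") {
    fam$mu <- phi[seq_len(fam$d)]
    fam$log_sigma <- phi[fam$d + seq_len(fam$d)]
  } else {
    fam$mu <- phi[seq_len(fam$d)]
    L <- matrix(0, fam$d, fam$d)
    L[lower.tri(L, diag = TRUE)] <- phi[-seq_len(fam$d)]
    diag(L) <- exp(diag(L))
    fam$L <- L
  }
  fam
}

# ---- objectives --------------------------------------------------------

#' Monte-Carlo ELBO estimate
#'
#' `(1/n) sum [log p(z_s, D) - log q(z_s)]` with `z_s` drawn by the
#' reparameterization trick. Unbiased for the true evidence lower bound;
#' the default single sample matches common ADVI practice.
#'
#' @param fam a `vi_family`.
#' @param model a [joint_posterior].
#' @param n_samples Monte-Carlo sample count (default 1).
#' @return the ELBO estimate (a single real).
#' @export
elbo_estimate <- function(fam, model, n_samples = 1L) {
  s <- vi_sample(fam, n_samples)
  lp <- apply(s$z, 1, model$log_density)
  if (any(!is.finite(lp))) stop("elbo_estimate: non-finite log joint in sample")
  mean(lp - vi_log_density(fam, s$z))
}

#' Pathwise (reparameterization) gradient of the ELBO
#'
#' Differentiates the single-sample ELBO through `z = mu + sigma * eps`
#' (or `mu + L eps`), using the model's analytic gradient. The full
#' Monte-Carlo entropy form is used, so the same estimator serves both
#' families; the score-function terms of log q cancel for mu and reduce to
#' +1 for the log-scale coordinates.
#'
#' @inheritParams elbo_estimate
#' @return list with `value` (ELBO estimate) and `grad` (w.r.t. packed phi).
#' @export
elbo_gradient <- function(fam, model, n_samples = 1L) {
  s <- vi_sample(fam, n_samples)
  n <- n_samples
  gphi <- numeric(vi_n_params(fam))
  val <- 0
  for (i in seq_len(n)) {
    z <- s$z[i, ]
    eps <- s$eps[i, ]
    gr <- model$grad(z)
    val <- val + gr$value - vi_log_density(fam, z)
    if (fam$kind == "mean_field") {
      # d/dmu = grad log p; d/dlog_sigma = grad log p * sigma*eps + 1
      gphi <- gphi + c(gr$grad, gr$grad * exp(fam$log_sigma) * eps + 1)
    } else {
      GL <- gr$grad %o% eps
      diag(GL) <- diag(GL) * diag(fam$L) + 1   # log-diag chain + entropy
      gphi <- gphi + c(gr$grad, GL[lower.tri(GL, diag = TRUE)])
    }
  }
  list(value = val / n, grad = gphi / n)
}

#' Self-normalized importance sampling batch
#'
#' Draws `S` samples from the variational distribution, computes raw
#' importance log-ratios `log p~(z) - log q(z)` against the unnormalized
#' posterior, normalizes the weights with a single log-sum-exp shift, and
#' reports the SNIS estimate of the forward KL divergence KL(p||q) with the
#' normalizing-constant estimate removed, plus the effective sample size
#' `1 / sum(w^2)`.
#'
#' @param fam a `vi_family`.
#' @param model a [joint_posterior].
#' @param S number of importance samples (>= 2; 10 is the usual default).
#' @return an object of class `snis_batch` with `z`, `log_ratios`,
#'   `weights`, `ess`, and `kl_report`.
#' @export
snis_batch <- function(fam, model, S = 10L) {
  if (S < 2L) stop("snis_batch: S must be >= 2")
  s <- vi_sample(fam, S)
  lp <- apply(s$z, 1, model$log_density)
  lq <- vi_log_density(fam, s$z)
  lr <- lp - lq
  if (all(!is.finite(lr))) stop("snis_batch: degenerate batch (all weights invalid)")
  m <- max(lr)
  w <- exp(lr - m)
  w <- w / sum(w)
  if (any(!is.finite(w))) stop("snis_batch: degenerate batch")
  log_norm <- m + log(mean(exp(lr - m)))   # log (1/S) sum p~/q
  structure(list(z = s$z, log_ratios = lr, weights = w,
                 ess = 1 / sum(w^2),
                 kl_report = sum(w * lr) - log_norm),
            class = "snis_batch")
}

#' SNIS gradient of the forward KL objective
#'
#' `-sum_s w_s grad_phi log q(z_s; phi)` with samples and weights treated
#' as constants: the estimator needs only the variational score, never the
#' model gradient.
#'
#' @param batch an `snis_batch`.
#' @param fam the `vi_family` the batch was drawn from.
#' @return gradient of `L_KL` w.r.t. packed phi (descent direction for
#'   minimization).
#' @export
forward_kl_gradient <- function(batch, fam) {
  sc <- vi_score(fam, batch$z)
  -as.numeric(t(sc) %*% batch$weights)
}

# ---- optimization loop -------------------------------------------------

#' Fit a variational approximation
#'
#' Adam-style first-order optimization of either the ELBO (maximized, via
#' the pathwise gradient) or the forward KL divergence (minimized, via the
#' gradient-free SNIS estimator). Checkpoints record the running objective
#' estimate; the fit is deterministic given the seed.
#'
#' @param model a [joint_posterior].
#' @param objective `"elbo"` or `"forward_kl"`.
#' @param family `"mean_field"` or `"full_rank"`, or an existing
#'   `vi_family` to continue from (e.g. [full_rank_from_mean_field]).
#' @param iterations optimization steps.
#' @param learning_rate Adam step size (defaults: 0.1 mean-field, 1e-5
#'   full-rank).
#' @param samples_per_step Monte-Carlo samples per step (default 1 for
#'   ELBO, 10 for forward KL).
#' @param seed RNG seed.
#' @param init unconstrained initialization for mu (defaults to the model's
#'   init point).
#' @param init_log_sigma initial log stdev for a fresh family.
#' @param checkpoint_every checkpoint interval in iterations.
#' @param polyak fraction of final iterations whose variational parameters
#'   are averaged into the returned family (Polyak-Ruppert averaging, which
#'   removes the stationary wander of a constant-step stochastic optimizer);
#'   0 disables averaging and returns the last iterate.
#' @return list with `family` (fitted), `trace` (data.frame of checkpoints:
#'   iteration, objective value, mean/sd summaries), and `objective`.
#' @export
fit_vi <- function(model, objective = c("elbo", "forward_kl"),
                   family = "mean_field", iterations = 5000L,
                   learning_rate = NULL, samples_per_step = NULL,
                   seed = 1L, init = NULL, init_log_sigma = -2,
                   checkpoint_every = 1000L, polyak = 0.25) {
  objective <- match.arg(objective)
  if (is.character(family)) {
    d <- model$dim
    mu0 <- if (is.null(init)) model$init else init
    fam <- if (family == "mean_field") {
      mean_field_gaussian(d, mu = mu0, log_sigma = rep(init_log_sigma, d))
    } else {
      full_rank_gaussian(d, mu = mu0, L = diag(exp(init_log_sigma), d))
    }
  } else {
    fam <- family
  }
  if (is.null(learning_rate)) {
    learning_rate <- if (fam$kind == "mean_field") 0.1 else 1e-5
  }
  if (is.null(samples_per_step)) {
    samples_per_step <- if (objective == "elbo") 1L else 10L
  }
  set.seed(seed)
  phi <- vi_pack(fam)
  mom1 <- numeric(length(phi))
  mom2 <- numeric(length(phi))
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  trace <- list()
  ck <- 0L
  avg_from <- if (polyak > 0) iterations - floor(polyak * iterations) + 1L else
    iterations + 1L
  phi_avg <- numeric(length(phi))
  n_avg <- 0L
  for (it in seq_len(iterations)) {
    fam <- vi_unpack(fam, phi)
    step <- tryCatch({
      if (objective == "elbo") {
        g <- elbo_gradient(fam, model, samples_per_step)
        list(obj = g$value, dir = g$grad)        # ascend
      } else {
        b <- snis_batch(fam, model, samples_per_step)
        list(obj = b$kl_report, dir = -forward_kl_gradient(b, fam))  # descend L_KL
      }
    }, error = function(e) e)
    if (inherits(step, "error")) {
      stop("fit_vi: objective failed at iteration ", it, ": ",
           conditionMessage(step))
    }
    if (!is.finite(step$obj) || any(!is.finite(step$dir))) {
      stop("fit_vi: non-finite objective/gradient at iteration ", it)
    }
    mom1 <- b1 * mom1 + (1 - b1) * step$dir
    mom2 <- b2 * mom2 + (1 - b2) * step$dir^2
    hat1 <- mom1 / (1 - b1^it)
    hat2 <- mom2 / (1 - b2^it)
    phi <- phi + learning_rate * hat1 / (sqrt(hat2) + adam_eps)
    if (it >= avg_from) {
      n_avg <- n_avg + 1L
      phi_avg <- phi_avg + (phi - phi_avg) / n_avg
    }
    if (it %% checkpoint_every == 0L || it == iterations) {
      ck <- ck + 1L
      fam_ck <- vi_unpack(fam, phi)
      trace[[ck]] <- data.frame(
        iteration = it, objective = step$obj,
        mu_mean = mean(fam_ck$mu),
        sigma_mean = if (fam_ck$kind == "mean_field")
          mean(exp(fam_ck$log_sigma)) else mean(diag(fam_ck$L)))
    }
  }
  fam <- vi_unpack(fam, if (n_avg > 0L) phi_avg else phi)
  trace <- do.call(rbind, trace)
  names(trace)[2] <- objective
  list(family = fam, trace = trace, objective = objective)
}
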