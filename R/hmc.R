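#' Leapfrog integration of Hamiltonian dynamics
#'
#' Velocity-Verlet (leapfrog) steps on the Hamiltonian
#' `-log p(z) + p' M^-1 p / 2` with diagonal mass `M`. Time-reversible and
#' symplectic: integrating, negating the momentum, and integrating again
#' returns to the start, and the energy error vanishes as the step size
#' goes to 0.
#'
#' @param model a [joint_posterior].
#' @param z,p position and momentum.
#' @param eps step size.
#' @param n_steps number of leapfrog steps.
#' @param mass diagonal of the mass matrix.
#' @param gr optional precomputed `model$grad(z)`.
#' @return list with `ok`, `z`, `p`, and `gr` (gradient at the end point).
#' @export
leapfrog_integrate <- function(model, z, p, eps, n_steps, mass = rep(1, length(z)),
                               gr = NULL) {
  safe_grad <- function(zz) {
    g <- tryCatch(model$grad(zz), error = function(e) NULL)
    if (is.null(g) || !is.finite(g$value) || any(!is.finite(g$grad))) NULL else g
  }
  if (is.null(gr)) gr <- safe_grad(z)
  if (is.null(gr)) return(list(ok = FALSE))
  p <- p + 0.5 * eps * gr$grad
  for (l in seq_len(n_steps)) {
    z <- z + eps * p / mass
    gr <- safe_grad(z)
    if (is.null(gr)) return(list(ok = FALSE))
    if (l < n_steps) p <- p + eps * gr$grad
  }
  p <- p + 0.5 * eps * gr$grad
  list(ok = TRUE, z = z, p = p, gr = gr)
}

#' Hamiltonian Monte Carlo on the unconstrained posterior
#'
#' Leapfrog integration with a Metropolis accept/reject correction. During
#' warmup the step size is adapted by dual averaging toward a target
#' acceptance probability of 0.8, and the diagonal mass matrix is set to
#' the inverse sample variances of the second half of warmup. Post-warmup
#' draws are transformed back to the constrained scale.
#'
#' @param model a [joint_posterior].
#' @param iterations post-warmup draws.
#' @param warmup warmup iterations (adaptation only, discarded).
#' @param n_leapfrog leapfrog steps per trajectory (fixed; default 10).
#' @param step_size initial leapfrog step size.
#' @param jitter relative step-size jitter per trajectory (uniform on
#'   `eps * (1 +/- jitter)`), which breaks the resonances a fixed
#'   trajectory length can hit on near-Gaussian targets.
#' @param target_accept dual-averaging target acceptance rate.
#' @param seed RNG seed.
#' @param init unconstrained start (defaults to the model's init point).
#' @return list with `samples` (matrix of constrained draws, named columns),
#'   `unconstrained` (matrix), `accept_rate`, `divergences`, `step_size`,
#'   and `mass_diag`.
#' @export
hmc_sample <- function(model, iterations = 1000L, warmup = 500L,
                       n_leapfrog = 10L, step_size = 0.1,
                       target_accept = 0.8, seed = 1L, init = NULL,
                       jitter = 0.15) {
  set.seed(seed)
  d <- model$dim
  z <- if (is.null(init)) model$init else init
  gr <- model$grad(z)
  mass <- rep(1, d)   # diagonal mass matrix (momentum covariance)
  # dual averaging state (Hoffman & Gelman 2014 defaults)
  eps <- step_size
  mu_da <- log(10 * eps)
  log_eps_bar <- 0
  H_bar <- 0
  gamma_da <- 0.05; t0 <- 10; kappa_da <- 0.75
  warm_store <- matrix(NA_real_, warmup, d)
  draws <- matrix(NA_real_, iterations, d)
  divergences <- 0L
  accepts <- 0L

  leapfrog <- function(z, p, eps, gr) {
    leapfrog_integrate(model, z, p, eps, n_leapfrog, mass, gr)
  }

  total <- warmup + iterations
  for (it in seq_len(total)) {
    p0 <- stats::rnorm(d, 0, sqrt(mass))
    H0 <- -gr$value + 0.5 * sum(p0^2 / mass)
    eps_it <- eps * stats::runif(1, 1 - jitter, 1 + jitter)
    prop <- leapfrog(z, p0, eps_it, gr)
    alpha <- 0
    if (prop$ok) {
      H1 <- -prop$gr$value + 0.5 * sum(prop$p^2 / mass)
      dH <- H1 - H0
      if (!is.finite(dH) || dH > 1000) {
        divergences <- divergences + 1L
      } else {
        alpha <- min(1, exp(-dH))
        if (stats::runif(1) < alpha) {
          z <- prop$z
          gr <- prop$gr
          if (it > warmup) accepts <- accepts + 1L
        }
      }
    } else if (it <= warmup) {
      divergences <- divergences + 1L
    } else {
      divergences <- divergences + 1L
    }
    if (it <= warmup) {
      # dual averaging on the acceptance statistic
      m <- it
      H_bar <- (1 - 1 / (m + t0)) * H_bar + (target_accept - alpha) / (m + t0)
      log_eps <- mu_da - sqrt(m) / gamma_da * H_bar
      w <- m^(-kappa_da)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      warm_store[it, ] <- z
      if (it == warmup) {
        eps <- exp(log_eps_bar)
        half <- warm_store[seq(floor(warmup / 2) + 1, warmup), , drop = FALSE]
        v <- apply(half, 2, stats::var)
        v[!is.finite(v) | v < 1e-10] <- 1
        mass <- 1 / v
      }
    } else {
      draws[it - warmup, ] <- z
    }
  }
  constrained <- do.call(rbind, lapply(seq_len(iterations), function(i) {
    flatten_constrained(model$constrain(draws[i, ]))
  }))
  list(samples = constrained, unconstrained = draws,
       accept_rate = accepts / iterations, divergences = divergences,
       step_size = eps, mass_diag = mass)
}
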