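analytic_elbo_gaussian <- function(m, s) {
  # ELBO of q = N(m, s^2) against an (unnormalized = normalized) N(0,1)
  # target: -KL(q || N(0,1))
  -(-log(s) + (s^2 + m^2 - 1) / 2)
}

test_that("the ELBO estimator is unbiased on Gaussian targets", {
  model <- toy_standard_normal(1)
  set.seed(71)
  # q equal to the target: ELBO is exactly 0 in expectation
  q <- mean_field_gaussian(1, mu = 0, log_sigma = 0)
  est <- replicate(5000, elbo_estimate(q, model, 1))
  expect_lt(abs(mean(est)), 3 * sd(est) / sqrt(length(est)) + 1e-12)

  # q = N(m, s): closed-form Gaussian KL oracle
  q2 <- mean_field_gaussian(1, mu = 0.7, log_sigma = log(1.4))
  est2 <- replicate(8000, elbo_estimate(q2, model, 1))
  expect_lt(abs(mean(est2) - analytic_elbo_gaussian(0.7, 1.4)),
            3 * sd(est2) / sqrt(length(est2)))
})

test_that("the ELBO of the exact posterior equals the log evidence", {
  set.seed(72)
  y <- rnorm(12, 0.8, 1)
  toy <- toy_conjugate_model(0, 1.5, 1, y)
  q <- mean_field_gaussian(1, mu = toy$posterior_mean,
                           log_sigma = log(toy$posterior_sd))
  est <- replicate(4000, elbo_estimate(q, toy, 1))
  expect_lt(abs(mean(est) - toy$log_evidence), 3 * sd(est) / sqrt(4000))
  # and the ELBO never exceeds the evidence at other q
  q2 <- mean_field_gaussian(1, mu = toy$posterior_mean + 0.5,
                            log_sigma = log(2 * toy$posterior_sd))
  est2 <- replicate(4000, elbo_estimate(q2, toy, 1))
  expect_lt(mean(est2), toy$log_evidence + 3 * sd(est2) / sqrt(4000))
})

test_that("the pathwise ELBO gradient is correct and centered at the optimum", {
  model <- toy_standard_normal(1)
  set.seed(73)
  # d ELBO / d m = -m in expectation; check at m = 2
  q <- mean_field_gaussian(1, mu = 2, log_sigma = 0)
  gs <- replicate(6000, elbo_gradient(q, model, 1)$grad[1])
  expect_lt(abs(mean(gs) + 2), 3 * sd(gs) / sqrt(length(gs)))

  # at the exact posterior of the conjugate toy the expected gradient is 0
  set.seed(74)
  y <- rnorm(10, -0.4, 1)
  toy <- toy_conjugate_model(0, 1, 1, y)
  qstar <- mean_field_gaussian(1, mu = toy$posterior_mean,
                               log_sigma = log(toy$posterior_sd))
  g2 <- replicate(8000, elbo_gradient(qstar, toy, 1)$grad)
  for (j in 1:2) {
    expect_lt(abs(mean(g2[j, ])), 3 * sd(g2[j, ]) / sqrt(ncol(g2)))
  }

  # common-random-number finite differences at a random phi
  q3 <- mean_field_gaussian(2, mu = c(0.3, -1), log_sigma = c(-0.5, 0.2))
  model3 <- toy_standard_normal(2)
  set.seed(75)
  g3 <- elbo_gradient(q3, model3, 1)
  phi <- c(q3$mu, q3$log_sigma)
  fd <- fd_gradient(function(ph) {
    qq <- mean_field_gaussian(2, mu = ph[1:2], log_sigma = ph[3:4])
    set.seed(75)
    elbo_estimate(qq, model3, 1)
  }, phi, h = 1e-6)
  expect_equal(g3$grad, fd, tolerance = 1e-4)
})

test_that("full-rank families: density, sampling, and ELBO gradient agree", {
  set.seed(76)
  L <- matrix(c(1.2, 0, 0.4, 0.8), 2, 2, byrow = FALSE)
  L[upper.tri(L)] <- 0
  q <- full_rank_gaussian(2, mu = c(0.5, -0.3), L = L)
  z <- glidetree:::vi_sample(q, 5000)$z
  S <- L %*% t(L)
  expect_lt(max(abs(cov(z) - S)), 0.1)
  # density matches the closed-form bivariate normal
  lq <- glidetree:::vi_log_density(q, c(0.2, 0.1))
  d <- c(0.2, 0.1) - q$mu
  expect_equal(lq, -0.5 * t(d) %*% solve(S, d) - 0.5 * determinant(S)$modulus[1] -
                 log(2 * pi), tolerance = 1e-10, ignore_attr = TRUE)
  # pathwise gradient vs common-random-number finite differences
  model <- toy_standard_normal(2)
  set.seed(77)
  g <- elbo_gradient(q, model, 1)
  phi <- glidetree:::vi_pack(q)
  fd <- fd_gradient(function(ph) {
    qq <- glidetree:::vi_unpack(q, ph)
    set.seed(77)
    elbo_estimate(qq, model, 1)
  }, phi, h = 1e-6)
  expect_equal(g$grad, fd, tolerance = 1e-4)
  # initialization from a fitted mean-field is exactly that distribution
  mf <- mean_field_gaussian(3, mu = c(1, 2, 3), log_sigma = c(-1, 0, 0.5))
  fr <- full_rank_from_mean_field(mf)
  zz <- matrix(rnorm(15), 5, 3)
  expect_equal(glidetree:::vi_log_density(fr, zz),
               glidetree:::vi_log_density(mf, zz), tolerance = 1e-12)
})

test_that("SNIS batches: proportional densities, weights, ESS, KL report", {
  model <- toy_standard_normal(1)
  q <- mean_field_gaussian(1, mu = 0, log_sigma = 0)  # q identical to p
  set.seed(78)
  b <- snis_batch(q, model, 10)
  expect_equal(b$weights, rep(0.1, 10), tolerance = 1e-12)
  expect_equal(b$kl_report, 0, tolerance = 1e-12)
  expect_equal(b$ess, 10, tolerance = 1e-9)
  expect_error(snis_batch(q, model, 1), "S must be")

  # two samples with raw log-ratios (0, log 3) -> weights (0.25, 0.75):
  # the normalized-weight arithmetic, checked directly
  lr <- c(0, log(3))
  w <- exp(lr - max(lr)); w <- w / sum(w)
  expect_equal(w, c(0.25, 0.75))

  # KL report matches the analytic KL(p || q) for a Gaussian pair
  target <- joint_posterior(list(param_block(
    "z", make_transform("identity", 1), prior = prior_normal(0, 2))))
  qn <- mean_field_gaussian(1, mu = 0, log_sigma = 0)
  kl_true <- log(1 / 2) + (4 + 0) / 2 - 0.5  # KL(N(0,4) || N(0,1))
  set.seed(79)
  reps <- replicate(12, snis_batch(qn, target, 1e4)$kl_report)
  expect_lt(abs(mean(reps) - kl_true), 3 * sd(reps) / sqrt(length(reps)))
  b2 <- snis_batch(qn, target, 1e4)
  expect_true(b2$ess >= 1 && b2$ess <= 1e4)
})

test_that("SNIS ESS approaches S as q approaches p", {
  set.seed(80)
  y <- rnorm(15, 1, 1)
  toy <- toy_conjugate_model(0, 1, 1, y)
  q_far <- mean_field_gaussian(1, mu = toy$posterior_mean + 2,
                               log_sigma = log(3 * toy$posterior_sd))
  q_close <- mean_field_gaussian(1, mu = toy$posterior_mean,
                                 log_sigma = log(toy$posterior_sd))
  ess_far <- mean(replicate(20, snis_batch(q_far, toy, 200)$ess))
  ess_close <- mean(replicate(20, snis_batch(q_close, toy, 200)$ess))
  expect_gt(ess_close / 200, 0.98)
  expect_lt(ess_far, ess_close)
})

test_that("the forward-KL gradient uses only the variational score", {
  q <- mean_field_gaussian(1, mu = 0, log_sigma = log(0.8))
  # symmetric samples with equal weights: mu-gradient exactly 0
  batch <- structure(list(z = matrix(c(-1.7, 1.7), 2, 1),
                          weights = c(0.5, 0.5)), class = "snis_batch")
  g <- forward_kl_gradient(batch, q)
  expect_equal(g[1], 0, tolerance = 1e-14)
  # single dominant weight at z0: mu-gradient = -(z0 - mu)/sigma^2
  batch2 <- structure(list(z = matrix(c(1.1, -0.3), 2, 1),
                           weights = c(1, 0)), class = "snis_batch")
  g2 <- forward_kl_gradient(batch2, q)
  expect_equal(g2[1], -(1.1 - 0) / 0.8^2, tolerance = 1e-12)
  # finite differences of L_KL(phi) = -sum w_s log q(z_s; phi) at fixed
  # samples and weights
  set.seed(81)
  zfix <- matrix(rnorm(6, 0, 2), 6, 1)
  wfix <- runif(6); wfix <- wfix / sum(wfix)
  batch3 <- structure(list(z = zfix, weights = wfix), class = "snis_batch")
  q3 <- mean_field_gaussian(1, mu = 0.4, log_sigma = -0.2)
  g3 <- forward_kl_gradient(batch3, q3)
  fd <- fd_gradient(function(ph) {
    qq <- mean_field_gaussian(1, mu = ph[1], log_sigma = ph[2])
    -sum(wfix * glidetree:::vi_log_density(qq, zfix))
  }, c(0.4, -0.2), h = 1e-6)
  expect_equal(g3, fd, tolerance = 1e-6)
})

test_that("variational fits recover the conjugate posterior", {
  set.seed(82)
  y <- rnorm(20, 1.5, 1)
  toy <- toy_conjugate_model(0, 2, 1, y)
  f1 <- fit_vi(toy, "elbo", iterations = 5000, learning_rate = 0.02, seed = 5)
  expect_lt(abs(f1$family$mu - toy$posterior_mean), 0.02)
  expect_lt(abs(exp(f1$family$log_sigma) / toy$posterior_sd - 1), 0.1)
  f2 <- fit_vi(toy, "forward_kl", iterations = 5000, learning_rate = 0.02,
               seed = 5, samples_per_step = 10)
  expect_lt(abs(f2$family$mu - toy$posterior_mean), 0.03)
  expect_lt(abs(exp(f2$family$log_sigma) / toy$posterior_sd - 1), 0.15)
  # trace format: iteration column then the objective column
  expect_equal(names(f1$trace)[1:2], c("iteration", "elbo"))
  expect_equal(names(f2$trace)[2], "forward_kl")
})

test_that("fits are deterministic given the seed", {
  set.seed(83)
  y <- rnorm(8, 0, 1)
  toy <- toy_conjugate_model(0, 1, 1, y)
  f1 <- fit_vi(toy, "elbo", iterations = 300, seed = 42, checkpoint_every = 50)
  f2 <- fit_vi(toy, "elbo", iterations = 300, seed = 42, checkpoint_every = 50)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$family$mu, f2$family$mu)
})

test_that("forward-KL fitting never invokes the model gradient", {
  set.seed(84)
  y <- rnorm(10, 1, 1)
  toy <- toy_conjugate_model(0, 1, 1, y)
  before <- toy$counts$gradient
  invisible(fit_vi(toy, "forward_kl", iterations = 400, seed = 7))
  expect_identical(toy$counts$gradient, before)
  expect_gt(toy$counts$log_density, 0L)
  # while the ELBO path does use it
  invisible(fit_vi(toy, "elbo", iterations = 50, seed = 7))
  expect_gt(toy$counts$gradient, before)
})

test_that("forward KL is mass-covering where the ELBO is mode-seeking", {
  mix <- toy_mixture_model(means = c(-2, 2), sds = c(0.6, 0.6))
  for (s in 1:5) {
    fe <- fit_vi(mix, "elbo", iterations = 2500, learning_rate = 0.05,
                 seed = s, init = 1.5)
    fk <- fit_vi(mix, "forward_kl", iterations = 2500, learning_rate = 0.05,
                 seed = s, init = 1.5, samples_per_step = 10)
    expect_gte(exp(fk$family$log_sigma), exp(fe$family$log_sigma))
  }
})

test_that("leapfrog integration is reversible and exact in the limit", {
  model <- toy_standard_normal(3)
  set.seed(85)
  z0 <- rnorm(3); p0 <- rnorm(3)
  fw <- leapfrog_integrate(model, z0, p0, 0.05, 30)
  bk <- leapfrog_integrate(model, fw$z, -fw$p, 0.05, 30)
  expect_lt(max(abs(bk$z - z0)), 1e-8)
  expect_lt(max(abs(-bk$p - p0)), 1e-8)
  # energy error vanishes with the step size on a quadratic target
  H <- function(z, p) 0.5 * sum(z^2) + 0.5 * sum(p^2)
  s <- leapfrog_integrate(model, z0, p0, 1e-4, 10)
  expect_lt(abs(H(s$z, s$p) - H(z0, p0)), 1e-6)
})

test_that("HMC recovers the moments of a 5-d standard normal", {
  m <- toy_standard_normal(5)
  h <- hmc_sample(m, iterations = 4000, warmup = 800, seed = 86)
  expect_gt(h$accept_rate, 0.6)
  for (j in 1:5) {
    x <- h$samples[, j]
    ac <- acf(x, lag.max = 50, plot = FALSE)$acf[-1]
    ess <- length(x) / (1 + 2 * sum(ac[ac > 0.01]))
    expect_lt(abs(mean(x)), 3 / sqrt(ess))
    expect_lt(abs(var(x) - 1), 3 * sqrt(2 / ess) + 0.02)
  }
})

test_that("MAP optimization finds analytic modes", {
  set.seed(87)
  y <- rnorm(15, -0.7, 1)
  toy <- toy_conjugate_model(0.2, 1.3, 1, y)
  fit <- map_optimize(toy)
  expect_lt(abs(fit$par$mu - toy$posterior_mean), 1e-6)
  # pure prior: mode at 0
  fit0 <- map_optimize(toy_standard_normal(3), init = c(1, -2, 0.5))
  expect_lt(max(abs(fit0$par$z)), 1e-6)
})

test_that("MAP branch length matches the closed-form JC69 distance", {
  # two sequences, flat prior on the evolutionary distance t (identity
  # transform, interior optimum): the MAP equals the analytic JC69 distance
  # -3/4 log(1 - 4 p-hat / 3)
  set.seed(88)
  n <- 500
  s1 <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  P <- transition_probs(substitution_model("JC69"), 0.15)
  s2 <- vapply(s1, function(a) {
    sample(c("A", "C", "G", "T"), 1,
           prob = P[match(a, c("A", "C", "G", "T")), ])
  }, "")
  phat <- mean(s1 != s2)
  d_analytic <- -0.75 * log(1 - 4 * phat / 3)
  mism <- sum(s1 != s2); match_n <- n - mism
  lik <- list(params = "jc",
              value = function(x) {
                Pt <- transition_probs(substitution_model("JC69"), x$t)
                match_n * log(Pt[1, 1] / 4) + mism * log(Pt[1, 2] / 4)
              },
              grad = function(x) {
                h <- 1e-6
                v <- function(t) {
                  Pt <- transition_probs(substitution_model("JC69"), t)
                  match_n * log(Pt[1, 1] / 4) + mism * log(Pt[1, 2] / 4)
                }
                list(value = v(x$t),
                     grads = list(t = (v(x$t + h) - v(x$t - h)) / (2 * h)))
              })
  model <- joint_posterior(list(param_block("t", make_transform("identity", 1),
                                            init = 0.1)), list(lik))
  fit <- map_optimize(model)
  expect_lt(abs(fit$par$t - d_analytic), 1e-4)
})
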