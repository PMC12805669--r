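test_that("demographic functions interpolate (linear) or step (constant)", {
  g <- demographic_grid(1, 1, log_pop_sizes = log(c(1, 2)))
  expect_equal(pop_size_at(g, 0.5, "linear"), 1.5)
  expect_equal(pop_size_at(g, 0.5, "constant"), 1)
  # beyond the cutoff both kinds freeze at the last value
  expect_equal(pop_size_at(g, 7, "linear"), 2)
  expect_equal(pop_size_at(g, 7, "constant"), 2)
  # equal values: flat under both kinds
  gf <- demographic_grid(2, 4, log_pop_sizes = rep(log(3), 5))
  ts <- seq(0, 3, by = 0.1)
  expect_equal(pop_size_at(gf, ts, "linear"), rep(3, length(ts)))
  expect_equal(pop_size_at(gf, ts, "constant"), rep(3, length(ts)))
  expect_error(pop_size_at(g, -1), "nonnegative")
})

test_that("the linear function is continuous at grid points, the constant one jumps", {
  set.seed(51)
  g <- demographic_grid(4, 5, log_pop_sizes = rnorm(6, 0, 0.8))
  th <- exp(g$log_pop_sizes)
  eps <- 1e-9
  for (i in 1:4) {
    x <- g$times[i + 1]
    expect_lt(abs(pop_size_at(g, x + eps, "linear") -
                    pop_size_at(g, x - eps, "linear")), 1e-6)
    # constant kind holds theta_{i-1} below x_i and theta_i at/above it
    jump <- abs(pop_size_at(g, x + eps, "constant") -
                  pop_size_at(g, x - eps, "constant"))
    expect_equal(jump, abs(th[i + 1] - th[i]), tolerance = 1e-6)
  }
})

test_that("inverse population integrals match closed forms and quadrature", {
  g <- demographic_grid(1, 1, log_pop_sizes = log(c(1, 2)))
  expect_equal(inverse_pop_integral(g, 0.3, 0.3, "linear"), 0)
  expect_equal(inverse_pop_integral(g, 0, 1, "linear"), log(2),
               tolerance = 1e-12)
  expect_equal(inverse_pop_integral(g, 0, 1, "constant"), 1)

  set.seed(52)
  for (i in 1:30) {
    M <- sample(1:8, 1)
    gg <- demographic_grid(runif(1, 0.5, 5), M, rnorm(M + 1, 0, 1))
    u <- runif(1, 0, gg$cutoff * 1.5)
    v <- u + runif(1, 0, gg$cutoff)
    for (kind in c("linear", "constant")) {
      quad <- quadrature_inv_pop(gg, u, v, kind)
      expect_lt(abs(inverse_pop_integral(gg, u, v, kind) - quad), 1e-9)
    }
  }
  expect_error(inverse_pop_integral(g, 2, 1), "u <= v")
})

test_that("inverse integrals are additive over the midpoint", {
  set.seed(53)
  g <- demographic_grid(3, 6, rnorm(7, 0, 1))
  for (i in 1:20) {
    u <- runif(1, 0, 4); w <- u + runif(1, 0, 2); v <- runif(1, u, w)
    for (kind in c("linear", "constant")) {
      expect_lt(abs(inverse_pop_integral(g, u, w, kind) -
                      inverse_pop_integral(g, u, v, kind) -
                      inverse_pop_integral(g, v, w, kind)), 1e-10)
    }
  }
})

test_that("coalescent densities reproduce constant-population closed forms", {
  # 2 isochronous tips coalescing at t under constant N: -log N - t/N
  tr <- read_newick_text("(A:1,B:1);")
  iv <- coalescent_intervals(tr)
  g1 <- demographic_grid(2, 1, log_pop_sizes = c(0, 0))  # N = 1
  expect_equal(coalescent_log_density(iv, g1, "linear"), -1)
  expect_equal(coalescent_log_density(iv, g1, "constant"), -1)

  # 3 tips at heights 0,0,1, coalescences at 0.5 and 2, N = 1: -1.5
  tr2 <- time_tree(parent = c(4L, 4L, 5L, 5L, 0L),
                   heights = c(0, 0, 1, 0.5, 2), labels = c("A", "B", "C"))
  iv2 <- coalescent_intervals(tr2)
  expect_equal(coalescent_log_density(iv2, g1, "linear"), -1.5)
  expect_equal(coalescent_log_density(iv2, g1, "constant"), -1.5)
})

test_that("skygrid and skyglide nest the constant-population model", {
  set.seed(54)
  for (i in 1:20) {
    tr <- random_tree(sample(3:15, 1), hetero = i %% 2 == 0)
    iv <- coalescent_intervals(tr)
    N <- runif(1, 0.5, 5)
    M <- sample(2:8, 1)
    g <- demographic_grid(runif(1, 1, 4), M, rep(log(N), M + 1))
    closed <- local({
      nz <- iv$intervals$end > iv$intervals$start
      cnt <- choose(iv$intervals$lineages, 2)
      n_coal <- sum(iv$intervals$end_type == "coalescence")
      -sum(cnt[nz] * (iv$intervals$end - iv$intervals$start)[nz]) / N -
        n_coal * log(N)
    })
    expect_lt(abs(coalescent_log_density(iv, g, "linear") - closed), 1e-10)
    expect_lt(abs(coalescent_log_density(iv, g, "constant") - closed), 1e-10)
  }
})

test_that("skyglide gradients are continuous across grid crossings, skygrid density jumps", {
  # place one coalescence just below a grid boundary and nudge it across
  tr <- time_tree(parent = c(4L, 4L, 5L, 5L, 0L),
                  heights = c(0, 0, 0, 0.999999, 2.5),
                  labels = c("A", "B", "C"))
  g <- demographic_grid(3, 3, log_pop_sizes = c(0, 1, -0.5, 0.3))
  grad_at <- function(h) {
    tr$heights[4] <- h
    glidetree:::coalescent_log_density_grad(coalescent_intervals(tr), g,
                                            "linear")$d_gamma
  }
  expect_lt(max(abs(grad_at(1 - 1e-6) - grad_at(1 + 1e-6))), 1e-3)
  dens_at <- function(h, kind) {
    tr$heights[4] <- h
    coalescent_log_density(coalescent_intervals(tr), g, kind)
  }
  # skygrid: the -log N(t_c) term jumps with the cell of the coalescence
  jump_grid <- abs(dens_at(1 + 1e-9, "constant") - dens_at(1 - 1e-9, "constant"))
  jump_glide <- abs(dens_at(1 + 1e-9, "linear") - dens_at(1 - 1e-9, "linear"))
  expect_gt(jump_grid, 0.1)
  expect_lt(jump_glide, 1e-6)
})

test_that("coalescent gradient matches finite differences", {
  set.seed(55)
  tr <- random_tree(8, hetero = TRUE)
  g <- demographic_grid(2, 5, rnorm(6, 0, 0.8))
  iv <- coalescent_intervals(tr)
  for (kind in c("linear", "constant")) {
    r <- glidetree:::coalescent_log_density_grad(iv, g, kind)
    expect_equal(r$value, coalescent_log_density(iv, g, kind),
                 tolerance = 1e-12)
    fd <- fd_gradient(function(lp) {
      coalescent_log_density(iv, demographic_grid(2, 5, lp), kind)
    }, g$log_pop_sizes)
    expect_equal(r$d_gamma, fd, tolerance = 1e-6)
  }
})

test_that("GMRF prior: closed form, shift invariance, gradient", {
  expect_equal(gmrf_log_prior(rep(2.3, 5), 1.7), (4 / 2) * log(1.7 / (2 * pi)))
  expect_equal(gmrf_log_prior(c(0, 1, 0), 2), log(2 / (2 * pi)) - 2)
  expect_equal(gmrf_log_prior(c(0, 1, 0), 2), -3.144729, tolerance = 1e-6)
  set.seed(56)
  gam <- rnorm(6)
  expect_equal(gmrf_log_prior(gam, 0.7), gmrf_log_prior(gam + 3.1, 0.7),
               tolerance = 1e-12)
  expect_error(gmrf_log_prior(gam, -1), "positive")
  r <- glidetree:::gmrf_log_prior_grad(gam, 0.7)
  expect_equal(r$d_gamma, fd_gradient(function(g) gmrf_log_prior(g, 0.7), gam),
               tolerance = 1e-6)
  expect_equal(r$d_kappa,
               (gmrf_log_prior(gam, 0.7 + 1e-6) -
                  gmrf_log_prior(gam, 0.7 - 1e-6)) / 2e-6, tolerance = 1e-5)
})
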