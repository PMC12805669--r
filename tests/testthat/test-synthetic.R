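test_that("pairwise coalescent times have the Kingman expectation", {
  set.seed(101)
  sc <- demographic_scenario("constant", n0 = 2)
  tm <- replicate(10000, {
    tr <- simulate_coalescent(sc, n_tips = 2)
    tr$heights[tr$root]
  })
  # E[T2] = N; Var = N^2
  expect_lt(abs(mean(tm) - 2), 3 * sd(tm) / sqrt(length(tm)))
})

test_that("10-tip constant-size TMRCA matches 2N(1 - 1/n)", {
  set.seed(102)
  sc <- demographic_scenario("constant", n0 = 1)
  tm <- replicate(10000, {
    tr <- simulate_coalescent(sc, n_tips = 10)
    tr$heights[tr$root]
  })
  expect_lt(abs(mean(tm) - 1.8), 3 * sd(tm) / sqrt(length(tm)))
})

test_that("exponential growth yields shorter trees than constant N(0)", {
  set.seed(103)
  n <- 1000
  t_const <- replicate(n, {
    tr <- simulate_coalescent(demographic_scenario("constant", n0 = 5),
                              n_tips = 8)
    tr$heights[tr$root]
  })
  t_growth <- replicate(n, {
    tr <- simulate_coalescent(
      demographic_scenario("exponential_growth", n0 = 5, growth_rate = 1),
      n_tips = 8)
    tr$heights[tr$root]
  })
  expect_lt(t.test(t_growth, t_const, alternative = "less")$p.value, 1e-6)
})

test_that("bottleneck waiting times follow the piecewise intensity", {
  # with the bisection inversion, the integrated intensity at the returned
  # waiting time must equal the exponential draw
  set.seed(104)
  sc <- demographic_scenario("bottleneck", n0 = 3, n_bottleneck = 0.5,
                             t_start = 1, t_end = 2, n_ancient = 4)
  for (i in 1:50) {
    s <- runif(1, 0, 3); k <- sample(2:6, 1); E <- rexp(1)
    w <- glidetree:::scenario_waiting_time(sc, s, k, E)
    expect_equal(choose(k, 2) *
                   glidetree:::scenario_inv_integral(sc, s, s + w), E,
                 tolerance = 1e-7)
  }
})

test_that("heterochronous simulation respects sampling heights", {
  set.seed(105)
  sh <- c(0, 0.3, 0.7, 1.1, 2)
  sc <- demographic_scenario("constant", n0 = 1, sampling_heights = sh)
  tr <- simulate_coalescent(sc)
  expect_equal(sort(tr$heights[1:5]), sort(sh))
  expect_gt(tr$heights[tr$root], max(sh))
  validate <- glidetree:::validate_time_tree(tr)
  expect_s3_class(validate, "time_tree")
})

test_that("sequence simulation matches JC69 mismatch expectations", {
  tr0 <- time_tree(parent = c(3L, 3L, 0L), heights = c(0, 0, 1e-300),
                   labels = c("A", "B"))
  set.seed(106)
  a0 <- simulate_alignment(tr0, substitution_model("JC69"),
                           clock = strict_clock(1e-9, TRUE), n_sites = 50)
  s0 <- expand_alignment(a0)
  expect_identical(s0[["A"]], s0[["B"]])

  # saturation: t = 100 -> mismatch fraction 3/4
  tr1 <- time_tree(parent = c(3L, 3L, 0L), heights = c(0, 0, 50),
                   labels = c("A", "B"))
  n <- 4000
  a1 <- simulate_alignment(tr1, substitution_model("JC69"),
                           clock = strict_clock(1, TRUE), n_sites = n)
  s1 <- expand_alignment(a1)
  mis1 <- mean(strsplit(s1[["A"]], "")[[1]] != strsplit(s1[["B"]], "")[[1]])
  expect_lt(abs(mis1 - 0.75), 3 * sqrt(0.75 * 0.25 / n))

  # closed form at total distance 0.2
  tr2 <- time_tree(parent = c(3L, 3L, 0L), heights = c(0, 0, 0.1),
                   labels = c("A", "B"))
  p_expect <- 0.75 * (1 - exp(-4 * 0.2 / 3))
  a2 <- simulate_alignment(tr2, substitution_model("JC69"),
                           clock = strict_clock(1, TRUE), n_sites = n)
  s2 <- expand_alignment(a2)
  mis2 <- mean(strsplit(s2[["A"]], "")[[1]] != strsplit(s2[["B"]], "")[[1]])
  expect_lt(abs(mis2 - p_expect), 3 * sqrt(p_expect * (1 - p_expect) / n))
})

test_that("the average simulated likelihood peaks at the generating distance", {
  # simulator/likelihood consistency: the MLE of the pairwise distance over
  # simulated alignments is nearly unbiased for the truth
  set.seed(107)
  t_true <- 0.3
  tr <- time_tree(parent = c(3L, 3L, 0L), heights = c(0, 0, t_true / 2),
                  labels = c("A", "B"))
  m <- substitution_model("JC69")
  cl <- strict_clock(1, TRUE)
  mles <- replicate(10, {
    aln <- simulate_alignment(tr, m, clock = cl, n_sites = 2000)
    opt <- optimize(function(d) {
      trd <- time_tree(parent = c(3L, 3L, 0L), heights = c(0, 0, d / 2),
                       labels = c("A", "B"))
      tree_log_likelihood(trd, aln, m, clock = cl)
    }, c(0.01, 2), maximum = TRUE)
    opt$maximum
  })
  expect_lt(abs(mean(mles) / t_true - 1), 0.05)
})

test_that("scenario presets encode the flagship configurations", {
  hcv <- scenario_preset("hcv_like")
  expect_equal(hcv$config$model$clock$rate, 7.9e-4)
  expect_true(hcv$config$model$clock$fixed)
  expect_equal(hcv$config$model$substitution$name, "GTR")
  expect_equal(hcv$config$model$site$categories, 4L)
  expect_true(all(hcv$scenario$sampling_heights == 0))

  sc2 <- scenario_preset("sc2_like")
  expect_equal(sc2$config$model$bridge$alpha, 0.25)
  expect_equal(sc2$config$model$bridge$delta, 1)
  expect_equal(sc2$config$model$bridge$scale, 2)
  expect_true(sc2$config$model$substitution$random_effects)
  # five population-size parameters on the grid
  expect_equal(sc2$config$model$coalescent$grid$segments + 1L, 5L)
  expect_gt(max(sc2$scenario$sampling_heights), 0)

  kinds <- vapply(c("validation_constant", "validation_growth",
                    "validation_bottleneck"),
                  function(n) scenario_preset(n)$scenario$kind, "")
  expect_setequal(unname(kinds),
                  c("constant", "exponential_growth", "bottleneck"))
  expect_error(scenario_preset("nope"))

  # desk-scale bounds: <= 30 taxa, <= 500 sites, <= 10 grid segments
  for (n in c("hcv_like", "sc2_like", "validation_constant",
              "validation_growth", "validation_bottleneck", "sharp_change")) {
    p <- scenario_preset(n)
    expect_lte(length(p$scenario$sampling_heights), 30L)
    expect_lte(p$n_sites, 500L)
    expect_lte(p$config$model$coalescent$grid$segments, 10L)
  }
})

test_that("simulated data sets are reproducible and well-formed", {
  d1 <- simulate_dataset("validation_constant", seed = 9)
  d2 <- simulate_dataset("validation_constant", seed = 9)
  expect_identical(expand_alignment(d1$aln), expand_alignment(d2$aln))
  expect_identical(d1$tree$heights, d2$tree$heights)
  expect_equal(d1$aln$site_count, 300L)
  expect_setequal(d1$tree$labels, d1$aln$taxa)
})

test_that("skyglide fits recover a constant demographic trajectory", {
  # simulate under validation_constant and check that the variational 95%
  # intervals for log N(t) cover the truth at >= 70% of grid points in at
  # least 4 of 5 replicates
  truth <- log(5)
  hits <- logical(5)
  for (s in 1:5) {
    ds <- simulate_dataset("validation_constant", seed = s)
    model <- build_model(ds$preset$config, ds$aln, ds$tree)
    fit <- fit_vi(model, "elbo", iterations = 3000, learning_rate = 0.05,
                  seed = s)
    idx <- model$offsets["log_pop"] + seq_len(model$dims["log_pop"])
    mu <- fit$family$mu[idx]
    sd <- exp(fit$family$log_sigma[idx])
    inside <- truth >= mu - 1.96 * sd & truth <= mu + 1.96 * sd
    hits[s] <- mean(inside) >= 0.7
  }
  expect_gte(sum(hits), 4)
})
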