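#' Run configuration
#'
#' Validates and normalizes the JSON analysis configuration. The schema is
#' this package's own (documented in the README and methods vignette); it
#' mirrors the usual block structure of phylodynamic configuration files:
#' optimizer settings at the top level and nested `substitution`, `site`,
#' `clock`, `coalescent` (and optional `bridge`) model blocks.
#'
#' @param config a nested list (already parsed JSON).
#' @return a validated `run_config` list.
#' @export
run_config <- function(config) {
  cfg <- config
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$iterations <- as.integer(cfg$iterations %||% 5000L)
  if (cfg$iterations < 1L) stop("config: iterations must be >= 1")
  cfg$learning_rate <- as.numeric(cfg$learning_rate %||% 0.1)
  if (cfg$learning_rate <= 0) stop("config: learning_rate must be positive")
  cfg$objective <- match.arg(cfg$objective %||% "elbo", c("elbo", "forward_kl"))
  cfg$family <- match.arg(cfg$family %||% "mean_field",
                          c("mean_field", "full_rank"))
  cfg$samples_per_step <- as.integer(cfg$samples_per_step %||%
                                       if (cfg$objective == "elbo") 1L else 10L)
  if (cfg$samples_per_step < 1L) stop("config: samples_per_step must be >= 1")
  cfg$checkpoint_every <- as.integer(cfg$checkpoint_every %||% 1000L)
  m <- cfg$model %||% list()
  m$substitution <- m$substitution %||% list(name = "JC69")
  if (!(m$substitution$name %in% c("JC69", "HKY", "GTR"))) {
    stop("config: unknown substitution model: ", m$substitution$name)
  }
  m$site <- m$site %||% list(name = "none")
  if (!(m$site$name %in% c("none", "weibull", "gamma"))) {
    stop("config: unknown site model: ", m$site$name)
  }
  m$clock <- m$clock %||% list(rate = 1, fixed = TRUE)
  if (is.null(m$clock$rate)) stop("config: clock block requires a rate")
  m$coalescent <- m$coalescent %||% list(name = "constant")
  if (!(m$coalescent$name %in% c("constant", "skygrid", "skyglide"))) {
    stop("config: unknown coalescent model: ", m$coalescent$name)
  }
  if (m$coalescent$name != "constant") {
    g <- m$coalescent$grid
    if (is.null(g$cutoff) || is.null(g$segments)) {
      stop("config: skygrid/skyglide require grid cutoff and segments")
    }
    m$coalescent$gmrf <- m$coalescent$gmrf %||% list(shape = 0.005, rate = 0.005)
  }
  if (isTRUE(m$substitution$random_effects)) {
    m$bridge <- m$bridge %||% list(alpha = 0.25, delta = 1, scale = 2)
  }
  cfg$model <- m
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a JSON run configuration
#'
#' @param path JSON file path.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("config: malformed JSON: ",
                                           conditionMessage(e), call. = FALSE))
  run_config(cfg)
}

#' Build the joint posterior from a configuration, alignment, and tree
#'
#' Wires the pruning likelihood, coalescent density, GMRF smoothing prior,
#' Bayesian bridge prior (for random-effects models), block priors, and
#' ADVI transforms into a [joint_posterior]. Fixed parameters (e.g. a fixed
#' clock rate) are excluded from the unconstrained vector entirely.
#'
#' @param config a `run_config` (or raw list).
#' @param aln an [alignment].
#' @param tree a [time_tree].
#' @return a [joint_posterior].
#' @export
build_model <- function(config, aln, tree) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  m <- cfg$model
  blocks <- list(height_block(tree))
  terms <- list()
  sub_name <- m$substitution$name
  has_re <- isTRUE(m$substitution$random_effects)
  est_freq <- !isFALSE(m$substitution$estimate_frequencies) && sub_name != "JC69"

  if (sub_name == "HKY") {
    blocks <- c(blocks, list(param_block(
      "kappa", make_transform("log_positive", 1L),
      prior = prior_lognormal(1, 1.25), init = m$substitution$kappa %||% 2)))
  }
  if (sub_name == "GTR") {
    blocks <- c(blocks, list(param_block(
      "rates", make_transform("stick_breaking_simplex", 6L),
      prior = prior_dirichlet(rep(1, 6)))))
  }
  if (est_freq) {
    blocks <- c(blocks, list(param_block(
      "frequencies", make_transform("stick_breaking_simplex", 4L),
      prior = prior_dirichlet(rep(1, 4)))))
  }
  if (has_re) {
    if (sub_name != "HKY") stop("config: random effects require the HKY model")
    br <- m$bridge
    blocks <- c(blocks, list(
      param_block("random_effects", make_transform("identity", 12L)),
      param_block("bridge_nu", make_transform("log_positive", 1L),
                  prior = prior_gamma(shape = br$delta, rate = 1 / br$scale),
                  init = 1)))
    terms <- c(terms, list(bridge_term(br$alpha)))
  }

  site_kind <- m$site$name
  K <- as.integer(m$site$categories %||% 4L)
  site_fixed <- isTRUE(m$site$fixed)
  free_shape <- site_kind != "none" && K > 1L && !site_fixed
  if (free_shape) {
    blocks <- c(blocks, list(param_block(
      "shape", make_transform("log_positive", 1L),
      prior = prior_lognormal(0, 1), init = m$site$shape %||% 0.5)))
  }
  clock_fixed <- !isFALSE(m$clock$fixed)
  if (!clock_fixed) {
    blocks <- c(blocks, list(param_block(
      "clock", make_transform("log_positive", 1L),
      prior = prior_lognormal(log(1e-3), 1.5), init = m$clock$rate)))
  }

  coal <- m$coalescent
  root_h <- tree$heights[tree$root]
  gamma_init <- log(max(root_h / 2, 1e-3))
  if (coal$name == "constant") {
    blocks <- c(blocks, list(param_block(
      "log_pop", make_transform("identity", 1L), init = gamma_init)))
    terms <- c(terms, list(coalescent_term(tree, cutoff = max(root_h, 1),
                                           segments = 1L, kind = "constant",
                                           tie_single = TRUE)))
  } else {
    segs <- as.integer(coal$grid$segments)
    blocks <- c(blocks, list(
      param_block("log_pop", make_transform("identity", segs + 1L),
                  init = rep(gamma_init, segs + 1L)),
      param_block("gmrf_precision", make_transform("log_positive", 1L),
                  prior = prior_gamma(shape = coal$gmrf$shape,
                                      rate = coal$gmrf$rate),
                  init = 1)))
    terms <- c(terms, list(
      coalescent_term(tree, cutoff = coal$grid$cutoff, segments = segs,
                      kind = if (coal$name == "skyglide") "linear" else "constant"),
      gmrf_term()))
  }

  site_builder <- function(x) {
    if (site_kind == "none") return(constant_rates())
    shape <- if (free_shape) x$shape else (m$site$shape %||% 0.5)
    if (site_kind == "weibull") discrete_weibull_rates(shape, K) else
      discrete_gamma_rates(shape, K)
  }
  subst_builder <- function(x) {
    substitution_model(
      sub_name,
      frequencies = if (est_freq) x$frequencies else rep(0.25, 4),
      kappa = if (sub_name == "HKY") (x$kappa %||% m$substitution$kappa %||% 1) else NULL,
      rates = if (sub_name == "GTR") x$rates else NULL,
      random_effects = if (has_re) x$random_effects else NULL)
  }
  clock_builder <- function(x) {
    strict_clock(if (clock_fixed) m$clock$rate else x$clock, fixed = clock_fixed)
  }
  terms <- c(list(tree_likelihood_term(tree, aln, subst_builder, site_builder,
                                       clock_builder, est_freq, free_shape,
                                       clock_fixed, has_re, sub_name)),
             terms)
  joint_posterior(blocks, terms)
}

tree_likelihood_term <- function(tree, aln, subst_builder, site_builder,
                                 clock_builder, est_freq, free_shape,
                                 clock_fixed, has_re, sub_name) {
  tip_cache <- lapply(seq_len(tree$n_tips),
                      function(i) tip_partials(aln, tree$labels[i]))
  if (!setequal(tree$labels, aln$taxa)) {
    stop("build_model: tree and alignment taxa differ")
  }
  wrt <- c(if (sub_name == "HKY") "kappa",
           if (sub_name == "GTR") "rates",
           if (est_freq) "frequencies",
           if (has_re) "random_effects")
  with_heights <- function(x) set_internal_heights(
    tree, x$heights[(tree$n_tips + 1L):tree$n_nodes])
  list(
    params = "tree_likelihood",
    value = function(x) {
      pruning_core(with_heights(x), aln, subst_builder(x), site_builder(x),
                   clock_builder(x), grad = FALSE, tip_cache = tip_cache)$loglik
    },
    grad = function(x) {
      r <- pruning_core(with_heights(x), aln, subst_builder(x), site_builder(x),
                        clock_builder(x), grad = TRUE, wrt = wrt,
                        tip_cache = tip_cache)
      grads <- list(heights = r$d_heights)
      if (sub_name == "HKY") grads$kappa <- r$d_subst$kappa
      if (sub_name == "GTR") grads$rates <- r$d_subst$rates
      if (est_freq) grads$frequencies <- r$d_subst$frequencies
      if (has_re) grads$random_effects <- r$d_subst$random_effects
      if (free_shape) grads$shape <- r$d_shape
      if (!clock_fixed) grads$clock <- r$d_clock
      list(value = r$loglik, grads = grads)
    }
  )
}

coalescent_term <- function(tree, cutoff, segments, kind, tie_single = FALSE) {
  n_tips <- tree$n_tips
  with_heights <- function(x) set_internal_heights(
    tree, x$heights[(n_tips + 1L):tree$n_nodes])
  make_grid <- function(x) {
    g <- if (tie_single) rep(x$log_pop, 2) else x$log_pop
    demographic_grid(cutoff, if (tie_single) 1L else segments, g)
  }
  list(
    params = "coalescent",
    value = function(x) {
      coalescent_log_density(coalescent_intervals(with_heights(x)),
                             make_grid(x), kind)
    },
    grad = function(x) {
      r <- coalescent_log_density_grad(
        coalescent_intervals(with_heights(x)), make_grid(x), kind)
      d_h <- numeric(tree$n_nodes)
      d_h[seq_along(r$d_heights)] <- r$d_heights
      d_h[seq_len(n_tips)] <- 0  # tip heights are data
      list(value = r$value,
           grads = list(heights = d_h,
                        log_pop = if (tie_single) sum(r$d_gamma) else r$d_gamma))
    }
  )
}

gmrf_term <- function() {
  list(
    params = "gmrf",
    value = function(x) gmrf_log_prior(x$log_pop, x$gmrf_precision),
    grad = function(x) {
      r <- gmrf_log_prior_grad(x$log_pop, x$gmrf_precision)
      list(value = r$value,
           grads = list(log_pop = r$d_gamma, gmrf_precision = r$d_kappa))
    }
  )
}

# Bridge prior on random effects, parameterized through nu = tau^{-alpha}
# (the gamma-distributed hyperparameter); tau_b = nu^{-1/alpha}.
bridge_term <- function(alpha) {
  list(
    params = "bridge",
    value = function(x) {
      tau <- x$bridge_nu^(-1 / alpha)
      bridge_log_density(x$random_effects, tau, alpha)
    },
    grad = function(x) {
      nu <- x$bridge_nu
      tau <- nu^(-1 / alpha)
      r <- bridge_log_density_grad(x$random_effects, tau, alpha)
      dtau_dnu <- (-1 / alpha) * nu^(-1 / alpha - 1)
      list(value = r$value,
           grads = list(random_effects = r$d_eps,
                        bridge_nu = r$d_tau * dtau_dnu))
    }
  )
}
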