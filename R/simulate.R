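#' Demographic scenarios for the coalescent simulator
#'
#' Effective population size trajectories N(t) in height (years before the
#' most recent sample): `constant` N0; `exponential_growth` with forward
#' growth rate g, so N(t) = N0 exp(-g t) looking into the past; and
#' `bottleneck`, N0 before `t_start`, `n_bottleneck` inside
#' `[t_start, t_end)`, and `n_ancient` beyond.
#'
#' @param kind scenario kind.
#' @param n0 present-day effective population size (time units).
#' @param growth_rate forward exponential growth rate (per year).
#' @param n_bottleneck,t_start,t_end,n_ancient bottleneck parameters.
#' @param sampling_heights tip sampling heights (years; 0 = isochronous).
#' @return an object of class `demographic_scenario` with `pop_size(t)`.
#' @export
demographic_scenario <- function(kind = c("constant", "exponential_growth",
                                          "bottleneck"),
                                 n0 = 1, growth_rate = 1,
                                 n_bottleneck = n0 / 10, t_start = 1,
                                 t_end = 2, n_ancient = n0,
                                 sampling_heights = NULL) {
  kind <- match.arg(kind)
  pop_size <- switch(kind,
    constant = function(t) rep(n0, length(t)),
    exponential_growth = function(t) n0 * exp(-growth_rate * t),
    bottleneck = function(t) {
      ifelse(t < t_start, n0, ifelse(t < t_end, n_bottleneck, n_ancient))
    })
  structure(list(kind = kind, n0 = n0, growth_rate = growth_rate,
                 n_bottleneck = n_bottleneck, t_start = t_start,
                 t_end = t_end, n_ancient = n_ancient,
                 sampling_heights = sampling_heights, pop_size = pop_size),
            class = "demographic_scenario")
}

# cumulative coalescent intensity for one lineage pair: integral of 1/N
# over [u, v]; closed form per scenario kind
scenario_inv_integral <- function(sc, u, v) {
  switch(sc$kind,
    constant = (v - u) / sc$n0,
    exponential_growth = {
      g <- sc$growth_rate
      if (abs(g) < 1e-14) (v - u) / sc$n0 else
        (exp(g * v) - exp(g * u)) / (sc$n0 * g)
    },
    bottleneck = {
      brk <- c(sc$t_start, sc$t_end)
      Ns <- c(sc$n0, sc$n_bottleneck, sc$n_ancient)
      lo <- c(0, brk); hi <- c(brk, Inf)
      tot <- 0
      for (i in 1:3) {
        a <- max(u, lo[i]); b <- min(v, hi[i])
        if (b > a) tot <- tot + (b - a) / Ns[i]
      }
      tot
    })
}

# waiting time w >= 0 from height s with k lineages solving
# choose(k,2) * integral_s^{s+w} 1/N = E; analytic for constant and
# exponential, bisection (1e-10 years) for the piecewise bottleneck
scenario_waiting_time <- function(sc, s, k, E) {
  cnt <- choose(k, 2)
  target <- E / cnt
  switch(sc$kind,
    constant = target * sc$n0,
    exponential_growth = {
      g <- sc$growth_rate
      if (abs(g) < 1e-14) target * sc$n0 else
        log(exp(g * s) + target * sc$n0 * g) / g - s
    },
    bottleneck = {
      hi <- 1
      while (scenario_inv_integral(sc, s, s + hi) < target) hi <- hi * 2
      lo <- 0
      while (hi - lo > 1e-10) {
        mid <- (lo + hi) / 2
        if (scenario_inv_integral(sc, s, s + mid) < target) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    })
}

#' Simulate a coalescent tree under a demographic scenario
#'
#' Time-rescaled coalescent: with k extant lineages the next coalescence
#' waits until `choose(k,2) * integral 1/N(t) dt` reaches an Exp(1) draw;
#' heterochronous samples join at their heights (pending sampling events
#' interrupt and restart the exponential clock, which is valid by
#' memorylessness); the merged pair is uniform at random.
#'
#' @param scenario a [demographic_scenario].
#' @param n_tips number of tips (used when the scenario carries no explicit
#'   `sampling_heights`).
#' @param labels tip labels (default `t1..tn`).
#' @return a [time_tree].
#' @export
simulate_coalescent <- function(scenario, n_tips = NULL, labels = NULL) {
  sh <- scenario$sampling_heights
  if (is.null(sh)) {
    if (is.null(n_tips)) stop("simulate_coalescent: n_tips or sampling_heights required")
    sh <- rep(0, n_tips)
  }
  n <- length(sh)
  if (n < 2L) stop("simulate_coalescent: need at least 2 tips")
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  sh <- sh - min(sh)
  ord <- order(sh)
  pending <- ord            # tip ids not yet sampled, by height
  pend_h <- sh[ord]
  active <- integer(0)
  s <- 0
  parent <- integer(2L * n - 1L)
  heights <- numeric(2L * n - 1L)
  heights[seq_len(n)] <- sh
  coal_nodes <- integer(0)
  coal_children <- list()
  coal_heights <- numeric(0)
  next_internal <- 0L
  repeat {
    # absorb all samples at or below current time
    while (length(pending) && pend_h[1] <= s + 1e-15) {
      active <- c(active, pending[1])
      pending <- pending[-1]; pend_h <- pend_h[-1]
    }
    k <- length(active)
    if (k < 2L) {
      if (!length(pending)) break
      s <- pend_h[1]
      next
    }
    w <- scenario_waiting_time(scenario, s, k, stats::rexp(1))
    if (length(pending) && s + w > pend_h[1]) {
      s <- pend_h[1]         # sampling event first; redraw (memoryless)
      next
    }
    s <- s + w
    pair <- sample(k, 2L)
    next_internal <- next_internal + 1L
    coal_children[[next_internal]] <- active[pair]
    coal_heights[next_internal] <- s
    active <- c(active[-pair], -next_internal)  # negative = internal placeholder
    if (length(active) == 1L && !length(pending)) break
  }
  # assign internal ids: root (oldest) gets n+1, then decreasing height
  ordc <- order(coal_heights, decreasing = TRUE)
  id_of <- integer(n - 1L)
  id_of[ordc] <- n + seq_len(n - 1L)
  for (j in seq_len(n - 1L)) {
    node <- id_of[j]
    heights[node] <- coal_heights[j]
    for (ch in coal_children[[j]]) {
      ch_id <- if (ch < 0L) id_of[-ch] else ch
      parent[ch_id] <- node
    }
  }
  time_tree(parent, heights, labels)
}

#' Simulate a nucleotide alignment down a time tree
#'
#' Root state from the stationary frequencies, then each child state drawn
#' from `P(duration * clock rate * category rate)` along every branch; each
#' site carries one rate category drawn uniformly (the discretized models
#' use equal weights).
#'
#' @param tree a [time_tree].
#' @param subst a [substitution_model].
#' @param sites a `site_rate_model`.
#' @param clock a [strict_clock].
#' @param n_sites number of sites.
#' @return an [alignment].
#' @export
simulate_alignment <- function(tree, subst, sites = constant_rates(),
                               clock = strict_clock(1, fixed = TRUE),
                               n_sites = 100L) {
  eig <- subst_eigen(subst)
  K <- sites$K
  cat_of <- sample.int(K, n_sites, replace = TRUE, prob = sites$weights)
  states <- matrix(0L, tree$n_nodes, n_sites)
  states[tree$root, ] <- sample.int(4L, n_sites, replace = TRUE,
                                    prob = subst$frequencies)
  for (nd in tree$preorder) {
    for (ch in tree$children[[nd]]) {
      dur <- tree$heights[nd] - tree$heights[ch]
      for (k in seq_len(K)) {
        idx <- which(cat_of == k)
        if (!length(idx)) next
        P <- prob_from_eigen(eig, dur * clock$rate * sites$rates[k])
        P <- pmax(P, 0); P <- P / rowSums(P)
        for (st in 1:4) {
          j <- idx[states[nd, idx] == st]
          if (length(j)) {
            states[ch, j] <- sample.int(4L, length(j), replace = TRUE,
                                        prob = P[st, ])
          }
        }
      }
    }
  }
  seqs <- apply(states[seq_len(tree$n_tips), , drop = FALSE], 1,
                function(r) paste(NUC[r], collapse = ""))
  names(seqs) <- tree$labels
  alignment(seqs)
}

#' Packaged analysis scenarios at desk scale
#'
#' Miniature study setups mirroring the two flagship analysis styles and
#' the three demographic validation scenarios: `hcv_like` (isochronous,
#' GTR + discrete gamma, fixed clock, skyglide grid), `sc2_like`
#' (heterochronous, HKY with nonreversible random effects under a bridge
#' prior with alpha 0.25, delta 1, scale 2, and a skyglide grid with five
#' population-size parameters), and `validation_constant` /
#' `validation_growth` / `validation_bottleneck` (JC69, fixed clock,
#' skyglide) used for demographic-reconstruction checks.
#'
#' A sixth preset, `sharp_change`, provides a heterochronous data set whose
#' true demography has an abrupt bottleneck; it is the setting where the
#' contrast between gradient-based fitting of continuous (skyglide) versus
#' discontinuous (skygrid) coalescent models shows.
#'
#' @param name preset name.
#' @return list with `config` (a `run_config`), `scenario` (a
#'   [demographic_scenario]), `n_sites`, and `truth` (the generating
#'   parameter values used by the simulator).
#' @export
scenario_preset <- function(name = c("hcv_like", "sc2_like",
                                     "validation_constant",
                                     "validation_growth",
                                     "validation_bottleneck",
                                     "sharp_change")) {
  name <- match.arg(name)
  preset <- switch(name,
    hcv_like = list(
      config = list(
        iterations = 5000L, learning_rate = 0.1, objective = "elbo",
        family = "mean_field", samples_per_step = 1L,
        model = list(
          substitution = list(name = "GTR"),
          site = list(name = "gamma", categories = 4L, shape = 0.5),
          clock = list(rate = 7.9e-4, fixed = TRUE),
          coalescent = list(name = "skyglide",
                            grid = list(cutoff = 150, segments = 6L),
                            gmrf = list(shape = 0.005, rate = 0.005)))),
      scenario = demographic_scenario("constant", n0 = 50,
                                      sampling_heights = rep(0, 16)),
      n_sites = 300L,
      truth = list(rates = c(0.08, 0.30, 0.06, 0.10, 0.36, 0.10),
                   frequencies = c(0.30, 0.20, 0.25, 0.25),
                   shape = 0.5, clock = 7.9e-4, n0 = 50)),
    sc2_like = list(
      config = list(
        iterations = 5000L, learning_rate = 0.1, objective = "elbo",
        family = "mean_field", samples_per_step = 1L,
        model = list(
          substitution = list(name = "HKY", random_effects = TRUE),
          site = list(name = "none"),
          clock = list(rate = 1e-3, fixed = TRUE),
          coalescent = list(name = "skyglide",
                            grid = list(cutoff = 0.3, segments = 4L),
                            gmrf = list(shape = 0.005, rate = 0.005)),
          bridge = list(alpha = 0.25, delta = 1, scale = 2))),
      scenario = demographic_scenario("constant", n0 = 0.3,
                                      sampling_heights = seq(0, 0.2,
                                                             length.out = 12)),
      n_sites = 300L,
      truth = list(kappa = 7, frequencies = c(0.30, 0.18, 0.20, 0.32),
                   random_effects = c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0),
                   clock = 1e-3, n0 = 0.3)),
    validation_constant = list(
      config = validation_config(cutoff = 12, segments = 5L, clock = 0.02),
      scenario = demographic_scenario("constant", n0 = 5,
                                      sampling_heights = rep(0, 20)),
      n_sites = 300L,
      truth = list(n0 = 5, clock = 0.02)),
    validation_growth = list(
      config = validation_config(cutoff = 10, segments = 5L, clock = 0.02),
      scenario = demographic_scenario("exponential_growth", n0 = 10,
                                      growth_rate = 0.25,
                                      sampling_heights = rep(0, 20)),
      n_sites = 300L,
      truth = list(n0 = 10, growth_rate = 0.25, clock = 0.02)),
    validation_bottleneck = list(
      config = validation_config(cutoff = 8, segments = 8L, clock = 0.03),
      scenario = demographic_scenario("bottleneck", n0 = 8,
                                      n_bottleneck = 0.8, t_start = 2,
                                      t_end = 4, n_ancient = 8,
                                      sampling_heights = rep(0, 20)),
      n_sites = 300L,
      truth = list(n0 = 8, n_bottleneck = 0.8, t_start = 2, t_end = 4,
                   clock = 0.03)),
    sharp_change = list(
      config = {
        cfg <- validation_config(cutoff = 6, segments = 6L, clock = 0.05)
        cfg$iterations <- 4000L
        cfg$learning_rate <- 0.05
        cfg
      },
      scenario = demographic_scenario("bottleneck", n0 = 4,
                                      n_bottleneck = 0.3, t_start = 1.5,
                                      t_end = 2.5, n_ancient = 4,
                                      sampling_heights = seq(0, 2,
                                                             length.out = 15)),
      n_sites = 200L,
      truth = list(n0 = 4, n_bottleneck = 0.3, t_start = 1.5, t_end = 2.5,
                   clock = 0.05)))
  preset$config <- run_config(preset$config)
  preset$name <- name
  preset
}

validation_config <- function(cutoff, segments, clock) {
  list(iterations = 5000L, learning_rate = 0.1, objective = "elbo",
       family = "mean_field", samples_per_step = 1L,
       model = list(
         substitution = list(name = "JC69"),
         site = list(name = "none"),
         clock = list(rate = clock, fixed = TRUE),
         coalescent = list(name = "skyglide",
                           grid = list(cutoff = cutoff, segments = segments),
                           gmrf = list(shape = 0.005, rate = 0.005))))
}

#' Simulate a full data set from a preset
#'
#' Draws the coalescent tree and alignment for a [scenario_preset] using
#' its generating parameter values.
#'
#' @param preset result of [scenario_preset] (or a preset name).
#' @param seed RNG seed.
#' @return list with `tree`, `aln`, `preset`.
#' @export
simulate_dataset <- function(preset, seed = 1L) {
  if (is.character(preset)) preset <- scenario_preset(preset)
  set.seed(seed)
  tree <- simulate_coalescent(preset$scenario)
  tr <- preset$truth
  m <- preset$config$model
  subst <- substitution_model(
    m$substitution$name,
    frequencies = tr$frequencies %||% rep(0.25, 4),
    kappa = tr$kappa, rates = tr$rates,
    random_effects = tr$random_effects)
  sites <- if (m$site$name == "none") constant_rates() else {
    if (m$site$name == "gamma") discrete_gamma_rates(tr$shape, m$site$categories)
    else discrete_weibull_rates(tr$shape, m$site$categories)
  }
  clock <- strict_clock(m$clock$rate, fixed = TRUE)
  aln <- simulate_alignment(tree, subst, sites, clock, preset$n_sites)
  list(tree = tree, aln = aln, preset = preset)
}
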