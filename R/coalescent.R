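#' Demographic grid for piecewise coalescent models
#'
#' Effective population sizes `theta_i = exp(gamma_i)` are attached to
#' equidistant grid times `x_0 = 0 < x_1 < ... < x_M = cutoff` (heights in
#' years before the most recent sample). The piecewise-linear ("skyglide")
#' demographic function interpolates between grid values and is continuous;
#' the piecewise-constant ("skygrid") variant holds `theta_i` on
#' `[x_i, x_{i+1})` and has jump discontinuities at the grid points. Beyond
#' the cutoff both use `theta_M`.
#'
#' @param cutoff grid cutoff C in years (positive).
#' @param segments number of segments M (the grid carries M+1 population
#'   size parameters).
#' @param log_pop_sizes numeric vector `gamma` of length `segments + 1`.
#' @return an object of class `demographic_grid`.
#' @export
demographic_grid <- function(cutoff, segments, log_pop_sizes = numeric(segments + 1)) {
  if (cutoff <= 0) stop("demographic_grid: cutoff must be positive")
  segments <- as.integer(segments)
  if (segments < 1L) stop("demographic_grid: need at least one segment")
  if (length(log_pop_sizes) != segments + 1L) {
    stop("demographic_grid: log_pop_sizes must have length segments + 1")
  }
  structure(list(cutoff = cutoff, M = segments,
                 times = seq(0, cutoff, length.out = segments + 1L),
                 log_pop_sizes = as.numeric(log_pop_sizes)),
            class = "demographic_grid")
}

grid_thetas <- function(grid) exp(grid$log_pop_sizes)

#' Effective population size N(t)
#'
#' @param grid a [demographic_grid].
#' @param t height(s) in years, nonnegative.
#' @param kind `"linear"` (skyglide) or `"constant"` (skygrid).
#' @return N(t), vectorized over `t`.
#' @export
pop_size_at <- function(grid, t, kind = c("linear", "constant")) {
  kind <- match.arg(kind)
  if (any(t < 0)) stop("pop_size_at: t must be nonnegative")
  th <- grid_thetas(grid)
  M <- grid$M
  dx <- grid$cutoff / M
  i <- pmin(pmax(floor(t / dx), 0), M - 1) + 1  # cell index, 1-based
  out <- numeric(length(t))
  beyond <- t >= grid$cutoff
  if (kind == "linear") {
    s <- (t - grid$times[i]) / dx
    out <- th[i] + (th[i + 1] - th[i]) * s
  } else {
    out <- th[i]
  }
  out[beyond] <- th[M + 1]
  out
}

#' Integrated inverse population size
#'
#' `integral_u^v dt / N(t)`, the quantity the coalescent exponent needs,
#' accumulated cell-by-cell in closed form (log-ratio rule within linear
#' cells, duration/theta within constant cells).
#'
#' @inheritParams pop_size_at
#' @param u,v interval bounds in years, `0 <= u <= v`.
#' @export
inverse_pop_integral <- function(grid, u, v, kind = c("linear", "constant")) {
  kind <- match.arg(kind)
  if (u < 0 || v < u) stop("inverse_pop_integral: need 0 <= u <= v")
  if (u == v) return(0)
  inv_integral_fast(grid_thetas(grid), grid$M, grid$cutoff / grid$M,
                    grid$cutoff, u, v, kind == "linear")
}

# inverse_pop_integral plus partial derivatives w.r.t. theta (length M+1)
# and the bounds u, v
inverse_pop_integral_grad <- function(grid, u, v, kind = "linear") {
  th <- grid_thetas(grid)
  M <- grid$M
  dx <- grid$cutoff / M
  d_th <- numeric(M + 1)
  total <- 0
  d_u <- 0; d_v <- 0
  if (u == v) return(list(value = 0, d_theta = d_th, d_u = 0, d_v = 0))
  v_orig <- v
  if (v > grid$cutoff) {
    lo <- max(u, grid$cutoff)
    total <- total + (v - lo) / th[M + 1]
    d_th[M + 1] <- d_th[M + 1] - (v - lo) / th[M + 1]^2
    d_v <- d_v + 1 / th[M + 1]
    if (u >= grid$cutoff) {
      d_u <- -1 / th[M + 1]
      return(list(value = total, d_theta = d_th, d_u = d_u, d_v = d_v))
    }
    v <- grid$cutoff
  }
  i0 <- min(max(floor(u / dx), 0), M - 1)
  i1 <- min(max(ceiling(v / dx) - 1, 0), M - 1)
  for (i in i0:i1) {
    a <- max(u, grid$times[i + 1])
    b2 <- min(v, grid$times[i + 2])
    if (b2 <= a) next
    sa <- (a - grid$times[i + 1]) / dx
    sb <- (b2 - grid$times[i + 1]) / dx
    if (kind == "constant") {
      total <- total + (b2 - a) / th[i + 1]
      d_th[i + 1] <- d_th[i + 1] - (b2 - a) / th[i + 1]^2
      if (a == u) d_u <- d_u - 1 / th[i + 1]
      if (b2 == v && v_orig <= grid$cutoff) d_v <- d_v + 1 / th[i + 1]
    } else {
      slope <- (th[i + 2] - th[i + 1]) / dx
      Na <- th[i + 1] * (1 - sa) + th[i + 2] * sa
      Nb <- th[i + 1] * (1 - sb) + th[i + 2] * sb
      if (abs(slope) > 1e-12 * th[i + 1]) {
        val <- (log(Nb) - log(Na)) / slope
        total <- total + val
        # d/d theta_i: slope depends with -1/dx, endpoints with (1-s)
        for (side in 1:2) {
          dsl <- if (side == 1) -1 / dx else 1 / dx
          dNa <- if (side == 1) (1 - sa) else sa
          dNb <- if (side == 1) (1 - sb) else sb
          g <- -dsl / slope * val + (dNb / Nb - dNa / Na) / slope
          d_th[i + side] <- d_th[i + side] + g
        }
      } else {
        # zero-slope limit: d/dtheta splits by the interval-mean position
        sbar <- (sa + sb) / 2
        total <- total + (b2 - a) / Na
        g <- -(b2 - a) / Na^2
        d_th[i + 1] <- d_th[i + 1] + g * (1 - sbar)
        d_th[i + 2] <- d_th[i + 2] + g * sbar
      }
      if (a == u) d_u <- d_u - 1 / Na
      if (b2 == v && v_orig <= grid$cutoff) d_v <- d_v + 1 / Nb
    }
  }
  list(value = total, d_theta = d_th, d_u = d_u, d_v = d_v)
}

#' Coalescent log-density under a piecewise demographic function
#'
#' The product over coalescent events of `1/N(t_c)` times
#' `exp(-choose(k,2) * integral 1/N)` over every inter-event interval, with
#' the interval's extant lineage count `k` (heterochronous sampling events
#' change `k` without contributing point mass).
#'
#' @param intervals a [coalescent_intervals] object.
#' @param grid a [demographic_grid].
#' @inheritParams pop_size_at
#' @return log-density (single real).
#' @export
coalescent_log_density <- function(intervals, grid, kind = c("linear", "constant")) {
  kind <- match.arg(kind)
  linear <- kind == "linear"
  iv <- intervals$intervals
  starts <- iv$start; ends <- iv$end
  cnts <- iv$lineages * (iv$lineages - 1) / 2
  is_coal <- iv$end_type == "coalescence"
  th <- grid_thetas(grid)
  M <- grid$M
  dx <- grid$cutoff / M
  total <- 0
  for (r in seq_along(starts)) {
    if (cnts[r] > 0 && ends[r] > starts[r]) {
      total <- total - cnts[r] *
        inv_integral_fast(th, M, dx, grid$cutoff, starts[r], ends[r], linear)
    }
    if (is_coal[r]) {
      tc <- ends[r]
      N <- if (tc >= grid$cutoff) th[M + 1] else {
        i <- floor(tc / dx)
        if (linear) {
          s <- (tc - i * dx) / dx
          th[i + 1] * (1 - s) + th[i + 2] * s
        } else th[i + 1]
      }
      total <- total - log(N)
    }
  }
  total
}

# hot path: cellwise integral of 1/N without argument checking
inv_integral_fast <- function(th, M, dx, cutoff, u, v, linear) {
  total <- 0
  if (v > cutoff) {
    lo <- if (u > cutoff) u else cutoff
    total <- (v - lo) / th[M + 1]
    if (u >= cutoff) return(total)
    v <- cutoff
  }
  i0 <- min(max(floor(u / dx), 0), M - 1)
  i1 <- min(max(ceiling(v / dx) - 1, 0), M - 1)
  for (i in i0:i1) {
    a <- max(u, i * dx)
    b2 <- min(v, (i + 1) * dx)
    if (b2 <= a) next
    if (!linear) {
      total <- total + (b2 - a) / th[i + 1]
    } else {
      slope <- (th[i + 2] - th[i + 1]) / dx
      Na <- th[i + 1] + slope * (a - i * dx)
      if (abs(slope) > 1e-12 * th[i + 1]) {
        Nb <- th[i + 1] + slope * (b2 - i * dx)
        total <- total + (log(Nb) - log(Na)) / slope
      } else {
        total <- total + (b2 - a) / Na
      }
    }
  }
  total
}

# log-density plus gradient w.r.t. gamma (log pop sizes) and node heights.
# d_heights is a full node vector; only internal (coalescence) nodes get
# nonzero entries since tip heights are data.
coalescent_log_density_grad <- function(intervals, grid, kind = "linear") {
  iv <- intervals$intervals
  M <- grid$M
  th <- grid_thetas(grid)
  dx <- grid$cutoff / M
  d_th <- numeric(M + 1)
  nodes <- unique(c(iv$end_node, intervals$events$node))
  d_height <- numeric(max(nodes))
  total <- 0
  ev <- intervals$events
  for (r in seq_len(nrow(iv))) {
    cnt <- choose(iv$lineages[r], 2)
    if (cnt > 0 && iv$end[r] > iv$start[r]) {
      g <- inverse_pop_integral_grad(grid, iv$start[r], iv$end[r], kind)
      total <- total - cnt * g$value
      d_th <- d_th - cnt * g$d_theta
      # start boundary is event r of ev; end boundary event r+1
      d_height[ev$node[r]] <- d_height[ev$node[r]] - cnt * g$d_u
      d_height[ev$node[r + 1]] <- d_height[ev$node[r + 1]] - cnt * g$d_v
    }
    if (iv$end_type[r] == "coalescence") {
      tc <- iv$end[r]
      N <- pop_size_at(grid, tc, kind)
      total <- total - log(N)
      if (tc >= grid$cutoff) {
        d_th[M + 1] <- d_th[M + 1] - 1 / N
      } else {
        i <- min(max(floor(tc / dx), 0), M - 1)
        s <- (tc - grid$times[i + 1]) / dx
        if (kind == "linear") {
          slope <- (th[i + 2] - th[i + 1]) / dx
          d_th[i + 1] <- d_th[i + 1] - (1 - s) / N
          d_th[i + 2] <- d_th[i + 2] - s / N
          d_height[ev$node[r + 1]] <- d_height[ev$node[r + 1]] - slope / N
        } else {
          d_th[i + 1] <- d_th[i + 1] - 1 / N
        }
      }
    }
  }
  list(value = total, d_gamma = d_th * th, d_heights = d_height)
}

#' Gaussian Markov random field log-prior on log population sizes
#'
#' First-order intrinsic GMRF: `(M/2) log(kappa / 2 pi) - (kappa/2) *
#' sum (gamma_{i+1} - gamma_i)^2` with `M = length(gamma) - 1`. The level of
#' `gamma` is unpenalized (intrinsic), as is customary for skygrid priors.
#'
#' @param gamma numeric vector of log effective population sizes.
#' @param kappa positive precision.
#' @return log-density.
#' @export
gmrf_log_prior <- function(gamma, kappa) {
  if (kappa <= 0) stop("gmrf_log_prior: kappa must be positive")
  M <- length(gamma) - 1L
  d <- diff(gamma)
  (M / 2) * log(kappa / (2 * pi)) - (kappa / 2) * sum(d^2)
}

gmrf_log_prior_grad <- function(gamma, kappa) {
  M <- length(gamma) - 1L
  d <- diff(gamma)
  g_gamma <- numeric(M + 1)
  g_gamma[1:M] <- kappa * d
  g_gamma[2:(M + 1)] <- g_gamma[2:(M + 1)] - kappa * d
  list(value = (M / 2) * log(kappa / (2 * pi)) - (kappa / 2) * sum(d^2),
       d_gamma = g_gamma,
       d_kappa = M / (2 * kappa) - sum(d^2) / 2)
}
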