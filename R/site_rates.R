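#' Discrete site-rate heterogeneity models
#'
#' Rate heterogeneity across sites is modeled by K equiprobable rate
#' categories placed at the quantile midpoints `(2k-1)/(2K)` of a mean-one
#' Weibull or gamma distribution (or a single constant category). After
#' discretization the category rates are renormalized so their mean is
#' exactly 1, which keeps the clock rate identifiable. The Weibull variant
#' has a closed-form inverse CDF (`scale * (-log(1-p))^(1/shape)` with
#' `scale = 1/gamma(1 + 1/shape)` for unit mean), so its shape derivative is
#' analytic; the gamma quantile has no closed-form shape derivative and is
#' differentiated by central differences on the discretization.
#'
#' @param shape positive shape parameter.
#' @param K number of categories (>= 1).
#' @return An object of class `site_rate_model` with fields `kind`, `shape`,
#'   `K`, `rates`, `weights`, and internal derivative hooks.
#' @examples
#' m <- discrete_gamma_rates(0.5, 4)
#' sum(m$rates * m$weights)  # exactly 1
#' @name site_rates
NULL

new_site_rate_model <- function(kind, shape, K, rates, drates = NULL) {
  structure(list(kind = kind, shape = shape, K = as.integer(K),
                 rates = rates, weights = rep(1 / K, K), drates = drates),
            class = "site_rate_model")
}

#' @rdname site_rates
#' @export
constant_rates <- function() new_site_rate_model("constant", NA_real_, 1L, 1)

weibull_raw_rates <- function(shape, K) {
  p <- (2 * seq_len(K) - 1) / (2 * K)
  (-log(1 - p))^(1 / shape)  # unit-scale; scale cancels in renormalization
}

#' @rdname site_rates
#' @export
discrete_weibull_rates <- function(shape, K) {
  if (shape <= 0) stop("discrete_weibull_rates: shape must be positive")
  if (K < 1) stop("discrete_weibull_rates: K must be >= 1")
  if (K == 1L) return(new_site_rate_model("weibull", shape, 1L, 1,
                                          drates = function(s) 0))
  raw <- weibull_raw_rates(shape, K)
  rates <- raw / mean(raw)
  drates <- function(s) {
    # d/ds of w^(1/s) = -w^(1/s) log(w) / s^2, then quotient rule on
    # raw/mean(raw)
    w <- -log(1 - (2 * seq_len(K) - 1) / (2 * K))
    r <- w^(1 / s)
    dr <- -r * log(w) / s^2
    (dr * mean(r) - r * mean(dr)) / mean(r)^2
  }
  new_site_rate_model("weibull", shape, K, rates, drates)
}

gamma_raw_rates <- function(shape, K) {
  p <- (2 * seq_len(K) - 1) / (2 * K)
  stats::qgamma(p, shape = shape, rate = shape)
}

#' @rdname site_rates
#' @export
discrete_gamma_rates <- function(shape, K) {
  if (shape <= 0) stop("discrete_gamma_rates: shape must be positive")
  if (K < 1) stop("discrete_gamma_rates: K must be >= 1")
  if (K == 1L) return(new_site_rate_model("gamma", shape, 1L, 1,
                                          drates = function(s) 0))
  raw <- gamma_raw_rates(shape, K)
  rates <- raw / mean(raw)
  drates <- function(s) {
    h <- 1e-6 * max(1, abs(s))
    rp <- gamma_raw_rates(s + h, K); rp <- rp / mean(rp)
    rm <- gamma_raw_rates(s - h, K); rm <- rm / mean(rm)
    (rp - rm) / (2 * h)
  }
  new_site_rate_model("gamma", shape, K, rates, drates)
}

# rebuild a site model of the same kind at a new shape
site_model_at_shape <- function(model, shape) {
  switch(model$kind,
         constant = model,
         weibull = discrete_weibull_rates(shape, model$K),
         gamma = discrete_gamma_rates(shape, model$K))
}

#' @export
print.site_rate_model <- function(x, ...) {
  cat(sprintf("site_rate_model: %s, K=%d, shape=%.4g\n", x$kind, x$K, x$shape))
  invisible(x)
}
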