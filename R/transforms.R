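#' ADVI-style bijective transforms between unconstrained and constrained space
#'
#' Each transform maps an unconstrained real slice `y` to a constrained
#' value `x` and reports the log absolute Jacobian determinant of that map,
#' which is added to the log joint so that densities of constrained
#' parameters are correctly pulled back to the real line. Available kinds:
#' `identity`, `log_positive` (`x = exp(y)`), `logistic_unit`
#' (`x = 1/(1+exp(-y))`), and `stick_breaking_simplex` (`K-1` reals to a
#' `K`-simplex, Stan convention with the `log(1/(K-k))` centering shift).
#'
#' @param kind transform name.
#' @param size length of the *constrained* value.
#' @return a `transform` object with `forward(y) -> list(x, logj, cache)`
#'   and `backward(cache, g_x, include_logj) -> g_y`.
#' @export
make_transform <- function(kind = c("identity", "log_positive",
                                    "logistic_unit", "stick_breaking_simplex"),
                           size = 1L) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  dim_u <- if (kind == "stick_breaking_simplex") size - 1L else size
  fwd <- switch(kind,
    identity = function(y) list(x = y, logj = 0, cache = NULL),
    log_positive = function(y) {
      x <- exp(y)
      list(x = x, logj = sum(y), cache = x)
    },
    logistic_unit = function(y) {
      x <- stats::plogis(y)
      list(x = x, logj = sum(log(x) + log1p(-x)), cache = x)
    },
    stick_breaking_simplex = function(y) {
      K <- length(y) + 1L
      z <- stats::plogis(y - log(K - seq_len(K - 1L)))
      x <- numeric(K)
      rem <- numeric(K)
      rem[1] <- 1
      logj <- 0
      for (k in seq_len(K - 1L)) {
        x[k] <- z[k] * rem[k]
        rem[k + 1] <- rem[k] - x[k]
        logj <- logj + log(z[k]) + log1p(-z[k]) + log(rem[k])
      }
      x[K] <- rem[K]
      list(x = x, logj = logj, cache = list(z = z, rem = rem))
    })
  bwd <- switch(kind,
    identity = function(cache, g_x, include_logj = TRUE) g_x,
    log_positive = function(cache, g_x, include_logj = TRUE) {
      g_x * cache + if (include_logj) 1 else 0
    },
    logistic_unit = function(cache, g_x, include_logj = TRUE) {
      g_x * cache * (1 - cache) + if (include_logj) 1 - 2 * cache else 0
    },
    stick_breaking_simplex = function(cache, g_x, include_logj = TRUE) {
      z <- cache$z; rem <- cache$rem
      K <- length(z) + 1L
      g_y <- numeric(K - 1L)
      g_rem <- g_x[K]  # running gradient w.r.t. rem_{k+1}
      for (k in (K - 1L):1L) {
        g_z <- (g_x[k] - g_rem) * rem[k]
        g_rem_k <- g_x[k] * z[k] + g_rem * (1 - z[k])
        if (include_logj) {
          g_z <- g_z + 1 / z[k] - 1 / (1 - z[k])
          g_rem_k <- g_rem_k + 1 / rem[k]
        }
        g_y[k] <- g_z * z[k] * (1 - z[k])
        g_rem <- g_rem_k
      }
      g_y
    })
  structure(list(kind = kind, size = size, dim_unconstrained = dim_u,
                 forward = fwd, backward = bwd), class = "transform")
}

#' Apply a transform to an unconstrained slice
#'
#' Convenience wrapper returning the constrained value and log-Jacobian.
#'
#' @param transform a `transform` from [make_transform].
#' @param y unconstrained values (length `dim_unconstrained`).
#' @return list with `x` (constrained) and `log_jacobian`.
#' @export
transform_to_constrained <- function(transform, y) {
  if (length(y) != transform$dim_unconstrained) {
    stop("transform_to_constrained: slice length mismatch")
  }
  if (any(!is.finite(y))) stop("transform_to_constrained: non-finite input")
  fw <- transform$forward(y)
  list(x = fw$x, log_jacobian = fw$logj)
}

#' Invert a transform (constrained to unconstrained)
#'
#' @param transform a `transform`.
#' @param x constrained value.
#' @return unconstrained vector.
#' @export
transform_to_unconstrained <- function(transform, x) {
  switch(transform$kind,
    identity = x,
    log_positive = log(x),
    logistic_unit = stats::qlogis(x),
    stick_breaking_simplex = {
      K <- length(x)
      rem <- 1 - cumsum(c(0, x[seq_len(K - 2L)]))
      z <- x[seq_len(K - 1L)] / rem
      stats::qlogis(z) + log(K - seq_len(K - 1L))
    })
}
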