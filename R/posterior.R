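#' Parameter block of a joint posterior
#'
#' A block names one model parameter, the bijection linking its constrained
#' domain to a slice of the global unconstrained vector, an optional prior
#' on the constrained value, and an initial value. The special kind
#' `"height_ratios"` (built internally by [build_model]) decodes internal
#' node heights from the ratio reparameterization of a fixed topology.
#'
#' @param name block name (unique within a model).
#' @param transform a `transform` from [make_transform].
#' @param prior optional `prior` object on the constrained value.
#' @param init initial constrained value (defaults chosen by kind).
#' @export
param_block <- function(name, transform, prior = NULL, init = NULL) {
  if (is.null(init)) {
    init <- switch(transform$kind,
                   identity = numeric(transform$size),
                   log_positive = rep(1, transform$size),
                   logistic_unit = rep(0.5, transform$size),
                   stick_breaking_simplex = rep(1 / transform$size, transform$size))
  }
  structure(list(name = name, kind = "transform", transform = transform,
                 prior = prior, init = init,
                 dim = transform$dim_unconstrained),
            class = "param_block")
}

height_block <- function(tree, prior = NULL) {
  machine <- height_transform_machine(tree)
  r <- heights_to_ratios(tree)
  init_y <- c(stats::qlogis(unname(r$ratios)), log(r$root_excess))
  structure(list(name = "heights", kind = "heights", machine = machine,
                 tree = tree, prior = prior, init_unconstrained = init_y,
                 dim = machine$dim),
            class = "param_block")
}

#' Assemble a joint posterior over unconstrained parameters
#'
#' Composes parameter blocks and additive log-density terms into an object
#' exposing `log_density(z)` and `grad(z)` on the global unconstrained
#' vector `z`. The value is the sum of all transform log-Jacobians, block
#' priors, and terms (likelihoods and coupling priors); the gradient is
#' exact, assembled by reverse-mode chain rule through the transforms.
#' Evaluation counts are kept in `$counts` so tests can verify that
#' gradient-free inference never touches the model gradient.
#'
#' @param blocks list of [param_block]s.
#' @param terms list of terms; each is a list with `params` (block names it
#'   reads), `value(x)` returning a scalar, and `grad(x)` returning
#'   `list(value=, grads=list(<block>=gradient w.r.t. constrained value))`.
#' @return an object of class `joint_posterior`.
#' @export
joint_posterior <- function(blocks, terms = list()) {
  names(blocks) <- vapply(blocks, `[[`, "", "name")
  dims <- vapply(blocks, `[[`, 0L, "dim")
  offsets <- cumsum(c(0L, dims))[seq_along(dims)]
  dim <- sum(dims)
  counts <- new.env(parent = emptyenv())
  counts$log_density <- 0L
  counts$gradient <- 0L

  slice <- function(z, i) z[offsets[i] + seq_len(dims[i])]

  forward_all <- function(z) {
    x <- list(); caches <- list(); logj <- 0
    for (i in seq_along(blocks)) {
      b <- blocks[[i]]
      y <- slice(z, i)
      if (b$kind == "heights") {
        fw <- b$machine$forward(y)
        x[[b$name]] <- fw$heights
        caches[[b$name]] <- fw
        logj <- logj + fw$logj
      } else {
        fw <- b$transform$forward(y)
        x[[b$name]] <- fw$x
        caches[[b$name]] <- fw$cache
        logj <- logj + fw$logj
      }
    }
    list(x = x, caches = caches, logj = logj)
  }

  prior_sum <- function(x) {
    s <- 0
    for (b in blocks) {
      if (!is.null(b$prior)) {
        v <- if (b$kind == "heights") b$prior$log_density(x[[b$name]]) else
          b$prior$log_density(x[[b$name]])
        s <- s + v
      }
    }
    s
  }

  obj <- list(
    dim = dim,
    blocks = blocks,
    terms = terms,
    counts = counts,
    offsets = stats::setNames(offsets, names(blocks)),
    dims = stats::setNames(dims, names(blocks)),
    constrain = function(z) forward_all(z)$x,
    log_density = function(z) {
      counts$log_density <- counts$log_density + 1L
      fw <- forward_all(z)
      total <- fw$logj + prior_sum(fw$x)
      for (tm in terms) total <- total + tm$value(fw$x)
      total
    },
    grad = function(z) {
      counts$gradient <- counts$gradient + 1L
      fw <- forward_all(z)
      g_x <- lapply(fw$x, function(v) numeric(length(v)))
      total <- fw$logj
      for (b in blocks) {
        if (!is.null(b$prior)) {
          total <- total + b$prior$log_density(fw$x[[b$name]])
          g_x[[b$name]] <- g_x[[b$name]] + b$prior$grad(fw$x[[b$name]])
        }
      }
      for (tm in terms) {
        gr <- tm$grad(fw$x)
        total <- total + gr$value
        for (nm in names(gr$grads)) {
          g_x[[nm]] <- g_x[[nm]] + gr$grads[[nm]]
        }
      }
      g <- numeric(dim)
      for (i in seq_along(blocks)) {
        b <- blocks[[i]]
        idx <- offsets[i] + seq_len(dims[i])
        if (b$kind == "heights") {
          g[idx] <- b$machine$backward(fw$caches[[b$name]], g_x[[b$name]],
                                       include_logj = TRUE)
        } else {
          g[idx] <- b$transform$backward(fw$caches[[b$name]], g_x[[b$name]],
                                         include_logj = TRUE)
        }
      }
      list(value = total, grad = g)
    },
    init = {
      z0 <- numeric(dim)
      for (i in seq_along(blocks)) {
        b <- blocks[[i]]
        idx <- offsets[i] + seq_len(dims[i])
        z0[idx] <- if (b$kind == "heights") b$init_unconstrained else
          transform_to_unconstrained(b$transform, b$init)
      }
      z0
    }
  )
  class(obj) <- "joint_posterior"
  obj
}

#' @export
print.joint_posterior <- function(x, ...) {
  cat(sprintf("joint_posterior: %d unconstrained parameters, %d blocks, %d terms\n",
              x$dim, length(x$blocks), length(x$terms)))
  for (b in x$blocks) cat(sprintf("  %-16s dim %d\n", b$name, b$dim))
  invisible(x)
}

#' Log joint density of a model at an unconstrained point
#'
#' @param model a [joint_posterior].
#' @param z unconstrained parameter vector.
#' @return log p(z, D) including transform Jacobians.
#' @export
log_joint <- function(model, z) {
  v <- model$log_density(z)
  if (!is.finite(v)) v else v
}

#' Gradient of the log joint
#'
#' @inheritParams log_joint
#' @return list with `value` and `grad`.
#' @export
log_joint_grad <- function(model, z) model$grad(z)

# flatten a constrained-value list into a named numeric vector (trace rows)
flatten_constrained <- function(x) {
  out <- numeric(0)
  for (nm in names(x)) {
    v <- x[[nm]]
    names(v) <- if (length(v) == 1L) nm else paste0(nm, ".", seq_along(v))
    out <- c(out, v)
  }
  out
}
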