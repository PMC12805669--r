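#' Node-height ratio reparameterization
#'
#' Internal node heights are rewritten as a root-height excess plus, for
#' every non-root internal node, a ratio in (0,1) of its position between
#' its lower bound (the oldest descendant tip) and its parent's height:
#' `ratio_i = (h_i - lb_i) / (h_parent - lb_i)`. The map is a bijection onto
#' a box, which is what gradient-based samplers and optimizers need; its
#' log-Jacobian is `sum log(h_parent - lb_i)`.
#'
#' @param tree a [time_tree].
#' @return A list of class `height_ratios` with `root_excess` (root height
#'   minus its lower bound), `ratios` (named by internal node index, root
#'   excluded, in preorder), and `lower_bounds` for all internal nodes.
#' @export
heights_to_ratios <- function(tree) {
  lb <- node_lower_bounds(tree)
  h <- tree$heights
  nonroot <- setdiff(tree$preorder, tree$root)
  ratios <- numeric(length(nonroot))
  for (k in seq_along(nonroot)) {
    i <- nonroot[k]
    p <- tree$parent[i]
    span <- h[p] - lb[i]
    if (h[i] <= lb[i] || h[i] >= h[p]) {
      stop(sprintf("heights_to_ratios: degenerate height at node %d", i))
    }
    ratios[k] <- (h[i] - lb[i]) / span
  }
  structure(list(
    root_excess = h[tree$root] - lb[tree$root],
    ratios = stats::setNames(ratios, nonroot),
    lower_bounds = lb[(tree$n_tips + 1L):tree$n_nodes]
  ), class = "height_ratios")
}

#' Decode height ratios back to a time tree
#'
#' Preorder decode: the root height is its lower bound plus the excess, and
#' each non-root internal height is `lb_i + ratio_i * (h_parent - lb_i)`.
#'
#' @param r a `height_ratios` object (or a list with `root_excess`, `ratios`
#'   in the preorder of `tree`).
#' @param tree a [time_tree] supplying the fixed topology and tip heights.
#' @return a [time_tree] with updated internal heights.
#' @export
ratios_to_heights <- function(r, tree) {
  h <- decode_heights(r$root_excess, unname(r$ratios), tree,
                      node_lower_bounds(tree))$heights
  tree$heights <- h
  tree
}

# shared decode returning heights; ratios in preorder over non-root internals
decode_heights <- function(root_excess, ratios, tree, lb) {
  h <- tree$heights
  h[tree$root] <- lb[tree$root] + root_excess
  nonroot <- setdiff(tree$preorder, tree$root)
  for (k in seq_along(nonroot)) {
    i <- nonroot[k]
    h[i] <- lb[i] + ratios[k] * (h[tree$parent[i]] - lb[i])
  }
  list(heights = h, order = nonroot)
}

#' Log-Jacobian of the height-ratio transform
#'
#' Log absolute determinant of the map from (root excess, ratios) to the
#' internal heights: `sum_i log(h_parent(i) - lb_i)` over non-root internal
#' nodes (the root excess contributes a unit factor).
#'
#' @inheritParams ratios_to_heights
#' @return a single real.
#' @export
log_jacobian_heights <- function(r, tree) {
  tree2 <- ratios_to_heights(r, tree)
  lb <- node_lower_bounds(tree2)
  nonroot <- setdiff(tree2$preorder, tree2$root)
  sum(log(tree2$heights[tree2$parent[nonroot]] - lb[nonroot]))
}

# Forward decode + log-Jacobian + reverse-mode pullback, used by the joint
# posterior. Input is the fully unconstrained slice y = (logit ratios in
# preorder, log root excess); forward returns the decoded heights and the
# total log-Jacobian (height decode + logistic + exponential parts), and
# backward pulls a gradient w.r.t. heights back to y.
height_transform_machine <- function(tree) {
  lb <- node_lower_bounds(tree)
  nonroot <- setdiff(tree$preorder, tree$root)
  root <- tree$root
  parent <- tree$parent
  list(
    dim = length(nonroot) + 1L,
    order = nonroot,
    forward = function(y) {
      m <- length(y)
      ratios <- stats::plogis(y[-m])
      excess <- exp(y[m])
      h <- tree$heights
      h[root] <- lb[root] + excess
      spans <- numeric(length(nonroot))
      for (k in seq_along(nonroot)) {
        i <- nonroot[k]
        spans[k] <- h[parent[i]] - lb[i]
        h[i] <- lb[i] + ratios[k] * spans[k]
      }
      logj <- sum(log(spans)) + sum(log(ratios) + log1p(-ratios)) + y[m]
      list(heights = h, logj = logj, spans = spans, ratios = ratios,
           excess = excess)
    },
    # g_h: gradient of the objective w.r.t. heights (full node vector);
    # include_logj adds d(logJ)/dy assuming logJ entered with coefficient 1.
    backward = function(fw, g_h, include_logj = TRUE) {
      gh <- g_h
      g_ratio <- numeric(length(nonroot))
      if (include_logj) {
        # d sum(log spans) / d h_parent = sum over transform children 1/span
        for (k in seq_along(nonroot)) {
          i <- nonroot[k]
          gh[parent[i]] <- gh[parent[i]] + 1 / fw$spans[k]
        }
      }
      # reverse preorder: children push gradient up to parents
      for (k in rev(seq_along(nonroot))) {
        i <- nonroot[k]
        g_ratio[k] <- gh[i] * fw$spans[k]
        gh[parent[i]] <- gh[parent[i]] + gh[i] * fw$ratios[k]
      }
      r <- fw$ratios
      g_y_ratio <- g_ratio * r * (1 - r) +
        if (include_logj) 1 - 2 * r else 0
      g_y_excess <- gh[root] * fw$excess + if (include_logj) 1 else 0
      c(g_y_ratio, g_y_excess)
    }
  )
}
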